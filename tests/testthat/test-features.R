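test_that("every candidate yields exactly 52 named features", {
  db <- build_linkage_db(hand_gaz(), augment = FALSE)
  gc <- generate_candidates(db, "17 WILSON STREET, COWDENBEATH KY4 9DQ")
  for (cd in gc$candidates) {
    fv <- make_features(cd)
    expect_length(fv, 52)
    expect_identical(names(fv), feature_names())
  }
  expect_length(feature_names(), 52)
})

test_that("blank fields contribute zeros; an all-blank record is all zero", {
  cand <- list(record = as.list(setNames(rep("", 11), address_fields())),
               alignments = list(), input = "SOME INPUT 12",
               mask = rep(TRUE, 13))
  fv <- make_features(cand)
  per_field <- fv[1:44]
  expect_true(all(per_field == 0))
  # residual features still see the unconsumed input
  expect_equal(unname(fv["input_residual_digits"]), 2)

  cand$input <- ""
  cand$mask <- logical(0)
  expect_true(all(make_features(cand) == 0))

  bad <- cand
  names(bad$record)[1] <- "WRONG_FIELD"
  expect_error(make_features(bad), "schema")
})

test_that("a perfectly matching input sums pct_field and M to the field count", {
  gaz <- hand_gaz()[3, ]  # 272 HIGH STREET, METHIL, LEVEN, KY8 3EQ
  db <- build_linkage_db(gaz, augment = FALSE)
  gc <- generate_candidates(db, render_address(gaz))
  fv <- make_features(gc$candidates[[1]])
  k <- sum(nzchar(unlist(gaz[1, address_fields()])))
  expect_equal(unname(fv["sum_pct_field"]), k)
  # each field aligns only its own share of the input, so per-field M < 1
  # except for the field that consumes the final remainder
  expect_gte(unname(fv["sum_harmonic_mean"]), 1)
  expect_lte(unname(fv["sum_harmonic_mean"]), k)
  expect_equal(unname(fv["input_residual_digits"]), 0)
})

test_that("training assembly follows the same-postcode negative sampling rule", {
  # six records in one postcode: 1 positive + 5 negatives under a high cap
  recs <- lapply(1:6, function(i) {
    blank_record(paste0("P", i), BUILDING_NUMBER = as.character(i),
                 THOROUGHFARE = "LONG STREET", POST_TOWN = "ABERKYLE",
                 POSTCODE = "ZZ1 5AA")
  })
  gaz <- dplyr::bind_rows(recs)
  db <- build_linkage_db(gaz, augment = FALSE)
  inputs <- tibble::tibble(id = 1L, address = render_address(gaz[4, ]))
  ann <- tibble::tibble(id = 1L, uprn = "P4", label = "MATCH")
  ts <- assemble_training(inputs, ann, db, negatives_cap = 10, seed = 2)
  expect_equal(sum(ts$y == 1), 1)
  expect_equal(sum(ts$y == 0), 5)

  # singleton postcode: positive only
  gaz1 <- hand_gaz()[2, ]
  db1 <- build_linkage_db(gaz1, augment = FALSE)
  ts1 <- assemble_training(tibble::tibble(id = 1L,
                                          address = render_address(gaz1)),
                           tibble::tibble(id = 1L, uprn = "U2",
                                          label = "MATCH"),
                           db1, negatives_cap = 10, seed = 2)
  expect_equal(sum(ts1$y == 1), 1)
  expect_equal(sum(ts1$y == 0), 0)

  # unknown identifier errors
  expect_error(assemble_training(inputs,
                                 tibble::tibble(id = 1L, uprn = "NOPE",
                                                label = "MATCH"),
                                 db), "not present")

  # determinism under a fixed seed
  big <- make_benchmark(shared_gaz(), 20, corruption_profile(0, 0, 0, 0, 0,
                                                             0, 0, 0),
                        seed = 77)
  a <- assemble_training(big$inputs, big$annotations, shared_db(),
                         negatives_cap = 3, seed = 5)
  b <- assemble_training(big$inputs, big$annotations, shared_db(),
                         negatives_cap = 3, seed = 5)
  expect_identical(a, b)
})

test_that("the forest separates linearly separable classes and is seed-stable", {
  withr::with_seed(31, {
    n <- 400
    x <- matrix(runif(n * 52), n, 52,
                dimnames = list(NULL, feature_names()))
    y <- as.integer(x[, "sum_pct_field"] > 0.5)
    x[, "sum_pct_field"] <- x[, "sum_pct_field"] + runif(n, 0, 0.01)
  })
  m <- train_matcher(list(x = x, y = y), ntree = 100, seed = 3)
  expect_gte(m$oob_accuracy, 0.99)

  # same seed twice: identical predictions
  m2 <- train_matcher(list(x = x, y = y), ntree = 100, seed = 3)
  expect_identical(predict(m, x), predict(m2, x))

  # single-class input refuses to train
  expect_error(train_matcher(list(x = x, y = rep(1L, n))), "both")
})

test_that("shuffled labels give chance-level out-of-bag accuracy", {
  withr::with_seed(37, {
    n <- 2000
    x <- matrix(runif(n * 52), n, 52,
                dimnames = list(NULL, feature_names()))
    y <- sample(rep(0:1, each = n / 2))
  })
  m <- train_matcher(list(x = x, y = y), ntree = 60, seed = 4)
  expect_gt(m$oob_accuracy, 0.4)
  expect_lt(m$oob_accuracy, 0.6)
})

test_that("match probabilities are calibrated around genuine alignments", {
  m <- shared_model()
  zero <- setNames(rep(0, 52), feature_names())
  expect_lt(predict(m, zero), 0.5)

  perfect <- zero
  perfect[paste0("pct_input_", c("BUILDING_NUMBER", "THOROUGHFARE",
                                 "POST_TOWN", "POSTCODE"))] <- 0.25
  perfect[paste0("pct_field_", c("BUILDING_NUMBER", "THOROUGHFARE",
                                 "POST_TOWN", "POSTCODE"))] <- 1
  perfect[paste0("char_cos_", c("BUILDING_NUMBER", "THOROUGHFARE",
                                "POST_TOWN", "POSTCODE"))] <- 1
  perfect["mean_char_cos"] <- 1
  perfect["sum_pct_input"] <- 1
  perfect["sum_pct_field"] <- 4
  perfect["sum_harmonic_mean"] <- 4 * 2 * 0.25 / 1.25
  expect_gt(predict(m, perfect), 0.5)

  withr::with_seed(41, {
    r <- matrix(runif(20 * 52, 0, 3), 20, 52,
                dimnames = list(NULL, feature_names()))
    p <- predict(m, r)
    expect_true(all(p >= 0 & p <= 1))
  })

  bad <- matrix(0, 1, 52)
  colnames(bad) <- rev(feature_names())
  expect_error(predict(m, bad), "feature names")
})

test_that("true pairs score above same-postcode false pairs on the synthetic fixture", {
  ts <- shared_training()
  m <- shared_model()
  p <- predict(m, ts$x)
  expect_gt(mean(p[ts$y == 1]), mean(p[ts$y == 0]))
  expect_gt(mean(p[ts$y == 1]) - mean(p[ts$y == 0]), 0.5)  # clear separation
})

test_that("model summaries expose importance and fit metadata", {
  m <- shared_model()
  td <- tidy(m)
  expect_true(all(c("feature", "importance") %in% names(td)))
  expect_equal(nrow(td), 52)
  g <- glance(m)
  expect_equal(g$ntree, 150)
  expect_equal(g$n_train, m$n_train)
  expect_s3_class(autoplot(m), "ggplot")
})
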