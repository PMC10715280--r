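test_that("load_gazetteer normalises values and enforces the schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- hand_gaz()[1:3, c("uprn", address_fields())]
  df$THOROUGHFARE[1] <- "wilson street"
  readr::write_csv(df, path)

  gaz <- load_gazetteer(path)
  expect_equal(nrow(gaz), 3)
  expect_false(any(gaz$is_augmented))
  expect_equal(gaz$THOROUGHFARE[1], "WILSON STREET")
  expect_equal(gaz$canonical_uprn, gaz$uprn)

  broken <- df[, setdiff(names(df), "POSTCODE")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, path2)
  expect_error(load_gazetteer(path2), "POSTCODE")

  dup <- dplyr::bind_rows(df, dplyr::mutate(df[1, ], THOROUGHFARE = "OTHER"))
  expect_error(load_gazetteer(dup), "duplicate identifier")
})

test_that("flat, saint and abbreviation variants are generated", {
  gaz <- hand_gaz()
  aug <- augment_gazetteer(gaz)

  # "FLAT 1" + number "5" can be written "5/1"
  v <- aug[aug$is_augmented & aug$BUILDING_NUMBER == "5/1", ]
  expect_equal(nrow(v), 1)
  expect_equal(v$canonical_uprn, "U2")
  expect_equal(v$SUB_BUILDING_NAME, "")

  # leading ST stands for SAINT in the database
  expect_true(any(aug$BUILDING_NAME == "SAINT ANDREWS HOUSE" &
                    aug$canonical_uprn == "U6"))

  # street-type abbreviation
  expect_true(any(aug$THOROUGHFARE == "BRUNSWICK RD" &
                    aug$canonical_uprn == "U2"))
  expect_true(any(aug$THOROUGHFARE == "WILSON ST" &
                    aug$canonical_uprn == "U1"))
})

test_that("aliases encode local knowledge and unknown identifiers error", {
  gaz <- hand_gaz()
  ali <- tibble::tibble(alias_text = "ROSELEA HOUSE COWDENBEATH",
                        uprn = "U4")
  aug <- augment_gazetteer(gaz, aliases = ali)
  v <- aug[aug$is_augmented & aug$BUILDING_NAME == "ROSELEA HOUSE COWDENBEATH", ]
  expect_equal(nrow(v), 1)
  expect_equal(v$canonical_uprn, "U4")
  expect_equal(v$POSTCODE, "KY5 2AB")  # inherited for blocking

  expect_error(augment_gazetteer(gaz, aliases = tibble::tibble(
    alias_text = "X", uprn = "U99")), "unknown identifier")
})

test_that("augmentation is monotone and the empty rule set is the identity", {
  gaz <- hand_gaz()
  aug <- augment_gazetteer(gaz)
  expect_true(all(gaz$uprn %in% aug$uprn))
  expect_true(all(aug$canonical_uprn %in% gaz$uprn))
  expect_gte(nrow(aug), nrow(gaz))

  none <- augment_gazetteer(gaz, rules = character(0))
  expect_equal(dplyr::select(none, -dplyr::any_of("dropped")),
               gaz, ignore_attr = TRUE)
})

test_that("augmentation never creates cross-property duplicates", {
  # range expansion of "1-3" collides with the existing number-2 property:
  # the colliding variant must be dropped and reported
  gaz <- mini_gaz(
    blank_record("R1", BUILDING_NUMBER = "1-3", THOROUGHFARE = "MAIN STREET",
                 POST_TOWN = "ABERKYLE", POSTCODE = "ZZ1 1AA"),
    blank_record("R2", BUILDING_NUMBER = "2", THOROUGHFARE = "MAIN STREET",
                 POST_TOWN = "ABERKYLE", POSTCODE = "ZZ1 1AA")
  )
  aug <- augment_gazetteer(gaz)
  expect_equal(nrow(check_consistency(aug)), 0)
  expect_true(any(grepl("^2 MAIN STREET", attr(aug, "dropped"))))
  # the non-colliding expansions survive
  expect_true(any(aug$BUILDING_NUMBER == "1" & aug$is_augmented))
  expect_true(any(aug$BUILDING_NUMBER == "3" & aug$is_augmented))
  # and the shared fixture's full augmentation stays consistent too
  expect_equal(nrow(check_consistency(shared_db()$gazetteer)), 0)
})

test_that("check_consistency reports duplicate renderings across properties", {
  gaz <- mini_gaz(
    blank_record("A1", BUILDING_NUMBER = "1", THOROUGHFARE = "HIGH STREET",
                 POSTCODE = "ZZ1 1AA"),
    blank_record("A2", BUILDING_NUMBER = "1", THOROUGHFARE = "HIGH STREET",
                 POSTCODE = "ZZ1 1AA")
  )
  rep <- check_consistency(gaz)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$n_records, 2)
  expect_equal(nrow(check_consistency(hand_gaz())), 0)
})

test_that("subsumption map learns child regions and resolves conflicts by majority", {
  gaz <- hand_gaz()
  sm <- build_subsumption_map(gaz)
  expect_true(any(sm$edges$child == "METHIL" & sm$edges$parent == "LEVEN"))
  expect_true(all(c("METHIL", "LEVEN", "COWDENBEATH") %in% sm$known_regions))

  empty <- build_subsumption_map(mini_gaz(blank_record("X1")))
  expect_equal(nrow(empty$edges), 0)

  conflicted <- mini_gaz(
    blank_record("C1", DEPENDENT_LOCALITY = "METHIL", POST_TOWN = "LEVEN"),
    blank_record("C2", DEPENDENT_LOCALITY = "METHIL", POST_TOWN = "LEVEN"),
    blank_record("C3", DEPENDENT_LOCALITY = "METHIL",
                 POST_TOWN = "GLENROTHES")
  )
  sm2 <- build_subsumption_map(conflicted)
  e <- sm2$edges[sm2$edges$child == "METHIL", ]
  expect_equal(e$parent, "LEVEN")
  expect_equal(e$n, 2L)
  expect_true(any(sm2$conflicts$parent == "GLENROTHES"))
})

test_that("rendering follows field order and flat styles", {
  r <- blank_record("Z1", SUB_BUILDING_NAME = "FLAT 1", BUILDING_NUMBER = "5",
                    THOROUGHFARE = "BRUNSWICK ROAD", POST_TOWN = "EDINBURGH",
                    POSTCODE = "EH7 5XR")
  expect_equal(render_address(r),
               "FLAT 1, 5 BRUNSWICK ROAD, EDINBURGH, EH7 5XR")
  expect_equal(render_address(r, style = "slash"),
               "5/1 BRUNSWICK ROAD, EDINBURGH, EH7 5XR")
  bare <- blank_record("Z2", THOROUGHFARE = "RIVERSIDE ROAD",
                       POSTCODE = "KY8 4LT")
  expect_equal(render_address(bare), "RIVERSIDE ROAD, KY8 4LT")
})
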