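test_that("dl_distance matches its definition on worked cases", {
  expect_identical(dl_distance("GREENBNAK", "GREENBANK"), 1L)  # transposition
  expect_identical(dl_distance("A", "A"), 0L)
  expect_identical(dl_distance("ST", "STREET"), 4L)
  expect_identical(dl_distance("", "ABC"), 3L)
  # symmetry
  expect_identical(dl_distance("KITTEN", "SITTING"),
                   dl_distance("SITTING", "KITTEN"))
})

test_that("dl_distance equals the brute-force edit-search oracle on tiny strings", {
  withr::with_seed(7, {
    for (k in 1:25) {
      a <- random_string(sample(0:4, 1), LETTERS[1:3])
      b <- random_string(sample(0:4, 1), LETTERS[1:3])
      d <- dl_distance(a, b)
      expected <- if (a == b) 0L else oracle_dl_bfs(a, b)
      expect_equal(d, expected, info = paste(a, b))
    }
  })
})

test_that("dl_distance satisfies the triangle inequality on sampled triples", {
  withr::with_seed(13, {
    for (k in 1:200) {
      s <- replicate(3, random_string(sample(0:8, 1), LETTERS[1:4]))
      d <- c(dl_distance(s[1], s[2]), dl_distance(s[2], s[3]),
             dl_distance(s[1], s[3]))
      expect_lte(d[3], d[1] + d[2])
    }
  })
})

test_that("tokens_equal applies the 0.2 normalised-distance threshold", {
  expect_true(tokens_equal("BRUNSWIK", "BRUNSWICK"))   # 1/9
  expect_false(tokens_equal("ST", "STREET"))            # 4/6
  expect_true(tokens_equal("ROAD", "ROAD"))
  expect_false(tokens_equal("ROAD", "ROAF"))            # 1/4 > 0.2
  expect_true(tokens_equal("ROADS", "ROADZ"))           # 1/5 = 0.2 boundary
})

test_that("nw_align reproduces worked alignments and enumeration scores", {
  al <- nw_align(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(al$score, 3)
  expect_equal(sum(al$columns[, 1] > 0 & al$columns[, 2] > 0), 3)

  al2 <- nw_align(c("A", "B"), "B")
  expect_equal(al2$score, 0)  # one match, one gap

  ch <- function(x) strsplit(x, "")[[1]]
  al3 <- nw_align(ch("GREEN BANK"), ch("GREENBANK"))
  paired <- al3$columns[al3$columns[, 1] > 0 & al3$columns[, 2] > 0, ]
  n_eq <- sum(ch("GREEN BANK")[paired[, 1]] == ch("GREENBANK")[paired[, 2]])
  expect_equal(n_eq, 9)
  expect_equal(sum(al3$columns[, 1] == 0 | al3$columns[, 2] == 0), 1)
})

test_that("nw_align score equals exhaustive enumeration on random pairs", {
  withr::with_seed(29, {
    for (k in 1:200) {
      a <- sample(LETTERS[1:4], sample(0:6, 1), replace = TRUE)
      b <- sample(LETTERS[1:4], sample(0:6, 1), replace = TRUE)
      expect_equal(nw_align(a, b)$score, oracle_nw_score(a, b),
                   info = paste(paste(a, collapse = ""),
                                paste(b, collapse = "")))
    }
  })
})

test_that("char_cos matches hand computations", {
  expect_equal(char_cos("AB", "BA"), 1)
  expect_equal(char_cos("AA", "AB"), 2 / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(char_cos("ABC", "XYZ"), 0)
  expect_equal(char_cos("", "ABC"), 0)
  expect_equal(char_cos("A-B C", "AB C-"), 1)  # punctuation/space ignored
})

test_that("summary score follows S = M - 0.01 I + 0.1 F exactly", {
  expect_equal(summary_score(1, 0, 1), 1.1, tolerance = 1e-12)
  expect_equal(summary_score(0.9, 2, 0.8), 0.96, tolerance = 1e-12)
  expect_equal(summary_score(0, 0, 0), 0)
  # monotonicity on random triples
  withr::with_seed(5, {
    M <- runif(50); F <- runif(50); I <- sample(0:5, 50, TRUE)
    expect_true(all(summary_score(M + 0.01, I, F) > summary_score(M, I, F)))
    expect_true(all(summary_score(M, I, F + 0.01) > summary_score(M, I, F)))
    expect_true(all(summary_score(M, I + 1, F) < summary_score(M, I, F)))
  })
})

test_that("token alignment locates fields with exact and fuzzy tokens", {
  al <- token_align("5/1 BRUNSWICK ROAD EDINBURGH", "BRUNSWICK ROAD")
  expect_equal(al$pct_field, 1)
  expect_equal(nrow(al$spans), 2)  # one span per matched token

  fuzzy <- token_align("5/1 BRUNSWIK ROAD", "BRUNSWICK ROAD")
  expect_equal(fuzzy$pct_field, 1)  # both tokens matched, one fuzzily

  concat <- token_align("GREENBANK TERRACE", "GREEN BANK TERRACE")
  expect_lt(concat$pct_field, 1)  # GREENBANK matches neither GREEN nor BANK
})

test_that("string alignment resolves concatenation and applies the 80% span rule", {
  s <- string_align("GREENBANK TERRACE", "GREEN BANK TERRACE")
  expect_equal(s$pct_field, 1)  # GREEN (5/5) and BANK (4/4) both retained

  discard <- string_align("ST", "STREET")
  expect_equal(discard$pct_field, 0)  # 2/6 = 33% < 80%: span discarded

  self <- string_align("17 WILSON STREET", "17 WILSON STREET")
  expect_equal(self$pct_input, 1)
  expect_equal(self$pct_field, 1)
})

test_that("align_field picks the higher-scoring route, token on ties", {
  exact <- align_field("5/1 BRUNSWICK ROAD EDINBURGH", "BRUNSWICK ROAD")
  expect_equal(exact$method, "token")

  concat <- align_field("GREENBANK TERRACE", "GREEN BANK TERRACE")
  expect_equal(concat$method, "string")
  expect_equal(concat$pct_field, 1)

  empty <- align_field("ANY INPUT", "")
  expect_equal(empty$S, 0)
  expect_equal(nrow(empty$spans), 0)
})

test_that("self-alignment of punctuation-free text is perfect", {
  withr::with_seed(17, {
    for (k in 1:20) {
      x <- paste(replicate(sample(1:4, 1), random_string(sample(2:8, 1),
                                                         LETTERS)),
                 collapse = " ")
      al <- align_field(x, x)
      expect_equal(al$pct_input, 1)
      expect_equal(al$pct_field, 1)
      expect_equal(al$M, 1)
      expect_equal(al$F, 1, tolerance = 1e-12)
      expect_equal(al$I, 0L)
      expect_equal(al$S, 1.1, tolerance = 1e-12)
    }
  })
})

test_that("alignment invariants hold on random field/input pairs", {
  withr::with_seed(23, {
    for (k in 1:40) {
      input <- paste(replicate(sample(2:5, 1),
                               random_string(sample(2:8, 1), LETTERS[1:6])),
                     collapse = " ")
      field <- paste(replicate(sample(1:3, 1),
                               random_string(sample(2:8, 1), LETTERS[1:6])),
                     collapse = " ")
      al <- align_field(input, field)
      if (al$pct_input == 0 || al$pct_field == 0) {
        expect_equal(al$M, 0)
      } else {
        # the harmonic mean lies between the two percentages
        expect_gte(al$M, min(al$pct_input, al$pct_field) - 1e-12)
        expect_lte(al$M, max(al$pct_input, al$pct_field) + 1e-12)
      }
      expect_equal(al$S, al$M - 0.01 * al$I + 0.1 * al$F, tolerance = 1e-12)
      if (nrow(al$spans) > 1) {
        expect_true(all(al$spans[-1, "start"] >
                          al$spans[-nrow(al$spans), "end"]))
      }
      if (nrow(al$spans) > 0) {
        expect_gte(min(al$spans[, "start"]), 1)
        expect_lte(max(al$spans[, "end"]), nchar(input))
      }
    }
  })
})
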