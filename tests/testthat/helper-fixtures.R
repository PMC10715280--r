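# Fixture builders. Everything is generated in code; the heavier shared
# objects (a 200-record synthetic database and a trained model) are built
# once per test run and memoised.

blank_record <- function(uprn = "U1", ...) {
  out <- tibble::tibble(uprn = uprn)
  for (f in address_fields()) out[[f]] <- ""
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out$is_augmented <- FALSE
  out$canonical_uprn <- out$uprn
  out
}

mini_gaz <- function(...) {
  dplyr::bind_rows(...)
}

# Hand-written 6-record gazetteer used across the unit tests.
hand_gaz <- function() {
  mini_gaz(
    blank_record("U1", BUILDING_NUMBER = "17", THOROUGHFARE = "WILSON STREET",
                 POST_TOWN = "COWDENBEATH", POSTCODE = "KY4 9DQ"),
    blank_record("U2", SUB_BUILDING_NAME = "FLAT 1", BUILDING_NUMBER = "5",
                 THOROUGHFARE = "BRUNSWICK ROAD", POST_TOWN = "EDINBURGH",
                 POSTCODE = "EH7 5XR"),
    blank_record("U3", BUILDING_NUMBER = "272", THOROUGHFARE = "HIGH STREET",
                 DEPENDENT_LOCALITY = "METHIL", POST_TOWN = "LEVEN",
                 POSTCODE = "KY8 3EQ"),
    blank_record("U4", BUILDING_NUMBER = "175",
                 THOROUGHFARE = "STENHOUSE STREET",
                 POST_TOWN = "COWDENBEATH", POSTCODE = "KY5 2AB"),
    blank_record("U5", BUILDING_NUMBER = "3", THOROUGHFARE = "WILSON STREET",
                 POST_TOWN = "COWDENBEATH", POSTCODE = "KY4 9DQ"),
    blank_record("U6", BUILDING_NAME = "ST ANDREWS HOUSE",
                 THOROUGHFARE = "RIVERSIDE ROAD", POST_TOWN = "LEVEN",
                 POSTCODE = "KY8 4LT")
  )
}

.shared <- new.env(parent = emptyenv())

shared_gaz <- function() {
  if (is.null(.shared$gaz)) .shared$gaz <- make_toy_gazetteer(200, seed = 11)
  .shared$gaz
}

shared_db <- function() {
  if (is.null(.shared$db)) .shared$db <- build_linkage_db(shared_gaz())
  .shared$db
}

shared_model <- function() {
  if (is.null(.shared$model)) {
    tb <- make_benchmark(shared_gaz(), 60, corruption_profile(
      typo = 0.05, abbreviation = 0.3, flat_flip = 0.25, wrong_postcode = 0,
      locality_dropout = 0.1, county_insertion = 0.1, not_in_db = 0,
      too_broad = 0), seed = 21)
    ts <- assemble_training(tb$inputs, tb$annotations, shared_db(),
                            negatives_cap = 10, seed = 31)
    .shared$training <- ts
    .shared$model <- train_matcher(ts, ntree = 150, seed = 41)
  }
  .shared$model
}

shared_training <- function() {
  shared_model()
  .shared$training
}
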