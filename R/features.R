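#' Names of the 52 classifier features
#'
#' Four alignment metrics per address field (fraction aligned on the input
#' side, fraction aligned on the field side, insertion count, character
#' cosine) times 11 fields, plus 8 overall summaries.
#'
#' @param schema The 11-field schema.
#' @return Character vector of length 52.
#' @export
feature_names <- function(schema = address_fields()) {
  c(paste0("pct_input_", schema),
    paste0("pct_field_", schema),
    paste0("n_insert_", schema),
    paste0("char_cos_", schema),
    "mean_char_cos",
    "input_residual_digits", "input_residual_singles",
    "field_residual_digits", "field_residual_singles",
    "sum_pct_input", "sum_pct_field", "sum_harmonic_mean")
}

count_digits <- function(x) {
  if (!nzchar(x)) return(0L)
  stringr::str_count(x, "[0-9]")
}

count_single_tokens <- function(x) {
  tk <- tokenize_pos(x)$tok
  sum(nchar(tk) == 1L)
}

#' Feature vector for one candidate pair
#'
#' Converts a candidate alignment set (one input address against one
#' gazetteer record, produced by [bfs_match()]) into the 52-dimensional
#' feature vector consumed by the matching classifier. Fields blank in the
#' record contribute zeros; overall features summarise the alignment
#' residuals on both sides.
#'
#' @param cand One candidate from [bfs_match()].
#' @param schema The 11-field schema.
#' @return Named numeric vector of length 52, ordered as [feature_names()].
#' @export
make_features <- function(cand, schema = address_fields()) {
  if (!setequal(names(cand$record), schema)) {
    stop("candidate record does not carry the configured field schema",
         call. = FALSE)
  }
  als <- lapply(setNames(schema, schema), function(f) {
    cand$alignments[[f]] %||% zero_alignment(cand$record[[f]])
  })
  pct_in <- vapply(als, `[[`, numeric(1), "pct_input")
  pct_f <- vapply(als, `[[`, numeric(1), "pct_field")
  ins <- vapply(als, function(a) as.numeric(a$I), numeric(1))
  fcos <- vapply(als, `[[`, numeric(1), "F")
  hm <- vapply(als, `[[`, numeric(1), "M")

  nonblank <- vapply(schema, function(f) nzchar(cand$record[[f]]), logical(1))
  mean_cos <- if (any(nonblank)) mean(fcos[nonblank]) else 0

  input_res <- visible_string(cand$input, cand$mask)
  field_res <- vapply(als, `[[`, character(1), "field_residual")

  v <- c(pct_in, pct_f, ins, fcos,
         mean_cos,
         count_digits(input_res),
         count_single_tokens(input_res),
         sum(vapply(field_res, count_digits, integer(1))),
         sum(vapply(field_res, count_single_tokens, integer(1))),
         sum(pct_in), sum(pct_f), sum(hm))
  setNames(v, feature_names(schema))
}
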