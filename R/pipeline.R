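#' Match free-text addresses against the gazetteer
#'
#' The end-to-end workflow: each address is cleaned, completed, parsed for
#' hints, blocked to a local subtree, and every candidate record in the
#' subtree is scored by the trained classifier. The `top_n` candidates are
#' returned per input, ranked by descending probability (exact probability
#' ties broken by total alignment score, then identifier); hits on augmented
#' variants report the canonical identifier.
#' When the postcode route yields a best score below `threshold` and a town
#' hint exists, the town/thoroughfare route is retried and the better result
#' kept (`route = "postcode+fallback"`).
#'
#' @param inputs Data frame with an `address` column and optional `id`
#'   (default: row number).
#' @param db A `linkage_db` from [build_linkage_db()].
#' @param model A `match_model` from [train_matcher()].
#' @param top_n Candidates returned per input (default 5).
#' @param threshold Acceptance threshold `t` on the probability (default 0.5).
#' @param min_match Blocking floor, see [dfs_block()].
#' @return Tibble with columns `input_id`, `rank`, `uprn` (canonical),
#'   `score`, `accepted`, `route`, `failure_reason`. Unmatchable inputs get
#'   one row with `rank` and `uprn` `NA` and `failure_reason` `"empty"` or
#'   `"blocking"`.
#' @export
match_addresses <- function(inputs, db, model, top_n = 5, threshold = 0.5,
                            min_match = 0.5) {
  inputs <- tibble::as_tibble(inputs)
  if (!"id" %in% names(inputs)) inputs$id <- seq_len(nrow(inputs))
  rows <- lapply(seq_len(nrow(inputs)), function(i) {
    match_one(inputs$address[i], inputs$id[i], db, model, top_n, threshold,
              min_match)
  })
  dplyr::bind_rows(rows)
}

score_route <- function(gc, model) {
  if (length(gc$candidates) == 0) return(NULL)
  feats <- t(vapply(gc$candidates, make_features,
                    numeric(length(feature_names()))))
  probs <- predict(model, feats)
  # classifier probability ranks candidates; exact ties (e.g. a flat number
  # swapped with the building number, where only the insertion count
  # differs) are broken by total alignment quality, then by identifier
  total_s <- vapply(gc$candidates, function(cd) {
    sum(vapply(cd$alignments, `[[`, numeric(1), "S"))
  }, numeric(1))
  tibble::tibble(
    uprn = vapply(gc$candidates, `[[`, character(1), "canonical_uprn"),
    score = probs, total_s = total_s) |>
    dplyr::group_by(.data$uprn) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$total_s),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$total_s),
                   .data$uprn) |>
    dplyr::select(-"total_s")
}

match_one <- function(address, id, db, model, top_n, threshold, min_match) {
  unmatchable <- function(reason) {
    tibble::tibble(input_id = id, rank = NA_integer_, uprn = NA_character_,
                   score = NA_real_, accepted = FALSE, route = NA_character_,
                   failure_reason = reason)
  }
  gc <- generate_candidates(db, address, min_match = min_match)
  if (identical(gc$failure, "empty")) return(unmatchable("empty"))
  ranked <- if (is.na(gc$failure)) score_route(gc, model) else NULL
  route <- gc$route

  # low-confidence postcode block: retry the town/thoroughfare descent
  need_fallback <- is.null(ranked) || ranked$score[1] < threshold
  if (need_fallback && !identical(route, "town") &&
      !is.null(gc$hints) && !is.na(gc$hints$post_town[1])) {
    gc2 <- generate_candidates(db, address, min_match = min_match,
                               route = "town")
    ranked2 <- if (is.na(gc2$failure)) score_route(gc2, model) else NULL
    if (!is.null(ranked2) &&
        (is.null(ranked) || ranked2$score[1] > ranked$score[1])) {
      ranked <- ranked2
      route <- if (is.null(route) || is.na(route)) "town" else "postcode+fallback"
    }
  }
  if (is.null(ranked)) return(unmatchable("blocking"))

  ranked <- head(ranked, top_n)
  tibble::tibble(input_id = id, rank = seq_len(nrow(ranked)),
                 uprn = ranked$uprn, score = ranked$score,
                 accepted = ranked$score >= threshold, route = route,
                 failure_reason = NA_character_)
}

#' F1 score
#'
#' Harmonic mean of precision and recall; defined as 0 (with a warning)
#' when both are 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return `2 * P * R / (P + R)`.
#' @examples
#' f1_score(0.993, 0.983)
#' @export
f1_score <- function(precision, recall) {
  denom <- precision + recall
  if (any(denom == 0, na.rm = TRUE)) {
    warning("precision and recall are both 0; F1 defined as 0")
  }
  ifelse(denom == 0, 0, 2 * precision * recall / denom)
}

normalise_annotations <- function(annotations) {
  ann <- tibble::as_tibble(annotations)
  if (!"label" %in% names(ann)) ann$label <- NA_character_
  ann$label[is.na(ann$label) & !is.na(ann$uprn)] <- "MATCH"
  ann
}

#' Threshold sweep of the confidence score
#'
#' For each threshold `t` in `grid`, cross-tabulates top-1 correctness
#' against acceptance (`score >= t`) and reports precision, recall and F1 -
#' the data behind a lift curve. An input with no accepted top-1 prediction
#' at `t` counts as rejected.
#'
#' @param predictions Output of [match_addresses()].
#' @param annotations Tibble `(id, uprn, label)`; `uprn` is `NA` for inputs
#'   annotated as not matchable.
#' @param grid Thresholds (default 0 to 1 in steps of 0.05).
#' @return Tibble `(threshold, tp, fp, fn, tn, precision, recall, f1)`.
#' @export
threshold_sweep <- function(predictions, annotations,
                            grid = seq(0, 1, by = 0.05)) {
  ann <- normalise_annotations(annotations)
  top1 <- dplyr::filter(predictions, is.na(.data$rank) | .data$rank == 1L)
  j <- dplyr::left_join(ann, top1, by = c(id = "input_id"))
  correct <- !is.na(j$uprn.x) & !is.na(j$uprn.y) & j$uprn.x == j$uprn.y
  score <- ifelse(is.na(j$score), -Inf, j$score)
  purrr::map_dfr(grid, function(t) {
    acc <- score >= t
    tp <- sum(correct & acc); fp <- sum(!correct & acc)
    fn <- sum(correct & !acc); tn <- sum(!correct & !acc)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else {
      NA_real_
    }
    tibble::tibble(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = precision, recall = recall, f1 = f1)
  })
}

#' Evaluate predictions against annotations
#'
#' Computes the full evaluation report: raw accuracy `c/n` (correct top-1
#' matches over all sampled inputs), adjusted accuracy `c/p` (over the
#' inputs a human could match), top-k accuracy (any correct identifier among
#' the k best), the not-possible breakdown, and the threshold sweep.
#'
#' @param predictions Output of [match_addresses()]; every `input_id` must
#'   appear in `annotations`.
#' @param annotations Tibble `(id, uprn, label)`. `label` is one of
#'   `NOT_IN_DB`, `TOO_BROAD`, `LOW_QUALITY` for unmatchable inputs and
#'   `MATCH` (or `NA`) otherwise.
#' @param top_k k for top-k accuracy (default 5).
#' @param grid Threshold grid for the sweep.
#' @param threshold Headline threshold for precision/recall/F1 (default 0.5).
#' @return Object of class `linkage_eval`; see [glance.linkage_eval()] and
#'   [tidy.linkage_eval()].
#' @export
evaluate_matches <- function(predictions, annotations, top_k = 5,
                             grid = seq(0, 1, by = 0.05), threshold = 0.5) {
  ann <- normalise_annotations(annotations)
  missing_ids <- setdiff(unique(predictions$input_id), ann$id)
  if (length(missing_ids) > 0) {
    stop("prediction id(s) absent from annotations: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  n <- nrow(ann)
  matchable <- !is.na(ann$uprn)
  p <- sum(matchable)

  top1 <- dplyr::filter(predictions, .data$rank %in% 1L)
  j1 <- dplyr::left_join(ann, top1, by = c(id = "input_id"))
  correct1 <- !is.na(j1$uprn.x) & !is.na(j1$uprn.y) & j1$uprn.x == j1$uprn.y
  c_count <- sum(correct1)

  topk <- predictions |>
    dplyr::filter(!is.na(.data$rank), .data$rank <= top_k) |>
    dplyr::inner_join(ann, by = c(input_id = "id")) |>
    dplyr::group_by(.data$input_id) |>
    dplyr::summarise(hit = any(!is.na(.data$uprn.y) &
                                 .data$uprn.x == .data$uprn.y),
                     .groups = "drop")
  ck <- sum(topk$hit)

  not_poss <- ann[!matchable, ]
  breakdown <- not_poss |>
    dplyr::count(.data$label, name = "n_cases") |>
    dplyr::mutate(pct_of_all = 100 * .data$n_cases / n,
                  pct_of_not_possible = 100 * .data$n_cases / max(nrow(not_poss), 1))

  sweep <- threshold_sweep(predictions, ann, grid)
  at_t <- threshold_sweep(predictions, ann, threshold)

  structure(list(
    n = n, p = p, c = c_count,
    raw_accuracy = c_count / n,
    adjusted_accuracy = if (p > 0) c_count / p else NA_real_,
    top_k = top_k,
    top_k_raw_accuracy = ck / n,
    top_k_adjusted_accuracy = if (p > 0) ck / p else NA_real_,
    n_not_possible = nrow(not_poss),
    pct_not_possible = 100 * nrow(not_poss) / n,
    breakdown = breakdown,
    threshold = threshold,
    precision = at_t$precision[1], recall = at_t$recall[1], f1 = at_t$f1[1],
    sweep = sweep
  ), class = "linkage_eval")
}

#' @export
print.linkage_eval <- function(x, ...) {
  cat("<linkage_eval> n = ", x$n, ", matchable p = ", x$p,
      ", correct c = ", x$c, "\n",
      sprintf("  raw accuracy      %.3f\n", x$raw_accuracy),
      sprintf("  adjusted accuracy %s\n",
              ifelse(is.na(x$adjusted_accuracy), "undefined (p = 0)",
                     sprintf("%.3f", x$adjusted_accuracy))),
      sprintf("  top-%d adjusted    %s\n", x$top_k,
              ifelse(is.na(x$top_k_adjusted_accuracy), "undefined",
                     sprintf("%.3f", x$top_k_adjusted_accuracy))),
      sprintf("  at t = %.2f: precision %.3f, recall %.3f, F1 %.3f\n",
              x$threshold, x$precision, x$recall, x$f1), sep = "")
  invisible(x)
}

#' One-row summary of an evaluation
#' @param x A `linkage_eval`.
#' @param ... Unused.
#' @export
glance.linkage_eval <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, c = x$c,
                 raw_accuracy = x$raw_accuracy,
                 adjusted_accuracy = x$adjusted_accuracy,
                 top_k = x$top_k,
                 top_k_adjusted_accuracy = x$top_k_adjusted_accuracy,
                 pct_not_possible = x$pct_not_possible,
                 precision = x$precision, recall = x$recall, f1 = x$f1)
}

#' Threshold-sweep table of an evaluation
#' @param x A `linkage_eval`.
#' @param ... Unused.
#' @export
tidy.linkage_eval <- function(x, ...) {
  x$sweep
}

#' Lift curve of an evaluation
#' @param object A `linkage_eval`.
#' @param ... Unused.
#' @export
autoplot.linkage_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$sweep,
                            c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "confidence threshold t", y = NULL,
                  title = "Match quality across confidence thresholds")
}
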