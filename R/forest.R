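#' Generate scored candidates for one input address
#'
#' The per-address front half of the matching workflow: clean, apply
#' knowledge-based completion/deletion, parse hints, block by tree descent,
#' then score every record in the blocked subtree by breadth-first
#' alignment. Used by both training assembly and matching.
#'
#' @param db A `linkage_db`.
#' @param address One raw address string.
#' @param min_match Blocking floor, see [dfs_block()].
#' @param route Passed to [dfs_block()].
#' @return List with `failure` (`NA`, `"empty"` or `"blocking"`),
#'   `candidates` (see [bfs_match()]), `cleaned`, `hints`, `route`.
#' @export
generate_candidates <- function(db, address, min_match = 0.5,
                                route = c("auto", "town")) {
  route <- match.arg(route)
  cl <- clean_address(address)
  if (is.na(cl) || !nzchar(cl)) {
    return(list(failure = "empty", candidates = list(),
                cleaned = cl, hints = NULL, route = NA_character_))
  }
  cl <- complete_address(cl, db$subsumption)
  hints <- parse_hints(cl, db$known_towns, db$known_thoroughfares)
  blk <- dfs_block(db, cl, hints, min_match = min_match, route = route)
  if (is.null(blk)) {
    return(list(failure = "blocking", candidates = list(),
                cleaned = cl, hints = hints, route = NA_character_))
  }
  list(failure = NA_character_,
       candidates = bfs_match(blk$node, cl, blk$mask, db$gazetteer,
                              blk$alignments),
       cleaned = cl, hints = hints, route = blk$route)
}

#' Assemble labelled training pairs
#'
#' One positive pair per annotated input (the candidate whose canonical
#' identifier equals the annotation) and up to `negatives_cap` negative
#' pairs drawn from candidates in the same postcode, excluding the true
#' match. Deterministic under `seed`.
#'
#' @param inputs Tibble with columns `id` and `address`.
#' @param annotations Tibble with columns `id`, `uprn` (`NA` for
#'   unmatchable inputs) and optionally `label`.
#' @param db A `linkage_db`.
#' @param negatives_cap Maximum negatives per positive (default 20).
#' @param seed Integer seed for negative sampling.
#' @param min_match Blocking floor.
#' @return Object of class `training_set`: list with feature matrix `x`,
#'   0/1 vector `y` and a `meta` tibble (`id`, `uprn`, `label`).
#' @export
assemble_training <- function(inputs, annotations, db, negatives_cap = 20,
                              seed = 1, min_match = 0.5) {
  ann <- dplyr::inner_join(inputs, annotations, by = "id")
  ann <- ann[!is.na(ann$uprn), ]
  bad <- setdiff(ann$uprn, db$gazetteer$canonical_uprn)
  if (length(bad) > 0) {
    stop("annotation identifier(s) not present in the gazetteer: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  xs <- list(); ys <- integer(); meta <- list()
  set.seed(seed)
  for (i in seq_len(nrow(ann))) {
    gc <- generate_candidates(db, ann$address[i], min_match = min_match)
    if (length(gc$candidates) == 0) next
    canon <- vapply(gc$candidates, `[[`, character(1), "canonical_uprn")
    pos_idx <- which(canon == ann$uprn[i])
    if (length(pos_idx) == 0) next  # blocking missed the true record
    feats <- lapply(gc$candidates, make_features)
    if (length(pos_idx) > 1) {
      # several augmented variants of the true record: keep the best-aligned
      s <- vapply(pos_idx, function(k) feats[[k]][["sum_pct_field"]], numeric(1))
      pos_idx <- pos_idx[which.max(s)]
    }
    pos_pc <- gc$candidates[[pos_idx]]$record$POSTCODE
    neg_idx <- which(canon != ann$uprn[i] &
                       vapply(gc$candidates, function(cd) {
                         !nzchar(pos_pc) || cd$record$POSTCODE == pos_pc
                       }, logical(1)))
    # one pair per distinct property
    neg_idx <- neg_idx[!duplicated(canon[neg_idx])]
    if (length(neg_idx) > negatives_cap) {
      neg_idx <- sort(sample(neg_idx, negatives_cap))
    }
    for (k in c(pos_idx, neg_idx)) {
      xs[[length(xs) + 1L]] <- feats[[k]]
      ys[length(ys) + 1L] <- as.integer(k == pos_idx)
      meta[[length(meta) + 1L]] <-
        tibble::tibble(id = ann$id[i], uprn = canon[k],
                       label = ifelse(k == pos_idx, "match", "non-match"))
    }
  }
  if (length(xs) == 0) stop("no training pairs could be assembled", call. = FALSE)
  out <- list(x = do.call(rbind, xs), y = ys, meta = dplyr::bind_rows(meta))
  rownames(out$x) <- NULL
  class(out) <- "training_set"
  out
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set> ", length(x$y), " pairs (",
      sum(x$y), " match / ", sum(x$y == 0), " non-match), ",
      ncol(x$x), " features\n", sep = "")
  invisible(x)
}

#' Train the random-forest matching classifier
#'
#' Bagged classification trees with gini splits and random feature subsets
#' per node; the averaged leaf class fraction is the match probability. The
#' forest is grown by the package's own implementation (seeded, fully
#' deterministic). Out-of-bag accuracy is reported in `glance()`.
#'
#' @param training A `training_set` from [assemble_training()], or a list
#'   with elements `x` (matrix, 52 columns) and `y` (0/1).
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param min_node Minimum records per leaf.
#' @param seed Integer seed; recorded in the model.
#' @return Object of class `match_model`.
#' @export
train_matcher <- function(training, ntree = 500, mtry = NULL, min_node = 1,
                          seed = 1) {
  x <- training$x; y <- as.integer(training$y)
  if (length(unique(y)) < 2) {
    stop("training data must contain both match and non-match pairs",
         call. = FALSE)
  }
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  fit <- rf_train_cpp(x, y, as.integer(ntree), as.integer(mtry),
                      as.integer(min_node), as.integer(seed))
  oob_ok <- !is.na(fit$oob_prob)
  structure(list(
    forest = fit$trees,
    importance = setNames(as.numeric(fit$importance), colnames(x)),
    oob_accuracy = mean((fit$oob_prob[oob_ok] >= 0.5) == y[oob_ok]),
    feature_names = colnames(x),
    ntree = ntree, mtry = mtry, min_node = min_node, seed = seed,
    threshold = 0.5,
    n_train = length(y), n_pos = sum(y)
  ), class = "match_model")
}

#' Match probabilities for feature vectors
#'
#' @param object A `match_model`.
#' @param newdata Numeric matrix (or single named vector) of features whose
#'   column names equal the model's feature names.
#' @param ... Unused.
#' @return Numeric vector of match probabilities in `[0, 1]`.
#' @export
predict.match_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  if (!identical(colnames(newdata), object$feature_names)) {
    stop("feature names do not match the model's feature schema",
         call. = FALSE)
  }
  rf_predict_cpp(object$forest, newdata)
}

#' @export
print.match_model <- function(x, ...) {
  cat("<match_model> ", x$ntree, " trees, mtry ", x$mtry, ", trained on ",
      x$n_train, " pairs (", x$n_pos, " match); OOB accuracy ",
      sprintf("%.3f", x$oob_accuracy), "\n", sep = "")
  invisible(x)
}

#' @rdname train_matcher
#' @param x A `match_model`.
#' @param ... Unused.
#' @export
tidy.match_model <- function(x, ...) {
  tibble::tibble(feature = names(x$importance),
                 importance = as.numeric(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname train_matcher
#' @export
glance.match_model <- function(x, ...) {
  tibble::tibble(ntree = x$ntree, mtry = x$mtry, n_train = x$n_train,
                 n_match = x$n_pos, oob_accuracy = x$oob_accuracy,
                 seed = x$seed)
}

#' @rdname train_matcher
#' @param object A `match_model`.
#' @param top_n Number of features shown.
#' @export
autoplot.match_model <- function(object, top_n = 15, ...) {
  df <- head(tidy(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Gini importance", y = NULL,
                  title = "Match-classifier feature importance")
}
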