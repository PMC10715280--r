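#' Damerau-Levenshtein distance
#'
#' Minimal number of single-character insertions, deletions, substitutions
#' and adjacent transpositions turning `a` into `b` (the unrestricted
#' variant, a true metric). Vectorised with recycling.
#'
#' @param a,b Character vectors.
#' @return Integer vector of edit counts.
#' @examples
#' dl_distance("GREENBNAK", "GREENBANK")  # one transposition
#' @export
dl_distance <- function(a, b) {
  dl_distance_cpp(as.character(a), as.character(b))
}

#' Fuzzy token equivalence
#'
#' Two tokens are considered the same when their Damerau-Levenshtein
#' distance, normalised by the longer token's length, is at most
#' `threshold`. The default 0.2 corresponds to less than one error in five
#' letters, which is where typographical errors typically start to occur.
#'
#' @param a,b Character vectors of tokens (recycled).
#' @param threshold Maximum normalised distance.
#' @return Logical vector.
#' @examples
#' tokens_equal("BRUNSWIK", "BRUNSWICK")  # TRUE, 1/9
#' tokens_equal("ST", "STREET")           # FALSE, 4/6
#' @export
tokens_equal <- function(a, b, threshold = 0.2) {
  d <- dl_distance(a, b)
  L <- pmax(nchar(as.character(a)), nchar(as.character(b)))
  ifelse(L == 0, TRUE, d / L <= threshold)
}

#' Needleman-Wunsch global alignment
#'
#' Aligns two symbol sequences globally, maximising
#' `match * n_match + mismatch * n_mismatch + gap * n_gap` under a linear
#' gap penalty. Ties in the traceback prefer the diagonal, making the
#' reported alignment deterministic.
#'
#' @param a,b Vectors of symbols (e.g. characters or tokens).
#' @param equal Comparator: a vectorised function of two symbols returning
#'   logical. Defaults to exact equality.
#' @param match,mismatch,gap Scoring parameters.
#' @return A list with `score` and `columns`, an integer matrix with one row
#'   per alignment column and 1-based indices into `a` and `b` (0 = gap).
#' @examples
#' nw_align(c("A", "B"), "B")$score  # 1 match + 1 gap = 0
#' @export
nw_align <- function(a, b, equal = `==`, match = 1, mismatch = -1, gap = -1) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) == 0 || length(b) == 0) {
    return(list(score = gap * (length(a) + length(b)),
                columns = cbind(a = c(seq_along(a), rep(0L, length(b))),
                                b = c(rep(0L, length(a)), seq_along(b)))))
  }
  eq <- outer(a, b, equal)
  res <- nw_align_eq_cpp(eq, match, mismatch, gap)
  colnames(res$columns) <- c("a", "b")
  res
}

#' Character-frequency cosine similarity
#'
#' Cosine of the character-count vectors of two strings over the alphabet
#' `A`-`Z`, `0`-`9` (spaces and punctuation are ignored). Returns 0 when
#' either string has no counted characters.
#'
#' @param a,b Single strings.
#' @return Similarity in `[0, 1]`.
#' @examples
#' char_cos("AB", "BA")  # 1: identical multisets
#' @export
char_cos <- function(a, b) {
  counts <- function(x) {
    ch <- strsplit(gsub("[^A-Z0-9]", "", toupper(x)), "", fixed = TRUE)[[1]]
    if (length(ch) == 0) return(NULL)
    table(ch)
  }
  ca <- counts(a); cb <- counts(b)
  if (is.null(ca) || is.null(cb)) return(0)
  keys <- union(names(ca), names(cb))
  va <- as.numeric(ca[keys]); va[is.na(va)] <- 0
  vb <- as.numeric(cb[keys]); vb[is.na(vb)] <- 0
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' Alignment summary score
#'
#' `S = M - 0.01 * I + 0.1 * F`, where `M` is the harmonic mean of the
#' fraction aligned on the input side and on the field side, `I` the number
#' of insertions opened inside the aligned region, and `F` the
#' character-frequency cosine similarity of the field and the matched text.
#'
#' @param M Harmonic mean of the two aligned percentages, in `[0, 1]`.
#' @param I Non-negative insertion count.
#' @param F Character-frequency cosine similarity in `[0, 1]`.
#' @return The score `S`.
#' @export
summary_score <- function(M, I, F) {
  M - 0.01 * I + 0.1 * F
}

# --- internal alignment machinery ------------------------------------------

# Replace unavailable (redacted) positions by spaces, preserving coordinates.
visible_string <- function(input, mask = NULL) {
  if (is.null(mask)) return(input)
  ch <- strsplit(input, "", fixed = TRUE)[[1]]
  ch[!mask] <- " "
  paste(ch, collapse = "")
}

# Word tokens ([A-Z0-9]+) with their 1-based start positions and lengths.
tokenize_pos <- function(s) {
  m <- gregexpr("[A-Z0-9]+", s)[[1]]
  if (m[1] == -1) {
    return(list(tok = character(), start = integer(), len = integer()))
  }
  list(tok = regmatches(s, gregexpr("[A-Z0-9]+", s))[[1]],
       start = as.integer(m),
       len = attr(m, "match.length"))
}

harmonic_mean2 <- function(x, y) {
  if (x <= 0 || y <= 0) return(0)
  2 * x * y / (x + y)
}

# Count maximal runs of gap columns strictly inside the matched region.
count_insertions <- function(cols, matched_rows) {
  if (length(matched_rows) == 0) return(0L)
  lo <- min(matched_rows); hi <- max(matched_rows)
  if (hi <= lo) return(0L)
  inside <- lo:hi
  gapcol <- cols[inside, 1] == 0L | cols[inside, 2] == 0L
  r <- rle(gapcol)
  sum(r$values)
}

positions_to_spans <- function(pos) {
  if (length(pos) == 0) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  pos <- sort(unique(pos))
  brk <- c(0, which(diff(pos) > 1), length(pos))
  out <- t(vapply(seq_len(length(brk) - 1), function(k) {
    c(pos[brk[k] + 1], pos[brk[k + 1]])
  }, integer(2)))
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

zero_alignment <- function(field, method = "token") {
  list(pct_input = 0, pct_field = 0, M = 0, I = 0L, F = 0, S = 0,
       method = method,
       spans = positions_to_spans(integer()),
       matched_input = "",
       field_residual = gsub("[^A-Z0-9 ]", "", field))
}

finalize_alignment <- function(al) {
  al$M <- harmonic_mean2(al$pct_input, al$pct_field)
  al$S <- summary_score(al$M, al$I, al$F)
  al
}

#' Token-based fuzzy alignment of a field into free text
#'
#' Both strings are tokenised on non-word characters and the token sequences
#' are globally aligned with [nw_align()] using [tokens_equal()] as the
#' comparator, so single typos inside long tokens still match. Matched
#' tokens contribute their character spans on the input side.
#'
#' @param input Free-text input (cleaned).
#' @param field Field value to locate.
#' @param mask Optional logical availability mask over `input` characters
#'   (positions already consumed by other fields are `FALSE`).
#' @return A field-alignment list: `pct_input`, `pct_field`, `M`, `I`, `F`,
#'   `S`, `method`, `spans` (matrix of 1-based inclusive input intervals),
#'   `matched_input`, `field_residual`.
#' @export
token_align <- function(input, field, mask = NULL) {
  vis <- visible_string(input, mask)
  ti <- tokenize_pos(vis)
  tf <- tokenize_pos(field)
  denom_in <- sum(ti$len); denom_f <- sum(tf$len)
  if (denom_in == 0 || denom_f == 0) return(zero_alignment(field, "token"))

  eq <- dl_ratio_matrix_cpp(ti$tok, tf$tok) <= 0.2
  res <- nw_align_eq_cpp(eq, 1, -1, -1)
  cols <- res$columns
  is_match <- cols[, 1] > 0 & cols[, 2] > 0 &
    eq[cbind(pmax(cols[, 1], 1L), pmax(cols[, 2], 1L))]
  mi <- cols[is_match, 1]; mf <- cols[is_match, 2]

  if (length(mi) == 0) return(zero_alignment(field, "token"))
  pos <- unlist(lapply(mi, function(k) seq(ti$start[k], length.out = ti$len[k])))
  al <- list(
    pct_input = sum(ti$len[mi]) / denom_in,
    pct_field = sum(tf$len[mf]) / denom_f,
    I = count_insertions(cols, which(is_match)),
    F = char_cos(field, paste(ti$tok[mi], collapse = "")),
    method = "token",
    spans = positions_to_spans(pos),
    matched_input = paste(ti$tok[mi], collapse = " "),
    field_residual = paste(tf$tok[-mf], collapse = " ")
  )
  finalize_alignment(al)
}

#' String-based alignment of a field into free text
#'
#' Character-level global alignment, essential where words are concatenated
#' (`"GREENBANK"` against `"GREEN BANK"`). After aligning, each token span
#' of the field is kept only if at least 80% of its characters aligned to
#' identical input characters (equivalent to the 0.2 distance threshold of
#' the token route); discarded spans contribute nothing.
#'
#' @inheritParams token_align
#' @return A field-alignment list (see [token_align()]), `method = "string"`.
#' @export
string_align <- function(input, field, mask = NULL) {
  vis <- visible_string(input, mask)
  ti <- tokenize_pos(vis)
  tf <- tokenize_pos(field)
  denom_in <- sum(ti$len); denom_f <- sum(tf$len)
  if (denom_in == 0 || denom_f == 0) return(zero_alignment(field, "string"))

  ca <- strsplit(vis, "", fixed = TRUE)[[1]]
  cb <- strsplit(field, "", fixed = TRUE)[[1]]
  eq <- outer(ca, cb, `==`)
  res <- nw_align_eq_cpp(eq, 1, -1, -1)
  cols <- res$columns
  matched <- cols[, 1] > 0 & cols[, 2] > 0 &
    eq[cbind(pmax(cols[, 1], 1L), pmax(cols[, 2], 1L))]
  word_b <- grepl("[A-Z0-9]", cb)
  matched_word <- matched & word_b[pmax(cols[, 2], 1L)]

  # 80% rule per field token span
  keep_rows <- logical(nrow(cols))
  kept_field_chars <- 0L
  residual <- character()
  for (k in seq_along(tf$tok)) {
    span <- seq(tf$start[k], length.out = tf$len[k])
    rows_k <- which(matched_word & cols[, 2] %in% span)
    if (length(rows_k) / tf$len[k] >= 0.8) {
      keep_rows[rows_k] <- TRUE
      kept_field_chars <- kept_field_chars + length(rows_k)
    } else {
      residual <- c(residual, tf$tok[k])
    }
  }
  if (!any(keep_rows)) return(zero_alignment(field, "string"))

  in_pos <- cols[keep_rows, 1]
  al <- list(
    pct_input = length(in_pos) / denom_in,
    pct_field = kept_field_chars / denom_f,
    I = count_insertions(cols, which(keep_rows)),
    F = char_cos(field, paste(ca[in_pos], collapse = "")),
    method = "string",
    spans = positions_to_spans(in_pos),
    matched_input = paste(ca[sort(in_pos)], collapse = ""),
    field_residual = paste(residual, collapse = " ")
  )
  finalize_alignment(al)
}

#' Best fuzzy occurrence of a field value inside free text
#'
#' Runs both the token-based and string-based alignment and returns
#' whichever has the higher summary score `S`; ties favour the token route.
#' An empty field yields a zero-metric alignment.
#'
#' @inheritParams token_align
#' @return A field-alignment list (see [token_align()]).
#' @examples
#' align_field("5/1 BRUNSWICK ROAD EDINBURGH", "BRUNSWICK ROAD")$pct_field
#' @export
align_field <- function(input, field, mask = NULL) {
  if (is.na(field) || !nzchar(field)) return(zero_alignment("", "token"))
  t_al <- token_align(input, field, mask)
  s_al <- string_align(input, field, mask)
  if (s_al$S > t_al$S) s_al else t_al
}
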