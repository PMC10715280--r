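# Independent oracles used to verify the compiled alignment kernels.

# Damerau-Levenshtein by the classic alphabet-indexed DP (unrestricted
# adjacent transpositions), written independently of the C++ kernel.
oracle_dl <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  if (n == 0) return(m)
  if (m == 0) return(n)
  inf <- n + m
  H <- matrix(0L, n + 2, m + 2)
  H[1, ] <- inf; H[, 1] <- inf
  H[2, 2:(m + 2)] <- 0:m
  H[2:(n + 2), 2] <- 0:n
  last_row <- integer(0)
  for (i in 1:n) {
    last_col <- 0L
    for (j in 1:m) {
      v <- unname(last_row[B[j]])
      i1 <- if (length(v) == 0 || is.na(v)) 0L else v
      j1 <- last_col
      cost <- 1L
      if (A[i] == B[j]) { cost <- 0L; last_col <- j }
      H[i + 2, j + 2] <- min(
        H[i + 1, j + 1] + cost,
        H[i + 1, j + 2] + 1L,
        H[i + 2, j + 1] + 1L,
        H[i1 + 1, j1 + 1] + (i - i1 - 1L) + 1L + (j - j1 - 1L))
    }
    last_row[A[i]] <- i
  }
  H[n + 2, m + 2]
}

# Brute-force definition of the distance: breadth-first search over string
# space using the four edit operations. Only feasible for tiny strings, but
# it depends on no recurrence at all.
oracle_dl_bfs <- function(a, b, max_d = 6) {
  if (a == b) return(0L)
  alphabet <- unique(strsplit(paste0(a, b, "A"), "")[[1]])
  edits1 <- function(s) {
    ch <- strsplit(s, "")[[1]]; n <- length(ch)
    out <- character(0)
    for (i in seq_len(n)) out <- c(out, paste(ch[-i], collapse = ""))
    for (i in seq_len(n)) for (x in alphabet) {
      if (x != ch[i]) {
        t <- ch; t[i] <- x; out <- c(out, paste(t, collapse = ""))
      }
    }
    for (i in 0:n) for (x in alphabet) {
      out <- c(out, paste(c(ch[seq_len(i)], x, ch[seq_len(n - i) + i]),
                          collapse = ""))
    }
    if (n >= 2) for (i in seq_len(n - 1)) {
      if (ch[i] != ch[i + 1]) {
        t <- ch; t[c(i, i + 1)] <- t[c(i + 1, i)]
        out <- c(out, paste(t, collapse = ""))
      }
    }
    unique(out)
  }
  frontier <- a
  seen <- paste0("k", a)
  for (d in seq_len(max_d)) {
    nxt <- character(0)
    for (s in frontier) {
      for (t in edits1(s)) {
        if (t == b) return(d)
        key <- paste0("k", t)
        if (!(key %in% seen) && abs(nchar(t) - nchar(b)) <= max_d - d) {
          seen <- c(seen, key)
          nxt <- c(nxt, t)
        }
      }
    }
    if (length(nxt) == 0) break
    frontier <- nxt
  }
  NA_integer_
}

# Needleman-Wunsch optimal score by exhaustive recursion over all monotone
# alignments (no DP table, no memoisation).
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  rec <- function(i, j) {
    if (i == 0) return(j * gap)
    if (j == 0) return(i * gap)
    max(rec(i - 1, j - 1) + (if (a[i] == b[j]) match else mismatch),
        rec(i - 1, j) + gap,
        rec(i, j - 1) + gap)
  }
  rec(length(a), length(b))
}

random_string <- function(len, alphabet = LETTERS[1:5]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
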