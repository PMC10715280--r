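#' Clean raw address text
#'
#' Uppercases, removes characters that are not common in address strings
#' (everything other than letters, digits, space, `-`, `/` and `,`),
#' collapses runs of whitespace, and trims. Cleaning is idempotent.
#'
#' @param x Character vector of raw address strings.
#' @return Character vector of cleaned strings. An input whose characters are
#'   all removed becomes the empty string, the pipeline's empty-input signal.
#' @examples
#' clean_address("5/1  Brunswick   Road!!")
#' @export
clean_address <- function(x) {
  x <- toupper(x)
  x <- gsub("[^A-Z0-9 ,/-]+", "", x)
  x <- gsub("\\s+", " ", x)
  x <- gsub(" ?, ?", ", ", x)   # normalise comma spacing
  trimws(x)
}

#' Default removal list for knowledge-based deletion
#'
#' Region words commonly present in free-text addresses but not used by the
#' gazetteer fields (counties and similar); extend or replace as needed.
#' A term is only ever removed when it does not occur as a region value in
#' the gazetteer itself.
#'
#' @return Character vector of terms.
#' @export
default_removal_terms <- function() {
  c("FIFE", "TAYSIDE", "ANGUS", "SCOTLAND", "PERTHSHIRE", "KINROSS-SHIRE",
    "MIDLOTHIAN", "LOTHIAN")
}

#' Knowledge-based completion and deletion
#'
#' Two fixes driven by knowledge inferred from the gazetteer: (1) when the
#' text names a child region (e.g. a dependent locality) but not its parent
#' (the post town it sits in), the parent is inserted directly after the
#' child; (2) region words that the gazetteer never uses (e.g. counties) are
#' deleted. Both steps are idempotent.
#'
#' @param x Character vector of cleaned address strings (see [clean_address()]).
#' @param subsumption A subsumption map from [build_subsumption_map()], or
#'   `NULL` to skip completion.
#' @param remove Character vector of candidate removal terms
#'   (default [default_removal_terms()]). Terms present in the gazetteer's
#'   `known_regions` are never removed.
#' @return Character vector of completed/pruned strings.
#' @examples
#' sm <- list(edges = tibble::tibble(child = "METHIL", parent = "LEVEN"),
#'            known_regions = c("METHIL", "LEVEN"))
#' complete_address("272 HIGH STREET, METHIL, KY8 3EQ", sm)
#' @export
complete_address <- function(x, subsumption = NULL,
                             remove = default_removal_terms()) {
  vapply(x, function(s) complete_one(s, subsumption, remove), character(1),
         USE.NAMES = FALSE)
}

complete_one <- function(s, subsumption, remove) {
  if (is.na(s) || !nzchar(s)) return(s)
  edges <- if (!is.null(subsumption)) subsumption$edges else NULL
  known <- if (!is.null(subsumption)) subsumption$known_regions else character()
  if (!is.null(edges) && nrow(edges) > 0) {
    # iterate so transitive chains (double dependent locality -> dependent
    # locality -> post town) resolve; the map is acyclic so this terminates
    for (pass in seq_len(nrow(edges) + 1L)) {
      changed <- FALSE
      for (k in seq_len(nrow(edges))) {
        child <- edges$child[k]; parent <- edges$parent[k]
        if (has_phrase(s, child) && !has_phrase(s, parent)) {
          s <- sub(phrase_regex(child), paste0(child, ", ", parent), s, perl = TRUE)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  for (term in setdiff(remove, known)) {
    if (has_phrase(s, term)) {
      s <- gsub(paste0(",? ?", phrase_regex(term)), "", s, perl = TRUE)
      s <- clean_address(s)
      s <- gsub("^, |, $", "", s)
    }
  }
  s
}

phrase_regex <- function(p) {
  paste0("(?<![A-Z0-9])", gsub("([][{}()+*^$|\\\\.?-])", "\\\\\\1", p),
         "(?![A-Z0-9])")
}

has_phrase <- function(s, p) {
  grepl(phrase_regex(p), s, perl = TRUE)
}

#' Parse structural hints from an address string
#'
#' Extracts, by regular expression and dictionary lookup, the three elements
#' that tend to be well formatted in free text and that drive blocking:
#' postcode (last match of the UK postcode pattern, normalised to
#' `"OUTCODE INCODE"`), post town (longest known town occurring in the text)
#' and thoroughfare (longest known thoroughfare occurring). Hints are never
#' guessed: each is either a substring of the input or `NA`.
#'
#' @param x Character vector of cleaned address strings.
#' @param known_towns,known_thoroughfares Character vectors of values drawn
#'   from the gazetteer.
#' @return A tibble with columns `address`, `postcode`, `post_town`,
#'   `thoroughfare` (character, `NA` where absent).
#' @export
parse_hints <- function(x, known_towns = character(),
                        known_thoroughfares = character()) {
  pc_re <- "(?<![A-Z0-9])([A-Z]{1,2}[0-9][0-9A-Z]?) ?([0-9][A-Z]{2})(?![A-Z0-9])"
  postcode <- vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    m <- gregexpr(pc_re, s, perl = TRUE)[[1]]
    if (m[1] == -1) return(NA_character_)
    last <- regmatches(s, gregexpr(pc_re, s, perl = TRUE))[[1]]
    last <- last[length(last)]
    sub(pc_re, "\\1 \\2", last, perl = TRUE)
  }, character(1), USE.NAMES = FALSE)
  longest_known <- function(s, pool) {
    if (is.na(s) || !nzchar(s) || length(pool) == 0) return(NA_character_)
    hit <- pool[vapply(pool, function(p) has_phrase(s, p), logical(1))]
    if (length(hit) == 0) return(NA_character_)
    hit[which.max(nchar(hit))]
  }
  tibble::tibble(
    address = x,
    postcode = postcode,
    post_town = vapply(x, longest_known, character(1), pool = known_towns,
                       USE.NAMES = FALSE),
    thoroughfare = vapply(x, longest_known, character(1),
                          pool = known_thoroughfares, USE.NAMES = FALSE)
  )
}
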