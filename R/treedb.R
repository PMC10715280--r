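#' Convert a gazetteer into a layered tree
#'
#' Each tree layer corresponds to one address field, in a fixed order; at
#' every node the parent's records are partitioned by that layer's value
#' (an empty value forms its own pass-through child). After the last layer
#' any still-unresolved group is split by identifier, so each leaf holds
#' exactly one gazetteer record.
#'
#' @param records Gazetteer tibble.
#' @param layer_order Character vector of field names, first layer first.
#' @return The root node: a nested list with elements `field`, `value`,
#'   `rows` (row indices into `records`) and `children` (`NULL` at leaves).
#' @export
build_tree <- function(records, layer_order = primary_layers()) {
  root <- list(field = NULL, value = NULL, rows = seq_len(nrow(records)))
  root$children <- split_children(records, root$rows, layer_order, 1L)
  root
}

split_children <- function(records, rows, layers, li) {
  if (li > length(layers)) {
    if (length(rows) == 1) return(NULL)
    return(lapply(rows, function(r) {
      list(field = "uprn", value = records$uprn[r], rows = r, children = NULL)
    }))
  }
  vals <- records[[layers[li]]][rows]
  groups <- split(rows, vals)  # alphabetical, hence deterministic
  lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    node <- list(field = layers[li], value = names(groups)[k], rows = g)
    node$children <- split_children(records, g, layers, li + 1L)
    node
  })
}

tree_leaves <- function(node) {
  if (is.null(node$children)) return(1L)
  sum(vapply(node$children, tree_leaves, integer(1)))
}

redact_mask <- function(mask, spans) {
  if (nrow(spans) > 0) {
    for (k in seq_len(nrow(spans))) mask[spans[k, 1]:spans[k, 2]] <- FALSE
  }
  mask
}

best_child <- function(children, input, mask) {
  best <- NULL
  for (ch in children) {
    if (!nzchar(ch$value)) next
    al <- align_field(input, ch$value, mask)
    if (is.null(best) || al$S > best$al$S) best <- list(node = ch, al = al)
  }
  best
}

#' Depth-first blocking descent
#'
#' Narrows the search to a local area: with a parsed postcode, one step down
#' the postcode-first tree; otherwise (or on request) two steps down the
#' town/thoroughfare tree. At each step every child name is aligned against
#' the (progressively redacted) input and the child with the best summary
#' score is chosen. Blocking fails - the address is unmatchable at this
#' stage - when the best child's matched fraction (`pct_field`) falls below
#' `min_match`.
#'
#' @param db A linkage database from [build_linkage_db()].
#' @param input Cleaned, completed input address string.
#' @param hints One-row hint tibble from [parse_hints()].
#' @param min_match Floor on the chosen child's matched name fraction
#'   (default 0.5).
#' @param route `"auto"` tries postcode first, then town/thoroughfare;
#'   `"town"` forces the two-step secondary descent.
#' @return `NULL` on blocking failure, else a list with `route`, the chosen
#'   subtree `node`, the DFS `alignments` (named by field) and the redacted
#'   input `mask`.
#' @export
dfs_block <- function(db, input, hints, min_match = 0.5,
                      route = c("auto", "town")) {
  route <- match.arg(route)
  mask <- rep(TRUE, nchar(input))
  if (route == "auto" && !is.na(hints$postcode[1])) {
    res <- best_child(db$primary$children, input, mask)
    if (!is.null(res) && res$al$pct_field >= min_match) {
      return(list(route = "postcode", node = res$node,
                  alignments = list(POSTCODE = res$al),
                  mask = redact_mask(mask, res$al$spans)))
    }
  }
  if (!is.na(hints$post_town[1])) {
    r1 <- best_child(db$secondary$children, input, mask)
    if (!is.null(r1) && r1$al$pct_field >= min_match) {
      m1 <- redact_mask(mask, r1$al$spans)
      r2 <- best_child(r1$node$children, input, m1)
      if (!is.null(r2) && r2$al$pct_field >= min_match) {
        return(list(route = "town", node = r2$node,
                    alignments = list(POST_TOWN = r1$al, THOROUGHFARE = r2$al),
                    mask = redact_mask(m1, r2$al$spans)))
      }
    }
  }
  NULL
}

#' Breadth-first candidate scoring under a blocked subtree
#'
#' Walks every branch below the blocked node. At each level the child's name
#' is aligned against that branch's redacted input; newly aligned positions
#' are redacted before recursing, so one candidate's per-field alignments
#' can never reuse the same input characters. Each leaf yields one candidate
#' alignment set, with the DFS-stage alignments carried in.
#'
#' @param node Subtree root (from [dfs_block()]).
#' @param input Cleaned input string.
#' @param mask Logical availability mask over `input` characters.
#' @param records The gazetteer tibble the tree was built from.
#' @param base_alignments Named list of alignments already made during the
#'   descent.
#' @return List of candidates; each has `row`, `uprn`, `canonical_uprn`,
#'   `record` (named list of field values), `alignments` (named by field),
#'   `input`, and the final `mask`.
#' @export
bfs_match <- function(node, input, mask, records, base_alignments = list()) {
  schema <- address_fields()
  out <- vector("list", length(node$rows))
  n_out <- 0L
  recurse <- function(nd, mask, acc) {
    if (is.null(nd$children)) {
      row <- nd$rows
      n_out <<- n_out + 1L
      out[[n_out]] <<- list(
        row = row, uprn = records$uprn[row],
        canonical_uprn = records$canonical_uprn[row],
        record = lapply(setNames(schema, schema),
                        function(f) records[[f]][row]),
        alignments = acc, input = input, mask = mask)
      return(invisible(NULL))
    }
    for (ch in nd$children) {
      if (identical(ch$field, "uprn")) {
        recurse(ch, mask, acc)
      } else if (!nzchar(ch$value)) {
        acc2 <- acc
        acc2[[ch$field]] <- zero_alignment("")
        recurse(ch, mask, acc2)
      } else {
        al <- align_field(input, ch$value, mask)
        acc2 <- acc
        acc2[[ch$field]] <- al
        recurse(ch, redact_mask(mask, al$spans), acc2)
      }
    }
  }
  recurse(node, mask, base_alignments)
  out[seq_len(n_out)]
}

#' Build the full linkage database
#'
#' Augments the gazetteer (unless `augment = FALSE`), builds the two
#' blocking trees (postcode-first and town/thoroughfare-first), the
#' region-subsumption map, and the hint dictionaries.
#'
#' @param gazetteer Gazetteer tibble from [load_gazetteer()].
#' @param augment Apply [augment_gazetteer()] first?
#' @param rules,aliases,abbreviations Passed to [augment_gazetteer()].
#' @return An object of class `linkage_db`.
#' @export
build_linkage_db <- function(gazetteer, augment = TRUE,
                             rules = augmentation_rules(), aliases = NULL,
                             abbreviations = default_abbreviations()) {
  gaz <- if (augment) {
    augment_gazetteer(gazetteer, rules = rules, aliases = aliases,
                      abbreviations = abbreviations)
  } else {
    gazetteer
  }
  db <- list(
    gazetteer = gaz,
    primary = build_tree(gaz, primary_layers()),
    secondary = build_tree(gaz, secondary_layers()),
    subsumption = build_subsumption_map(gaz),
    known_towns = sort(unique(gaz$POST_TOWN[nzchar(gaz$POST_TOWN)])),
    known_thoroughfares = sort(unique(gaz$THOROUGHFARE[nzchar(gaz$THOROUGHFARE)]))
  )
  class(db) <- "linkage_db"
  db
}

#' @export
print.linkage_db <- function(x, ...) {
  n_aug <- sum(x$gazetteer$is_augmented)
  cat("<linkage_db>\n",
      " records:   ", nrow(x$gazetteer) - n_aug, " (+", n_aug,
      " augmented variants)\n",
      " postcodes: ", length(x$primary$children), "\n",
      " towns:     ", length(x$known_towns), "\n", sep = "")
  invisible(x)
}
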