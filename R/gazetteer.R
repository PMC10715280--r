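#' Load a gazetteer table
#'
#' Reads a delimited file (or accepts a data frame) with one row per
#' property: a unique identifier column `uprn` plus the 11 address fields of
#' the schema. Values are cleaned (uppercased, irregular characters removed,
#' whitespace normalised) and empty cells become empty strings.
#'
#' @param path Path to a delimited file (delimiter auto-detected by
#'   [readr::read_delim()] from `,`/tab), or a data frame already in memory.
#' @param schema Character vector of the 11 expected field columns.
#' @return A gazetteer tibble with columns `uprn`, the 11 schema fields,
#'   `is_augmented` (all `FALSE`) and `canonical_uprn` (equal to `uprn`).
#' @export
load_gazetteer <- function(path, schema = address_fields()) {
  df <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_character()))
  }
  names(df) <- gsub(" ", "_", toupper(names(df)))
  names(df)[names(df) == "UPRN"] <- "uprn"
  missing <- setdiff(c("uprn", schema), names(df))
  if (length(missing) > 0) {
    stop("gazetteer is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, c("uprn", schema)]
  df$uprn <- as.character(df$uprn)
  if (any(is.na(df$uprn) | !nzchar(df$uprn))) {
    stop("gazetteer contains empty identifiers", call. = FALSE)
  }
  for (f in schema) {
    v <- clean_address(as.character(df[[f]]))
    v[is.na(v)] <- ""
    df[[f]] <- v
  }
  dup <- df$uprn[duplicated(df$uprn)]
  if (length(dup) > 0) {
    grp <- df[df$uprn %in% dup, ]
    distinct_n <- nrow(dplyr::distinct(grp))
    if (distinct_n > length(unique(dup))) {
      stop("duplicate identifier(s) with differing fields: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
    df <- dplyr::distinct(df)
  }
  df$is_augmented <- FALSE
  df$canonical_uprn <- df$uprn
  tibble::as_tibble(df)
}

#' Render a gazetteer record as free text
#'
#' Concatenates the non-empty fields in natural postal order, separated by
#' commas, with the building number prefixed to its thoroughfare. The
#' `"slash"` style writes flats as `"number/flat"` (e.g. `"5/1 BRUNSWICK
#' ROAD"`) instead of `"FLAT 1, 5 BRUNSWICK ROAD"`.
#'
#' @param records Gazetteer tibble (one or more rows).
#' @param style `"comma"` (default) or `"slash"`.
#' @return Character vector of rendered addresses, one per row.
#' @export
render_address <- function(records, style = c("comma", "slash")) {
  style <- match.arg(style)
  vapply(seq_len(nrow(records)), function(i) {
    r <- as.list(records[i, ])
    sub_b <- r$SUB_BUILDING_NAME
    num <- r$BUILDING_NUMBER
    if (style == "slash" && nzchar(sub_b) && nzchar(num) &&
        grepl("^FLAT [A-Z0-9]+$", sub_b)) {
      num <- paste0(num, "/", sub("^FLAT ", "", sub_b))
      sub_b <- ""
    }
    street <- trimws(paste(num, r$THOROUGHFARE))
    parts <- c(r$ORGANISATION_NAME, r$DEPARTMENT_NAME, sub_b,
               r$BUILDING_NAME, street, r$DEPENDENT_THOROUGHFARE,
               r$DOUBLE_DEPENDENT_LOCALITY, r$DEPENDENT_LOCALITY,
               r$POST_TOWN, r$POSTCODE)
    paste(parts[nzchar(parts)], collapse = ", ")
  }, character(1))
}

#' Default abbreviation table
#'
#' Street-type abbreviations used both for gazetteer augmentation (deriving
#' the abbreviated alternative forms of standard addresses) and by the
#' synthetic corruption generator.
#'
#' @return Tibble with columns `full` and `abbr`.
#' @export
default_abbreviations <- function() {
  tibble::tribble(
    ~full,      ~abbr,
    "ROAD",     "RD",
    "STREET",   "ST",
    "AVENUE",   "AVE",
    "DRIVE",    "DR",
    "PLACE",    "PL",
    "CRESCENT", "CRES",
    "GARDENS",  "GDNS",
    "TERRACE",  "TERR",
    "COURT",    "CT"
  )
}

#' Names of the registered augmentation rules
#' @return Character vector of rule names accepted by [augment_gazetteer()].
#' @export
augmentation_rules <- function() {
  c("abbreviations", "saint_forms", "flat_formats", "number_ranges")
}

#' Augment a gazetteer with alternative address forms
#'
#' Derives alternative renderings from the standard records so that
#' non-standard inputs can match textually: street-type abbreviations
#' (`ROAD` -> `RD`), saint forms (leading `ST` -> `SAINT`), flat formats
#' (`FLAT 1` + number `5` -> `5/1` and `5F1`, and back), numeric range
#' expansion (`1-3` -> `1`, `2`, `3`), plus optional local-knowledge aliases.
#' Variants keep `canonical_uprn` pointing at their source record and never
#' receive new identifiers. Variants whose rendered text collides with a
#' different property's record are dropped (consistency rule); the dropped
#' renderings are attached as attribute `"dropped"`.
#'
#' @param records Gazetteer tibble from [load_gazetteer()].
#' @param rules Subset of [augmentation_rules()] to apply.
#' @param aliases Optional tibble `(alias_text, uprn)` encoding local
#'   knowledge (a free-text name known to refer to one property).
#' @param abbreviations Abbreviation table (`full`, `abbr`).
#' @return Gazetteer tibble: all input rows plus augmented variants
#'   (`is_augmented = TRUE`).
#' @export
augment_gazetteer <- function(records, rules = augmentation_rules(),
                              aliases = NULL,
                              abbreviations = default_abbreviations()) {
  stopifnot(all(rules %in% augmentation_rules()))
  schema <- address_fields()
  variants <- list()
  add_variant <- function(row) variants[[length(variants) + 1L]] <<- row

  for (i in seq_len(nrow(records))) {
    r <- records[i, ]

    if ("abbreviations" %in% rules) {
      v <- r
      for (f in c("THOROUGHFARE", "DEPENDENT_THOROUGHFARE")) {
        for (k in seq_len(nrow(abbreviations))) {
          v[[f]] <- gsub(paste0("\\b", abbreviations$full[k], "\\b"),
                         abbreviations$abbr[k], v[[f]])
        }
      }
      if (!identical(v, r)) add_variant(v)
    }

    if ("saint_forms" %in% rules) {
      for (f in c("THOROUGHFARE", "BUILDING_NAME", "ORGANISATION_NAME")) {
        if (grepl("^ST\\.? [A-Z]", r[[f]])) {
          v <- r
          v[[f]] <- sub("^ST\\.? ", "SAINT ", v[[f]])
          add_variant(v)
        }
      }
    }

    if ("flat_formats" %in% rules) {
      sb <- r$SUB_BUILDING_NAME; num <- r$BUILDING_NUMBER
      if (grepl("^FLAT [A-Z0-9]+$", sb) && nzchar(num)) {
        fl <- sub("^FLAT ", "", sb)
        v <- r; v$BUILDING_NUMBER <- paste0(num, "/", fl); v$SUB_BUILDING_NAME <- ""
        add_variant(v)
        v <- r; v$BUILDING_NUMBER <- paste0(num, "F", fl); v$SUB_BUILDING_NAME <- ""
        add_variant(v)
      } else if (grepl("^([0-9]+)/([A-Z0-9]+)$", num)) {
        v <- r
        v$SUB_BUILDING_NAME <- paste("FLAT", sub("^[0-9]+/", "", num))
        v$BUILDING_NUMBER <- sub("/.*$", "", num)
        add_variant(v)
      }
    }

    if ("number_ranges" %in% rules &&
        grepl("^[0-9]+-[0-9]+$", r$BUILDING_NUMBER)) {
      lo <- as.integer(sub("-.*$", "", r$BUILDING_NUMBER))
      hi <- as.integer(sub("^.*-", "", r$BUILDING_NUMBER))
      if (!is.na(lo) && !is.na(hi) && hi > lo && hi - lo <= 10) {
        for (k in lo:hi) {
          v <- r; v$BUILDING_NUMBER <- as.character(k)
          add_variant(v)
        }
      }
    }
  }

  if (!is.null(aliases) && nrow(aliases) > 0) {
    bad <- setdiff(aliases$uprn, records$uprn)
    if (length(bad) > 0) {
      stop("alias table references unknown identifier(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (k in seq_len(nrow(aliases))) {
      src <- records[match(aliases$uprn[k], records$uprn), ]
      v <- src
      for (f in schema) v[[f]] <- ""
      v$BUILDING_NAME <- clean_address(aliases$alias_text[k])
      v$POSTCODE <- src$POSTCODE
      v$POST_TOWN <- src$POST_TOWN
      add_variant(v)
    }
  }

  if (length(variants) == 0) {
    attr(records, "dropped") <- character()
    return(records)
  }
  var_tbl <- dplyr::bind_rows(variants)
  var_tbl$is_augmented <- TRUE
  var_tbl$canonical_uprn <- var_tbl$uprn

  # consistency: never create a rendering that already exists (conflicting
  # property: logged drop; same property: silently redundant), and collapse
  # identical variants derived via different rule paths
  base_txt <- render_address(records)
  var_txt <- render_address(var_tbl)
  in_base <- match(var_txt, base_txt)
  collide_base <- !is.na(in_base)
  conflict_base <- collide_base &
    records$canonical_uprn[replace(in_base, is.na(in_base), 1L)] !=
      var_tbl$canonical_uprn
  first_idx <- match(var_txt, var_txt)
  dup_var <- first_idx != seq_along(var_txt)
  conflict_var <- dup_var &
    var_tbl$canonical_uprn[first_idx] != var_tbl$canonical_uprn
  keep <- !collide_base & !dup_var
  dropped <- unique(var_txt[(conflict_base | conflict_var)])
  out <- dplyr::bind_rows(records, var_tbl[keep, ])
  attr(out, "dropped") <- dropped
  out
}

#' Report duplicated renderings across distinct properties
#'
#' Groups records whose rendered full-address text is identical while their
#' canonical identifiers differ. An empty report means the (augmented)
#' gazetteer is consistent.
#'
#' @param records Gazetteer tibble.
#' @return Tibble `(rendered, n_records, uprns)`, one row per duplicate group.
#' @export
check_consistency <- function(records) {
  txt <- render_address(records)
  tibble::tibble(rendered = txt,
                 canonical = records$canonical_uprn) |>
    dplyr::group_by(.data$rendered) |>
    dplyr::summarise(n_records = dplyr::n(),
                     n_canonical = dplyr::n_distinct(.data$canonical),
                     uprns = paste(unique(.data$canonical), collapse = ";"),
                     .groups = "drop") |>
    dplyr::filter(.data$n_canonical > 1) |>
    dplyr::select("rendered", "n_records", "uprns")
}

#' Build the region-subsumption map
#'
#' Learns, from the gazetteer, which child region sits inside which parent
#' region (dependent locality within post town; double dependent locality
#' within dependent locality). Conflicting parents for a child are resolved
#' by majority, with conflicts reported in the `conflicts` element.
#'
#' @param records Gazetteer tibble.
#' @return A list with `edges` (tibble `child`, `parent`, `n`),
#'   `known_regions` (all distinct non-empty region values) and `conflicts`
#'   (tibble of discarded minority edges).
#' @export
build_subsumption_map <- function(records) {
  pairs <- dplyr::bind_rows(
    tibble::tibble(child = records$DEPENDENT_LOCALITY,
                   parent = records$POST_TOWN),
    tibble::tibble(child = records$DOUBLE_DEPENDENT_LOCALITY,
                   parent = records$DEPENDENT_LOCALITY)
  )
  pairs <- dplyr::filter(pairs, nzchar(.data$child), nzchar(.data$parent))
  known <- unique(unlist(lapply(region_fields(),
                                function(f) records[[f]][nzchar(records[[f]])])))
  if (nrow(pairs) == 0) {
    return(list(edges = tibble::tibble(child = character(),
                                       parent = character(),
                                       n = integer()),
                known_regions = known %||% character(),
                conflicts = tibble::tibble(child = character(),
                                           parent = character(),
                                           n = integer())))
  }
  counts <- dplyr::count(pairs, .data$child, .data$parent, name = "n")
  edges <- counts |>
    dplyr::group_by(.data$child) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$parent, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  conflicts <- dplyr::anti_join(counts, edges, by = c("child", "parent"))
  # guard against cycles (a region subsuming itself transitively)
  edges <- dplyr::filter(edges, .data$child != .data$parent)
  list(edges = edges, known_regions = known, conflicts = conflicts)
}
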