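#' Corruption profile for synthetic inputs
#'
#' Per-operation rates with which the generator perturbs a rendered address,
#' reproducing the input-variation taxonomy seen in register free text:
#' typographical errors, street-type abbreviations, flat-format flips
#' (`"FLAT 1, 5"` vs `"5/1"`), wrong postcodes, omitted post towns, county
#' insertions, and inputs that are genuinely absent from, or too broad for,
#' the gazetteer. Defaults anchor to observed real-data shares where these
#' are known (abbreviations ~0.31 of inputs; 2.4% not in database, 0.6% too
#' broad); rates with no observed counterpart default to a plausible 0.1.
#'
#' @param typo,abbreviation,flat_flip,wrong_postcode,locality_dropout,county_insertion,not_in_db,too_broad
#'   Rates in `[0, 1]`, each applied independently.
#' @return A named list of class `corruption_profile`.
#' @export
corruption_profile <- function(typo = 0.1, abbreviation = 0.3,
                               flat_flip = 0.25, wrong_postcode = 0.01,
                               locality_dropout = 0.1,
                               county_insertion = 0.1,
                               not_in_db = 0.024, too_broad = 0.006) {
  p <- list(typo = typo, abbreviation = abbreviation, flat_flip = flat_flip,
            wrong_postcode = wrong_postcode,
            locality_dropout = locality_dropout,
            county_insertion = county_insertion,
            not_in_db = not_in_db, too_broad = too_broad)
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1))
  class(p) <- "corruption_profile"
  p
}

# Name pools. Deliberately disjoint between towns / localities / street
# stems / organisations so a zero-corruption rendering is unambiguous, and
# all postcodes use the reserved fake "ZZ" outcodes so fixtures can never
# collide with a real address.
syn_towns <- function() {
  c("ABERKYLE", "DUNVALE", "INCHBERRY", "KIRKFELL", "MOSSBRAE",
    "STRATHOLM", "GLENDOON", "NETHERWICK")
}
syn_localities <- function() {
  c("MILLHAVEN", "FERNLEA", "CRAIGDEN", "BIRCHWORTH", "EASTER HOWE",
    "WESTER HOWE", "LADYFIELD", "THORNCROFT", "REDSHAW", "OXGANG",
    "QUARRYHEAD", "SALTWELL", "HARELAW", "MUIRTON GREEN", "PITDARG",
    "COLDENHAUGH")
}
syn_street_stems <- function() {
  c("BRUNSWICK", "ALDERBANK", "CRAIGMOUNT", "ROWANTREE", "HOLLYBUSH",
    "MAYFIELD", "GRANGE", "STATION", "CHURCHILL", "BALGREEN", "CORSTON",
    "DALKEITH", "ELMVIEW", "FOUNTAIN", "GILMERTON", "HAWTHORNDEN",
    "IVYBANK", "JUNIPER", "KINGSKNOWE", "LARCHFIELD", "MERCHISTON",
    "NEWBATTLE", "ORCHARDFIELD", "PENTLAND", "QUEENSFERRY", "RAVELSTON",
    "SILVERKNOWE", "TORPHIN", "ULSTER", "VIEWFORTH", "WARRENDER",
    "SAUGHTON", "BLACKFORD", "CANAAN", "DREGHORN", "FAIRMILE",
    "GREENBANK", "HERMITAGE", "INVERLEITH", "LIBERTON")
}
syn_street_types <- function() {
  c("ROAD", "STREET", "AVENUE", "DRIVE", "PLACE", "CRESCENT", "GARDENS",
    "TERRACE", "COURT")
}
syn_orgs <- function() {
  c("ROSELEA CARE HOME", "THE WILLOWS NURSING HOME", "BRAESIDE LODGE",
    "HILLCREST RESIDENTIAL HOME", "SUNNYBANK HOUSE", "WOODLANDS SURGERY",
    "HARBOUR PHARMACY", "OLD MILL BAKERY", "ANCHOR GARAGE",
    "FAIRWAYS HOTEL", "GLEBE DENTAL PRACTICE", "MEADOWBANK DAY CENTRE")
}

#' Generate a synthetic UK-style gazetteer
#'
#' Deterministically (under `seed`) builds `n` property records with
#' plausible structure: towns with dependent localities, streets grouped
#' into shared postcodes (reserved fake `ZZ` outcodes), building numbers,
#' and configurable shares of flats and organisation names.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param p_flat Share of records that are flats (sub-building `FLAT k`).
#' @param p_org Share of records carrying an organisation name. Raise this
#'   to emulate care-home-heavy sampling.
#' @return Gazetteer tibble in [load_gazetteer()] layout.
#' @export
make_toy_gazetteer <- function(n = 500, seed = 1, p_flat = 0.25,
                               p_org = 0.12) {
  stopifnot(n >= 1)
  set.seed(seed)
  schema <- address_fields()
  n_towns <- max(2L, min(length(syn_towns()), ceiling(n / 150)))
  towns <- syn_towns()[seq_len(n_towns)]
  locs <- matrix(syn_localities()[seq_len(2 * n_towns)], nrow = n_towns)

  n_streets <- max(2L, ceiling(n / 8))
  stems <- syn_street_stems()
  street_name <- character(n_streets)
  street_town <- character(n_streets)
  street_loc <- character(n_streets)
  for (s in seq_len(n_streets)) {
    stem <- stems[(s - 1) %% length(stems) + 1]
    type <- syn_street_types()[(s - 1) %/% length(stems) %% 9 + 1]
    street_name[s] <- paste(stem, type)
    ti <- sample.int(n_towns, 1)
    street_town[s] <- towns[ti]
    street_loc[s] <- if (runif(1) < 0.5) locs[ti, sample.int(2, 1)] else ""
  }

  # postcodes: each street split into runs of ~4 properties, unique incodes
  rec_street <- sort(sample.int(n_streets, n, replace = TRUE))
  out <- tibble::tibble(uprn = sprintf("U%06d", seq_len(n)))
  for (f in schema) out[[f]] <- ""
  numbers <- integer(n)
  for (s in unique(rec_street)) {
    idx <- which(rec_street == s)
    numbers[idx] <- seq_along(idx)
  }
  out$BUILDING_NUMBER <- as.character(numbers)
  out$THOROUGHFARE <- street_name[rec_street]
  out$POST_TOWN <- street_town[rec_street]
  out$DEPENDENT_LOCALITY <- street_loc[rec_street]

  letters24 <- setdiff(LETTERS, c("I", "O"))
  incode_pool <- as.vector(outer(0:9, as.vector(outer(letters24, letters24,
                                                      paste0)),
                                 paste0))
  town_outcode <- setNames(paste0("ZZ", seq_len(n_towns)), towns)
  # one postcode per run of ~4 neighbouring properties on a street; incodes
  # drawn without replacement within each town, so postcodes are unique per
  # (street, group) by construction
  grp <- integer(n)
  for (s in unique(rec_street)) {
    idx <- which(rec_street == s)
    grp[idx] <- ceiling(seq_along(idx) / 4)
  }
  gkey <- paste0(rec_street, "_", grp)
  pc <- character(n)
  for (tw in towns) {
    sel <- out$POST_TOWN == tw
    if (!any(sel)) next
    keys <- unique(gkey[sel])
    codes <- sample(incode_pool, length(keys))
    pc[sel] <- paste(town_outcode[tw], codes[match(gkey[sel], keys)])
  }
  out$POSTCODE <- pc

  is_flat <- runif(n) < p_flat
  out$SUB_BUILDING_NAME[is_flat] <-
    paste("FLAT", sample(1:4, sum(is_flat), replace = TRUE))
  is_org <- runif(n) < p_org
  out$ORGANISATION_NAME[is_org] <-
    sample(syn_orgs(), sum(is_org), replace = TRUE)

  out$is_augmented <- FALSE
  out$canonical_uprn <- out$uprn
  out
}

apply_typo <- function(token) {
  ops <- c("insert", "delete", "substitute", "transpose")
  op <- sample(ops, 1)
  ch <- strsplit(token, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (op == "insert") {
    pos <- sample.int(n + 1, 1)
    ch <- append(ch, sample(LETTERS, 1), after = pos - 1)
  } else if (op == "delete") {
    ch <- ch[-sample.int(n, 1)]
  } else if (op == "substitute") {
    pos <- sample.int(n, 1)
    ch[pos] <- sample(setdiff(LETTERS, ch[pos]), 1)
  } else {
    if (n < 2) return(token)
    pos <- sample.int(n - 1, 1)
    if (ch[pos] == ch[pos + 1]) return(apply_typo(token))
    ch[c(pos, pos + 1)] <- ch[c(pos + 1, pos)]
  }
  paste(ch, collapse = "")
}

#' Corrupt one record into a free-text input
#'
#' Renders the record and applies each enabled corruption with its profile
#' rate. `not_in_db` fabricates an address absent from the gazetteer (an
#' out-of-range building number on a real street); `too_broad` renders the
#' street without its premise elements. Both carry the matching truth label.
#'
#' @param record One gazetteer row.
#' @param profile A [corruption_profile()].
#' @param gazetteer The full gazetteer (used to fabricate out-of-database
#'   numbers).
#' @return List with `address`, `uprn` (`NA` when not matchable) and `label`
#'   (`MATCH`, `NOT_IN_DB` or `TOO_BROAD`).
#' @export
corrupt_address <- function(record, profile = corruption_profile(),
                            gazetteer = NULL) {
  if (runif(1) < profile$not_in_db) {
    fake <- record
    street_nums <- if (!is.null(gazetteer)) {
      suppressWarnings(as.integer(
        gazetteer$BUILDING_NUMBER[gazetteer$THOROUGHFARE == record$THOROUGHFARE]))
    } else {
      as.integer(record$BUILDING_NUMBER)
    }
    top <- max(c(0L, street_nums), na.rm = TRUE)
    fake$BUILDING_NUMBER <- as.character(top + sample(50:99, 1))
    fake$SUB_BUILDING_NAME <- ""
    fake$ORGANISATION_NAME <- ""
    return(list(address = render_address(fake), uprn = NA_character_,
                label = "NOT_IN_DB"))
  }
  if (runif(1) < profile$too_broad) {
    broad <- record
    for (f in c("ORGANISATION_NAME", "DEPARTMENT_NAME", "SUB_BUILDING_NAME",
                "BUILDING_NAME", "BUILDING_NUMBER")) {
      broad[[f]] <- ""
    }
    return(list(address = render_address(broad), uprn = NA_character_,
                label = "TOO_BROAD"))
  }

  style <- if (nzchar(record$SUB_BUILDING_NAME) &&
               runif(1) < profile$flat_flip) "slash" else "comma"
  drop_town <- nzchar(record$DEPENDENT_LOCALITY) &&
    runif(1) < profile$locality_dropout
  rec <- record
  if (drop_town) rec$POST_TOWN <- ""
  s <- render_address(rec, style = style)

  if (runif(1) < profile$abbreviation) {
    ab <- default_abbreviations()
    for (k in seq_len(nrow(ab))) {
      s <- gsub(paste0("\\b", ab$full[k], "\\b"), ab$abbr[k], s)
    }
  }
  if (runif(1) < profile$typo) {
    tk <- tokenize_pos(s)
    elig <- which(nchar(tk$tok) >= 5 & grepl("^[A-Z]+$", tk$tok))
    if (length(elig) > 0) {
      k <- elig[sample.int(length(elig), 1)]
      s <- paste0(substr(s, 1, tk$start[k] - 1), apply_typo(tk$tok[k]),
                  substr(s, tk$start[k] + tk$len[k], nchar(s)))
    }
  }
  if (runif(1) < profile$wrong_postcode && nzchar(record$POSTCODE)) {
    pcs <- strsplit(record$POSTCODE, "", fixed = TRUE)[[1]]
    inc <- (nchar(record$POSTCODE) - 2):nchar(record$POSTCODE)
    pos <- sample(inc, 1)
    repl <- if (grepl("[0-9]", pcs[pos])) {
      sample(setdiff(as.character(0:9), pcs[pos]), 1)
    } else {
      sample(setdiff(LETTERS, pcs[pos]), 1)
    }
    wrong <- record$POSTCODE
    substr(wrong, pos, pos) <- repl
    s <- sub(record$POSTCODE, wrong, s, fixed = TRUE)
  }
  if (runif(1) < profile$county_insertion && nzchar(record$POSTCODE)) {
    county <- sample(c("FIFE", "TAYSIDE", "ANGUS"), 1)
    s <- sub(paste0(", ", record$POSTCODE), paste0(", ", county, ", ",
                                                   record$POSTCODE),
             s, fixed = TRUE)
  }
  list(address = s, uprn = record$uprn, label = "MATCH")
}

#' Generate a matching benchmark
#'
#' Draws `n_inputs` records stratified across postcodes (every postcode
#' represented before any is repeated), corrupts each rendering under
#' `profile`, and returns the inputs and truth annotations in the pipeline's
#' formats. Deterministic under `seed`.
#'
#' @param gazetteer Gazetteer tibble (canonical records only are sampled).
#' @param n_inputs Number of inputs to draw.
#' @param profile A [corruption_profile()].
#' @param seed Integer seed.
#' @return List of two tibbles: `inputs` (`id`, `address`) and `annotations`
#'   (`id`, `uprn`, `label`).
#' @export
make_benchmark <- function(gazetteer, n_inputs, profile = corruption_profile(),
                           seed = 1) {
  stopifnot(n_inputs >= 1)
  set.seed(seed)
  gaz <- gazetteer[!gazetteer$is_augmented, ]
  by_pc <- split(seq_len(nrow(gaz)), gaz$POSTCODE)
  by_pc <- by_pc[sample.int(length(by_pc))]
  by_pc <- lapply(by_pc, function(ix) ix[sample.int(length(ix))])
  # round-robin across postcodes: every postcode represented before any
  # postcode contributes a second record
  rounds <- lapply(seq_len(max(lengths(by_pc))), function(r) {
    vapply(by_pc, function(ix) {
      if (length(ix) >= r) ix[r] else NA_integer_
    }, integer(1))
  })
  ordered <- unlist(rounds, use.names = FALSE)
  picks <- head(ordered[!is.na(ordered)], n_inputs)
  rows <- lapply(seq_along(picks), function(i) {
    cr <- corrupt_address(gaz[picks[i], ], profile, gaz)
    tibble::tibble(id = i, address = cr$address, uprn = cr$uprn,
                   label = cr$label)
  })
  tab <- dplyr::bind_rows(rows)
  list(inputs = tab[, c("id", "address")],
       annotations = tab[, c("id", "uprn", "label")])
}
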