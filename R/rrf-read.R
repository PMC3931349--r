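# Column layouts for the Rich Release Format (RRF) dialect. The release files
# name their columns nowhere; these orders follow the public RxNorm
# documentation. Only the fields the pipeline projects out are load-bearing.

#' Column schemas for the RRF files the pipeline reads
#'
#' Named character vectors giving the ordered column names of each
#' pipe-delimited release file: `RXNCONSO` (concept names, 18 columns),
#' `RXNSAT` (attributes, 13), `RXNCUI` (retired identifiers, 5), `RXNSAB`
#' (source metadata, 25), `RXNREL` (relationships, 16) and `RXNCUICHANGES`
#' (7; parsed and logged only).
#'
#' @format A named list of character vectors.
#' @export
rrf_schemas <- list(
  RXNCONSO = c("RXCUI", "LAT", "TS", "LUI", "STT", "SUI", "ISPREF", "RXAUI",
               "SAUI", "SCUI", "SDUI", "SAB", "TTY", "CODE", "STR", "SRL",
               "SUPPRESS", "CVF"),
  RXNSAT = c("RXCUI", "LUI", "SUI", "RXAUI", "STYPE", "CODE", "ATUI", "SATUI",
             "ATN", "SAB", "ATV", "SUPPRESS", "CVF"),
  RXNCUI = c("CUI1", "VER_START", "VER_END", "CARDINALITY", "CUI2"),
  RXNSAB = c("VCUI", "RCUI", "VSAB", "RSAB", "SON", "SF", "SVER", "VSTART",
             "VEND", "IMETA", "RMETA", "SLC", "SCC", "SRL", "TFR", "CFR",
             "CXTY", "TTYL", "ATNL", "LAT", "CENC", "CURVER", "SABIN", "SSN",
             "SCIT"),
  RXNREL = c("RXCUI1", "RXAUI1", "STYPE1", "REL", "RXCUI2", "RXAUI2",
             "STYPE2", "RELA", "RUI", "SRUI", "SAB", "SL", "DIR", "RG",
             "SUPPRESS", "CVF"),
  RXNCUICHANGES = c("RXAUI", "CODE", "SAB", "TTY", "STR", "OLD_RXCUI",
                    "NEW_RXCUI")
)

# source vocabulary code marking rows curated by RxNorm itself (rows from
# RxNorm's commercial sources are never used)
RXNORM_SAB <- "RXNORM"

# the four term types the ontology is built from
DRON_TTYS <- c("SCDF", "SCD", "SBD", "IN")

#' Read one pipe-delimited RRF file
#'
#' Parses a file in the RRF dialect: one record per line, fields separated by
#' `|`, an optional trailing delimiter, no quoting or escapes, UTF-8. Lines
#' whose field count disagrees with the schema are a parse error naming the
#' file and line (strict mode) or are dropped with a warning (lenient mode).
#'
#' @param path file to read.
#' @param schema ordered character vector of column names, e.g. an element of
#'   [rrf_schemas].
#' @param strict reject malformed lines (`TRUE`, default) or drop them with a
#'   warning.
#' @return A tibble with one column per schema entry, all character.
#' @export
#' @examples
#' f <- tempfile(fileext = ".RRF")
#' writeLines("100|foo|", f)
#' read_rrf(f, c("ID", "VAL"))
read_rrf <- function(path, schema, strict = TRUE) {
  if (!file.exists(path)) {
    dron_abort(paste0("RRF file not found: ", path), class = "dronr_missing_file")
  }
  ncol <- length(schema)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(as_tibble(setNames(rep(list(character()), ncol), schema)))
  }
  # sentinel keeps a final empty field distinguishable from a trailing "|"
  parts <- strsplit(paste0(lines, "\x01"), "|", fixed = TRUE)
  parts <- lapply(parts, function(p) {
    last <- p[length(p)]
    if (last == "\x01") p[-length(p)] else c(p[-length(p)], substr(last, 1L, nchar(last) - 1L))
  })
  nf <- lengths(parts)
  bad <- which(nf != ncol)
  if (length(bad) > 0L) {
    msg <- paste0("malformed RRF line in ", basename(path), ": line ", bad[1L],
                  " has ", nf[bad[1L]], " fields, expected ", ncol)
    if (strict) dron_abort(msg, class = "dronr_parse_error")
    rlang::warn(paste0(msg, " (", length(bad), " line(s) dropped)"))
    parts <- parts[-bad]
    if (length(parts) == 0L) {
      return(as_tibble(setNames(rep(list(character()), ncol), schema)))
    }
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = ncol, byrow = TRUE)
  as_tibble(setNames(lapply(seq_len(ncol), function(i) m[, i]), schema))
}

#' Extract drug-concept atoms from parsed concept-file rows
#'
#' Keeps only rows curated by RxNorm itself (`SAB == "RXNORM"`) whose term
#' type is one of SCDF, SCD, SBD or IN, and collapses them to one atom per
#' (RXCUI, term type). The name comes from the preferred row (`ISPREF == "Y"`)
#' when one exists, otherwise the first row in file order; conflicting
#' preferred names are logged and the first wins.
#'
#' @param conso tibble of parsed `RXNCONSO` rows (see [read_rrf]).
#' @return A tibble with columns `rxcui`, `tty`, `name`.
#' @export
extract_atoms <- function(conso) {
  rows <- conso |>
    filter(.data$SAB == RXNORM_SAB, .data$TTY %in% DRON_TTYS) |>
    mutate(.file_order = row_number(),
           .pref = .data$ISPREF == "Y") |>
    arrange(.data$RXCUI, .data$TTY, desc(.data$.pref), .data$.file_order)
  dup <- rows |>
    group_by(.data$RXCUI, .data$TTY) |>
    filter(.data$.pref, dplyr::n_distinct(.data$STR) > 1L) |>
    ungroup()
  if (nrow(dup) > 0L) {
    rlang::warn(paste0("conflicting preferred names for ",
                       dplyr::n_distinct(dup$RXCUI),
                       " concept(s); first row in file order kept"))
  }
  rows |>
    group_by(.data$RXCUI, .data$TTY) |>
    slice(1L) |>
    ungroup() |>
    select(rxcui = "RXCUI", tty = "TTY", name = "STR") |>
    arrange(.data$rxcui, .data$tty)
}

#' Extract RxNorm-curated NDC attributes from parsed attribute-file rows
#'
#' Keeps exactly the rows whose attribute name is `NDC` and whose source is
#' RxNorm itself; codes from other sources (e.g. MTHSPL) are discarded. NDC
#' strings are kept verbatim: RxNorm-curated codes are already normalized.
#'
#' @param sat tibble of parsed `RXNSAT` rows.
#' @param version release label the attributes were observed in.
#' @return A distinct tibble with columns `ndc`, `rxcui`, `version`.
#' @export
extract_ndc_attributes <- function(sat, version = NA_character_) {
  sat |>
    filter(.data$ATN == "NDC", .data$SAB == RXNORM_SAB, nzchar(.data$ATV)) |>
    select(ndc = "ATV", rxcui = "RXCUI") |>
    distinct() |>
    mutate(version = version) |>
    arrange(.data$ndc, .data$rxcui)
}

#' Extract retirement records from parsed retired-identifier rows
#'
#' Each row of the retired-identifier file carries a retired identifier
#' (`cui1`), the identifier its information merged into (`cui2`) and a
#' cardinality: `cui1 == cui2` marks an identifier entered in error,
#' cardinality greater than one marks a split.
#'
#' @param cui tibble of parsed `RXNCUI` rows.
#' @return A tibble with columns `cui1`, `cui2`, `cardinality` (integer),
#'   `self_referential`, `split`.
#' @export
extract_retirements <- function(cui) {
  if (nrow(cui) == 0L) {
    return(tibble(cui1 = character(), cui2 = character(),
                  cardinality = integer(), self_referential = logical(),
                  split = logical()))
  }
  card <- suppressWarnings(as.integer(cui$CARDINALITY))
  bad <- which(is.na(card) | card < 1L)
  if (length(bad) > 0L) {
    dron_abort(paste0("invalid cardinality '", cui$CARDINALITY[bad[1L]],
                      "' in retired-identifier file at row ", bad[1L]),
               class = "dronr_parse_error")
  }
  if (any(!nzchar(cui$CUI1))) {
    dron_abort("empty cui1 in retired-identifier file", class = "dronr_parse_error")
  }
  tibble(cui1 = cui$CUI1, cui2 = cui$CUI2, cardinality = card,
         self_referential = cui$CUI1 == cui$CUI2,
         split = card > 1L)
}

#' Extract the release version string from parsed source-metadata rows
#'
#' The metadata file must contain exactly one row for the RxNorm source; its
#' version field is captured verbatim. The chronological ordinal is assigned
#' by the caller (the ingestion orchestrator), not parsed from the label.
#'
#' @param sab tibble of parsed `RXNSAB` rows.
#' @return The version label, a length-one character vector.
#' @export
extract_version <- function(sab) {
  rows <- filter(sab, .data$RSAB == RXNORM_SAB)
  if (nrow(rows) != 1L) {
    dron_abort(paste0("expected exactly one RxNorm row in source metadata, found ",
                      nrow(rows)), class = "dronr_version_error")
  }
  rows$SVER[[1L]]
}

# relationship labels accepted from the optional relationship file, read as
# "rxcui1 <rela> rxcui2": SCD isa SCDF, SBD tradename_of SCD,
# SCDF/SCD has_ingredient IN
DRON_RELAS <- c("isa", "tradename_of", "has_ingredient")

extract_relationships <- function(rel) {
  rel |>
    filter(.data$SAB == RXNORM_SAB, .data$RELA %in% DRON_RELAS) |>
    select(rxcui1 = "RXCUI1", rela = "RELA", rxcui2 = "RXCUI2") |>
    distinct() |>
    arrange(.data$rxcui1, .data$rela, .data$rxcui2)
}

#' Read one release directory into a release snapshot
#'
#' Parses the five processed files (`RXNSAB.RRF`, `RXNCONSO.RRF`,
#' `RXNSAT.RRF`, `RXNCUI.RRF`, `RXNCUICHANGES.RRF`) plus the optional
#' relationship file `RXNREL.RRF` from one release directory. `RXNSAB` and
#' `RXNCONSO` are required; the others default to empty when absent. The
#' identifier-change file is parsed and counted but contributes nothing
#' downstream: the deprecation mapping is derived from the retired-identifier
#' file plus disappearance detection. The release files are not referentially
#' closed (attributes and relationships may cite identifiers with no atom);
#' that is tolerated and surfaces later as unattachable rows.
#'
#' @param dir release directory.
#' @param ordinal position of this release in the chronological series.
#' @param strict parse mode, see [read_rrf].
#' @return A `dron_release` object: a list with `version` (label + ordinal),
#'   `atoms`, `ndc_attributes`, `retirements`, `relationships` tibbles and
#'   `n_changes`.
#' @export
read_release <- function(dir, ordinal = 1L, strict = TRUE) {
  p <- function(f) file.path(dir, f)
  label <- extract_version(read_rrf(p("RXNSAB.RRF"), rrf_schemas$RXNSAB, strict))
  atoms <- extract_atoms(read_rrf(p("RXNCONSO.RRF"), rrf_schemas$RXNCONSO, strict))
  empty <- function(schema) as_tibble(setNames(rep(list(character()), length(schema)), schema))
  ndc <- extract_ndc_attributes(
    if (file.exists(p("RXNSAT.RRF"))) read_rrf(p("RXNSAT.RRF"), rrf_schemas$RXNSAT, strict)
    else empty(rrf_schemas$RXNSAT),
    label
  )
  ret <- extract_retirements(
    if (file.exists(p("RXNCUI.RRF"))) read_rrf(p("RXNCUI.RRF"), rrf_schemas$RXNCUI, strict)
    else empty(rrf_schemas$RXNCUI)
  )
  rel <- if (file.exists(p("RXNREL.RRF"))) {
    extract_relationships(read_rrf(p("RXNREL.RRF"), rrf_schemas$RXNREL, strict))
  } else {
    tibble(rxcui1 = character(), rela = character(), rxcui2 = character())
  }
  n_changes <- if (file.exists(p("RXNCUICHANGES.RRF"))) {
    nrow(read_rrf(p("RXNCUICHANGES.RRF"), rrf_schemas$RXNCUICHANGES, strict))
  } else 0L
  dron_log("release ", label, ": ", nrow(atoms), " atoms, ", nrow(ndc),
           " NDC attributes, ", nrow(ret), " retirement records, ",
           n_changes, " change rows (logged only)")
  structure(
    list(version = list(label = label, ordinal = as.integer(ordinal)),
         atoms = atoms, ndc_attributes = ndc, retirements = ret,
         relationships = rel, n_changes = n_changes),
    class = "dron_release"
  )
}

#' @export
print.dron_release <- function(x, ...) {
  cat("<dron_release> ", x$version$label, " (ordinal ", x$version$ordinal, ")\n",
      "  atoms: ", nrow(x$atoms),
      "  ndc attributes: ", nrow(x$ndc_attributes),
      "  retirements: ", nrow(x$retirements),
      "  relationships: ", nrow(x$relationships), "\n", sep = "")
  invisible(x)
}
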