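# Writer for the RRF dialect. Primarily serves the synthetic-fixture
# generator, and gives the parser a round-trip partner: a snapshot written
# here and re-read with read_release() compares equal field by field.

rrf_line <- function(fields) paste0(paste(fields, collapse = "|"), "|")

write_rrf <- function(rows, path) {
  # rows: character matrix or data frame, one output line per row
  if (is.data.frame(rows)) rows <- as.matrix(rows)
  lines <- if (length(rows) == 0L) character() else apply(rows, 1L, rrf_line)
  readr::write_lines(lines, path)
  invisible(path)
}

blank_row <- function(schema, ...) {
  row <- setNames(rep("", length(schema)), schema)
  vals <- list(...)
  row[names(vals)] <- unlist(vals)
  row
}

#' Write a release snapshot as an RRF release directory
#'
#' Serializes atoms, NDC attributes, retirement records and relationships in
#' the pipe-delimited RRF dialect, producing `RXNSAB.RRF`, `RXNCONSO.RRF`,
#' `RXNSAT.RRF`, `RXNCUI.RRF`, `RXNCUICHANGES.RRF` and (when relationships are
#' present) `RXNREL.RRF`. Fields the pipeline does not read are left empty.
#' Re-reading the directory with [read_release()] reproduces the inputs.
#'
#' @param dir output directory (created if needed).
#' @param version release label written into the source-metadata file.
#' @param atoms tibble with `rxcui`, `tty`, `name`.
#' @param ndc_attributes tibble with `ndc`, `rxcui`.
#' @param retirements tibble with `cui1`, `cui2`, `cardinality` (may be empty).
#' @param relationships tibble with `rxcui1`, `rela`, `rxcui2` (may be empty).
#' @return `dir`, invisibly.
#' @export
write_release <- function(dir, version, atoms,
                          ndc_attributes = tibble(ndc = character(), rxcui = character()),
                          retirements = tibble(cui1 = character(), cui2 = character(),
                                               cardinality = integer()),
                          relationships = tibble(rxcui1 = character(), rela = character(),
                                                 rxcui2 = character())) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- rrf_schemas

  sab <- t(blank_row(s$RXNSAB, RSAB = RXNORM_SAB, VSAB = paste0("RXNORM_", version),
                     SON = "RxNorm normalized names", SVER = version, CURVER = "Y",
                     SABIN = "Y", LAT = "ENG"))
  write_rrf(sab, file.path(dir, "RXNSAB.RRF"))

  conso <- t(vapply(seq_len(nrow(atoms)), function(i) {
    blank_row(s$RXNCONSO, RXCUI = atoms$rxcui[i], LAT = "ENG", ISPREF = "Y",
              RXAUI = as.character(i), SAB = RXNORM_SAB, TTY = atoms$tty[i],
              CODE = atoms$rxcui[i], STR = atoms$name[i], SUPPRESS = "N")
  }, character(length(s$RXNCONSO))))
  if (nrow(atoms) == 0L) conso <- matrix(character(), ncol = length(s$RXNCONSO))
  write_rrf(conso, file.path(dir, "RXNCONSO.RRF"))

  sat <- t(vapply(seq_len(nrow(ndc_attributes)), function(i) {
    blank_row(s$RXNSAT, RXCUI = ndc_attributes$rxcui[i], STYPE = "CUI",
              ATN = "NDC", SAB = RXNORM_SAB, ATV = ndc_attributes$ndc[i],
              SUPPRESS = "N")
  }, character(length(s$RXNSAT))))
  if (nrow(ndc_attributes) == 0L) sat <- matrix(character(), ncol = length(s$RXNSAT))
  write_rrf(sat, file.path(dir, "RXNSAT.RRF"))

  cui <- t(vapply(seq_len(nrow(retirements)), function(i) {
    blank_row(s$RXNCUI, CUI1 = retirements$cui1[i], VER_START = version,
              VER_END = version, CARDINALITY = as.character(retirements$cardinality[i]),
              CUI2 = retirements$cui2[i])
  }, character(length(s$RXNCUI))))
  if (nrow(retirements) == 0L) cui <- matrix(character(), ncol = length(s$RXNCUI))
  write_rrf(cui, file.path(dir, "RXNCUI.RRF"))

  # change file mirrors the retirement rows; it is parsed and logged only
  chg <- t(vapply(seq_len(nrow(retirements)), function(i) {
    blank_row(s$RXNCUICHANGES, RXAUI = as.character(i), SAB = RXNORM_SAB,
              OLD_RXCUI = retirements$cui1[i], NEW_RXCUI = retirements$cui2[i])
  }, character(length(s$RXNCUICHANGES))))
  if (nrow(retirements) == 0L) chg <- matrix(character(), ncol = length(s$RXNCUICHANGES))
  write_rrf(chg, file.path(dir, "RXNCUICHANGES.RRF"))

  if (nrow(relationships) > 0L) {
    rel <- t(vapply(seq_len(nrow(relationships)), function(i) {
      blank_row(s$RXNREL, RXCUI1 = relationships$rxcui1[i], STYPE1 = "CUI",
                REL = "RO", RXCUI2 = relationships$rxcui2[i], STYPE2 = "CUI",
                RELA = relationships$rela[i], SAB = RXNORM_SAB)
    }, character(length(s$RXNREL))))
    write_rrf(rel, file.path(dir, "RXNREL.RRF"))
  }
  invisible(dir)
}
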