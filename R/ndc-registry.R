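# Comprehensive historical NDC registry. Every (NDC, RXCUI) association ever
# observed in any release is kept forever, with the release span over which it
# was seen; nothing is deleted. After provenance resolution each entry lands
# in exactly one status class.

NDC_INCLUDED <- "INCLUDED"
NDC_EXCLUDED_ERROR <- "EXCLUDED_ERROR"
NDC_EXCLUDED_SPLIT <- "EXCLUDED_SPLIT"
NDC_ORPHANED <- "ORPHANED"

#' Create an empty historical NDC registry
#'
#' The registry accumulates one entry per (NDC, original RXCUI) pair across
#' the whole release series, mirroring a comprehensive NDC table: codes
#' dropped from current releases stay queryable forever.
#'
#' @return A `dron_ndc_registry` object (a tibble with metadata).
#' @export
ndc_registry_init <- function() {
  structure(
    list(entries = tibble(ndc = character(), original_rxcui = character(),
                          first_seen = integer(), last_seen = integer()),
         versions = tibble(ordinal = integer(), label = character()),
         finalized = FALSE),
    class = "dron_ndc_registry"
  )
}

#' @export
print.dron_ndc_registry <- function(x, ...) {
  cat("<dron_ndc_registry> ", nrow(x$entries), " (ndc, rxcui) pair(s) across ",
      nrow(x$versions), " release(s)",
      if (x$finalized) "; finalized" else "", "\n", sep = "")
  invisible(x)
}

#' Accumulate one release's NDC attributes into the registry
#'
#' Upserts each observed (NDC, RXCUI) pair: a new pair opens an entry with
#' `first_seen = last_seen =` the release ordinal; a known pair extends its
#' `last_seen`. Entries are never deleted, so a code that moves between
#' identifiers keeps one entry per identifier it was ever attached to.
#'
#' @param registry a `dron_ndc_registry`.
#' @param release a `dron_release` snapshot, ingested in chronological order.
#' @return The updated registry.
#' @export
ndc_accumulate <- function(registry, release) {
  ord <- release$version$ordinal
  if (nrow(registry$versions) > 0L && ord <= max(registry$versions$ordinal)) {
    dron_abort(paste0("releases must be ingested in chronological order; got ordinal ",
                      ord, " after ", max(registry$versions$ordinal)),
               class = "dronr_out_of_order")
  }
  registry$versions <- bind_rows(registry$versions,
                                 tibble(ordinal = ord, label = release$version$label))
  obs <- distinct(release$ndc_attributes, .data$ndc, .data$rxcui)
  if (nrow(obs) == 0L) return(registry)
  e <- registry$entries
  key_e <- paste(e$ndc, e$original_rxcui, sep = "\r")
  key_o <- paste(obs$ndc, obs$rxcui, sep = "\r")
  hit <- match(key_o, key_e)
  seen <- !is.na(hit)
  e$last_seen[hit[seen]] <- ord
  registry$entries <- bind_rows(
    e,
    tibble(ndc = obs$ndc[!seen], original_rxcui = obs$rxcui[!seen],
           first_seen = ord, last_seen = ord)
  )
  registry$finalized <- FALSE
  registry
}

#' Assign a status to every registry entry via provenance resolution
#'
#' Each entry's original identifier is resolved: entered-in-error identifiers
#' give `EXCLUDED_ERROR` and split identifiers `EXCLUDED_SPLIT` (both left out
#' of the emitted ontology); current or merged identifiers give `INCLUDED`
#' with the terminal identifier; identifiers that vanished with no record give
#' `ORPHANED`, retained under the last known identifier so historical claims
#' lookups keep working. When one NDC has several included entries resolving
#' to different identifiers, the entry with the latest `last_seen` wins at
#' export time and the losers are logged.
#'
#' @param registry a `dron_ndc_registry`.
#' @param prov a compacted `dron_provenance` table.
#' @return The registry with `status` and `resolved_rxcui` columns.
#' @export
ndc_finalize <- function(registry, prov) {
  res <- resolve_rxcui(registry$entries$original_rxcui, prov)
  registry$entries <- registry$entries |>
    mutate(resolved_rxcui = res$terminal,
           status = dplyr::case_when(
             res$kind == STATUS_ERROR ~ NDC_EXCLUDED_ERROR,
             res$kind == STATUS_SPLIT ~ NDC_EXCLUDED_SPLIT,
             res$kind == STATUS_ORPHANED ~ NDC_ORPHANED,
             TRUE ~ NDC_INCLUDED
           ))
  registry$finalized <- TRUE
  registry
}

#' The deduplicated set of NDCs carried into the ontology
#'
#' Filters the finalized registry to `INCLUDED` and `ORPHANED` entries and
#' returns exactly one (ndc, resolved identifier) pair per code: the entry
#' with the latest `last_seen` wins, included entries beating orphaned ones on
#' ties, then later `first_seen`, then larger identifier, so the result is a
#' deterministic function of the release history alone.
#'
#' @param registry a finalized `dron_ndc_registry`.
#' @return A tibble with columns `ndc`, `resolved_rxcui`, `orphaned`.
#' @export
ndc_included <- function(registry) {
  if (!registry$finalized) {
    dron_abort("registry must be finalized before exporting included NDCs",
               class = "dronr_unfinalized")
  }
  kept <- filter(registry$entries, .data$status %in% c(NDC_INCLUDED, NDC_ORPHANED))
  if (nrow(kept) == 0L) {
    return(tibble(ndc = character(), resolved_rxcui = character(), orphaned = logical()))
  }
  multi <- kept |>
    group_by(.data$ndc) |>
    filter(dplyr::n_distinct(.data$resolved_rxcui) > 1L) |>
    ungroup()
  if (nrow(multi) > 0L) {
    dron_log(dplyr::n_distinct(multi$ndc),
             " NDC(s) resolve to multiple identifiers; latest observation wins")
  }
  kept |>
    arrange(.data$ndc, desc(.data$last_seen), .data$status != NDC_INCLUDED,
            desc(.data$first_seen), desc(.data$resolved_rxcui)) |>
    group_by(.data$ndc) |>
    slice(1L) |>
    ungroup() |>
    mutate(orphaned = .data$status == NDC_ORPHANED) |>
    select("ndc", "resolved_rxcui", "orphaned") |>
    arrange(.data$ndc)
}

#' Full observation history of one NDC
#'
#' @param registry a `dron_ndc_registry`.
#' @param ndc the code to look up.
#' @return Tibble of every entry ever observed for the code.
#' @export
ndc_history <- function(registry, ndc) {
  filter(registry$entries, .data$ndc == !!ndc) |> arrange(.data$first_seen)
}
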