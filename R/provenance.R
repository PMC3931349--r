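# Deprecated-identifier tracking. A provenance table mirrors the master
# conversion table of the build pipeline (old_rxcui -> new_rxcui), with the
# two literal status codes "ERROR" (entered in error) and "S_RXNCUI" (split)
# plus an ORPHANED flag for identifiers that vanish with no retirement record.

STATUS_MERGED <- "MERGED"
STATUS_ERROR <- "ERROR"
STATUS_SPLIT <- "SPLIT"
STATUS_ORPHANED <- "ORPHANED"
STATUS_CURRENT <- "CURRENT"

# literal codes used in the persisted two-column form
CODE_ERROR <- "ERROR"
CODE_SPLIT <- "S_RXNCUI"

#' Create an empty provenance table
#'
#' A provenance table maps every retired identifier (`old_rxcui`) to the
#' identifier now carrying its information (`new_rxcui`), or to a status:
#' `ERROR` (entered in error), `SPLIT` (information divided across several
#' successors, untrackable without manual work) or `ORPHANED` (identifier
#' vanished from a release with no retirement record; its data is retained
#' under the last known identifier). `observed_current` records the
#' identifiers present in the most recent ingested release.
#'
#' @return A `dron_provenance` object.
#' @export
provenance_init <- function() {
  structure(
    list(entries = tibble(old_rxcui = character(), new_rxcui = character(),
                          status = character()),
         observed_current = character(),
         compacted = TRUE),
    class = "dron_provenance"
  )
}

#' @export
print.dron_provenance <- function(x, ...) {
  tab <- table(factor(x$entries$status,
                      levels = c(STATUS_MERGED, STATUS_ERROR, STATUS_SPLIT, STATUS_ORPHANED)))
  cat("<dron_provenance> ", nrow(x$entries), " retired identifier(s); ",
      length(x$observed_current), " current; ",
      if (x$compacted) "compacted" else "NOT compacted", "\n  ",
      paste(names(tab), as.integer(tab), sep = ": ", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Detect identifiers retired by the release being ingested
#'
#' The concept-names file of a release lists every current identifier, so any
#' previously observed identifier absent from it must have been retired.
#'
#' @param known_ids character vector of identifiers accumulated from all prior
#'   releases (atoms and NDC associations).
#' @param release a `dron_release` snapshot.
#' @return Character vector of newly retired identifiers.
#' @export
detect_retired <- function(known_ids, release) {
  setdiff(known_ids, release$atoms$rxcui)
}

# classify the retirement records of one release, one row per cui1:
# ERROR when cui1 == cui2, SPLIT when cardinality > 1, else MERGED(cui2).
# Conflicting records for one cui1 are a hard error.
classify_retirements <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(cui1 = character(), status = character(), cui2 = character()))
  }
  cls <- records |>
    mutate(kind = dplyr::case_when(
      .data$self_referential ~ STATUS_ERROR,
      .data$split ~ STATUS_SPLIT,
      TRUE ~ STATUS_MERGED
    )) |>
    group_by(.data$cui1) |>
    summarise(n_kinds = dplyr::n_distinct(.data$kind),
              kind = .data$kind[1L],
              n_targets = dplyr::n_distinct(.data$cui2),
              cui2 = .data$cui2[1L], .groups = "drop")
  bad <- filter(cls, .data$n_kinds > 1L | (.data$kind == STATUS_MERGED & .data$n_targets > 1L))
  if (nrow(bad) > 0L) {
    dron_abort(paste0("conflicting retirement records for identifier(s): ",
                      paste(bad$cui1, collapse = ", ")),
               class = "dronr_retirement_conflict")
  }
  cls |>
    mutate(cui2 = if_else(.data$kind == STATUS_MERGED, .data$cui2, NA_character_)) |>
    select("cui1", status = "kind", "cui2")
}

#' Apply a release's retirement records to the provenance table
#'
#' Every unresolved key (an identifier that disappeared but has so far no
#' explanation, carried as `ORPHANED`) with a matching record is upgraded:
#' `cui1 == cui2` marks entry-in-error, cardinality above one marks a split,
#' and a single-target record a merge into `cui2`. Keys with no record stay
#' `ORPHANED`, self-referential and flagged. Previously merged entries whose
#' successor was itself retired are repaired by the subsequent
#' [compact_closure()] pass.
#'
#' @param prov a `dron_provenance` table.
#' @param records retirement-record tibble from [extract_retirements()].
#' @return The updated (uncompacted) `dron_provenance` table.
#' @export
apply_retirements <- function(prov, records) {
  cls <- classify_retirements(records)
  e <- prov$entries
  idx <- match(e$old_rxcui, cls$cui1)
  upgrade <- !is.na(idx) & e$status == STATUS_ORPHANED
  e$status[upgrade] <- cls$status[idx[upgrade]]
  e$new_rxcui[upgrade] <- if_else(
    cls$status[idx[upgrade]] == STATUS_MERGED,
    cls$cui2[idx[upgrade]],
    NA_character_
  )
  prov$entries <- e
  prov$compacted <- FALSE
  prov
}

#' Compact the provenance table to its transitive closure
#'
#' Rewrites every merge chain so each retired identifier points directly at
#' the latest identifier referring to the same entity with no intervening
#' steps. A chain ending in an entry-in-error (resp. split) absorbs that
#' status. A chain ending at an orphaned identifier points at the orphan,
#' whose own flagged self-entry is preserved. Cycles, which the update
#' procedure assumes never to exist, raise an error naming the cycle.
#'
#' @param prov a `dron_provenance` table.
#' @return The compacted table; compaction is idempotent.
#' @export
compact_closure <- function(prov) {
  e <- prov$entries
  if (nrow(e) == 0L) {
    prov$compacted <- TRUE
    return(prov)
  }
  key_idx <- setNames(seq_len(nrow(e)), e$old_rxcui)
  # memo: per key, resolved (status, terminal)
  res_status <- rep(NA_character_, nrow(e))
  res_terminal <- rep(NA_character_, nrow(e))

  resolve_key <- function(i) {
    path <- integer()
    j <- i
    repeat {
      if (!is.na(res_status[j])) break
      path <- c(path, j)
      if (e$status[j] %in% c(STATUS_ERROR, STATUS_SPLIT)) {
        res_status[j] <<- e$status[j]; res_terminal[j] <<- NA_character_
        path <- path[-length(path)]
        break
      }
      if (e$status[j] == STATUS_ORPHANED) {
        res_status[j] <<- STATUS_ORPHANED; res_terminal[j] <<- e$old_rxcui[j]
        path <- path[-length(path)]
        break
      }
      nxt <- key_idx[e$new_rxcui[j]]
      if (is.na(nxt)) { # points outside the table: a terminal identifier
        res_status[j] <<- STATUS_MERGED; res_terminal[j] <<- e$new_rxcui[j]
        path <- path[-length(path)]
        break
      }
      if (nxt %in% path) {
        cyc <- e$old_rxcui[path[which(path == nxt)[1L]:length(path)]]
        dron_abort(paste0("cycle in provenance chain: ",
                          paste(c(cyc, cyc[1L]), collapse = " -> ")),
                   class = "dronr_provenance_cycle")
      }
      j <- nxt
    }
    # propagate the resolved end state back along the walked path
    for (k in path) {
      if (res_status[j] %in% c(STATUS_ERROR, STATUS_SPLIT)) {
        res_status[k] <<- res_status[j]; res_terminal[k] <<- NA_character_
      } else {
        res_status[k] <<- STATUS_MERGED; res_terminal[k] <<- res_terminal[j]
      }
    }
    invisible(NULL)
  }
  for (i in seq_len(nrow(e))) resolve_key(i)

  prov$entries <- tibble(old_rxcui = e$old_rxcui,
                         new_rxcui = res_terminal,
                         status = res_status) |>
    arrange(.data$old_rxcui)
  prov$compacted <- TRUE
  prov
}

#' Resolve identifiers to their terminal form or status
#'
#' Maps each identifier to one of: `CURRENT` (present in the most recent
#' release; terminal is itself), `MERGED` (terminal is the latest identifier
#' for the same entity), `ORPHANED` (vanished with no record; terminal is the
#' last known identifier, i.e. itself), or `ERROR` / `SPLIT` (no terminal).
#' Identifiers never seen at all resolve to `CURRENT` with a logged warning.
#'
#' @param rxcui character vector of identifiers.
#' @param prov a compacted `dron_provenance` table.
#' @return A tibble with columns `rxcui`, `kind`, `terminal`.
#' @export
resolve_rxcui <- function(rxcui, prov) {
  if (!prov$compacted) {
    dron_abort("provenance table must be compacted before resolution",
               class = "dronr_uncompacted")
  }
  e <- prov$entries
  idx <- match(rxcui, e$old_rxcui)
  is_current <- rxcui %in% prov$observed_current
  kind <- dplyr::case_when(
    is_current ~ STATUS_CURRENT,
    !is.na(idx) ~ e$status[idx],
    TRUE ~ STATUS_CURRENT
  )
  terminal <- dplyr::case_when(
    is_current ~ rxcui,
    !is.na(idx) & e$status[idx] == STATUS_MERGED ~ e$new_rxcui[idx],
    !is.na(idx) & e$status[idx] == STATUS_ORPHANED ~ rxcui,
    !is.na(idx) ~ NA_character_,
    TRUE ~ rxcui
  )
  unknown <- !is_current & is.na(idx)
  if (any(unknown)) {
    dron_log(sum(unknown), " identifier(s) never observed in any release; treated as current")
  }
  tibble(rxcui = rxcui, kind = kind, terminal = terminal)
}

#' Ingest one release into the provenance table
#'
#' The per-release update procedure: (1) identifiers previously observed but
#' absent from the release's concept file are detected as newly retired and
#' added as unresolved keys; (2) the release's retirement records classify
#' keys as merged, entered-in-error or split; (3) the transitive closure is
#' recomputed so every chain points at its terminal identifier. A retired
#' identifier that reappears in a newer release is treated as current again
#' (re-activation) and its entry dropped, with a log line.
#'
#' @param prov a `dron_provenance` table.
#' @param release a `dron_release` snapshot.
#' @param known_ids identifiers accumulated from all prior releases.
#' @return The updated, compacted `dron_provenance` table.
#' @export
update_provenance <- function(prov, release, known_ids) {
  current <- unique(release$atoms$rxcui)
  reactivated <- intersect(prov$entries$old_rxcui, current)
  if (length(reactivated) > 0L) {
    dron_log(length(reactivated), " retired identifier(s) reappeared; treated as current again")
    prov$entries <- filter(prov$entries, !.data$old_rxcui %in% reactivated)
  }
  newly <- setdiff(detect_retired(known_ids, release), prov$entries$old_rxcui)
  if (length(newly) > 0L) {
    prov$entries <- bind_rows(
      prov$entries,
      tibble(old_rxcui = newly, new_rxcui = newly, status = STATUS_ORPHANED)
    )
  }
  prov <- apply_retirements(prov, release$retirements)
  prov$observed_current <- current
  compact_closure(prov)
}

#' Persist a provenance table in its two-column conversion form
#'
#' Writes a tab-separated file with columns `old_rxcui`, `new_rxcui`,
#' `orphaned`. Status codes are stored literally as `ERROR` and `S_RXNCUI`;
#' orphaned identifiers are stored as a self-reference with the flag set.
#'
#' @param prov a `dron_provenance` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(prov, path) {
  out <- prov$entries |>
    mutate(new_rxcui = dplyr::case_when(
      .data$status == STATUS_ERROR ~ CODE_ERROR,
      .data$status == STATUS_SPLIT ~ CODE_SPLIT,
      .data$status == STATUS_ORPHANED ~ .data$old_rxcui,
      TRUE ~ .data$new_rxcui
    ),
    orphaned = .data$status == STATUS_ORPHANED) |>
    select("old_rxcui", "new_rxcui", "orphaned")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
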