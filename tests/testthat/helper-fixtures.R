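# Shared fixture builders. Everything is generated in code at test time; the
# cache avoids re-running the full pipeline for every file that inspects it.

small_config <- function(seed = 11L, n_merges = 2L, n_splits = 1L,
                         n_errors = 1L, n_silent = 1L, ...) {
  fixture_config(seed = seed, n_ingredients = 12L, n_cdfs = 8L, n_cds = 16L,
                 n_bds = 4L, n_ndcs = 20L, n_releases = 4L, n_merges = n_merges,
                 n_splits = n_splits, n_errors = n_errors, n_silent = n_silent,
                 ...)
}

.fixture_cache <- new.env(parent = emptyenv())

# full pipeline run on a seeded fixture, memoized per (seed, size) key
cached_run <- function(seed = 101L, small = TRUE) {
  key <- paste0("run_", seed, "_", small)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- if (small) small_config(seed = seed) else fixture_config(seed = seed)
  dir <- file.path(tempdir(), paste0("dronr-fix-", seed, "-", small))
  series <- generate_release_series(cfg, dir)
  chebi <- file.path(dir, "mini-chebi.owl")
  generate_mini_chebi(cfg, chebi)
  run <- list(config = cfg, series = series, manifest = series$manifest,
              chebi = chebi, build = build_dron(series$dirs, chebi))
  .fixture_cache[[key]] <- run
  run
}

# one hand-built release: one ingredient in two forms, three clinical drugs,
# one branded drug, five NDCs (all countable by eye)
tiny_release_dir <- function(dir = tempfile()) {
  atoms <- tibble::tibble(
    rxcui = c("11", "21", "22", "31", "32", "33", "41"),
    tty = c("IN", "SCDF", "SCDF", "SCD", "SCD", "SCD", "SBD"),
    name = c("aspirin", "aspirin tablet", "aspirin capsule",
             "aspirin 100 mg tablet", "aspirin 200 mg tablet",
             "aspirin 100 mg capsule", "brandaspirin 100 mg capsule")
  )
  rels <- tibble::tibble(
    rxcui1 = c("21", "22", "31", "32", "33", "41"),
    rela = c("has_ingredient", "has_ingredient", "isa", "isa", "isa",
             "tradename_of"),
    rxcui2 = c("11", "11", "21", "21", "22", "33")
  )
  ndcs <- tibble::tibble(
    ndc = sprintf("%011d", 1:5),
    rxcui = c("31", "32", "33", "41", "41")
  )
  write_release(dir, version = "TINY_01", atoms = atoms,
                ndc_attributes = ndcs, relationships = rels)
  dir
}

# independent brute-force oracle: resolve an identifier by chasing raw
# retirement records (union over all releases), never touching the
# provenance-table implementation
chain_oracle <- function(id, records, final_atoms, ever_seen) {
  seen <- character()
  repeat {
    if (id %in% final_atoms) {
      return(list(kind = if (length(seen) == 0L) "CURRENT" else "MERGED",
                  terminal = id))
    }
    hit <- records[records$cui1 == id, , drop = FALSE]
    if (nrow(hit) == 0L) {
      # vanished with no record
      return(list(kind = if (length(seen) == 0L) "ORPHANED" else "MERGED",
                  terminal = id))
    }
    if (any(hit$cui1 == hit$cui2)) return(list(kind = "ERROR", terminal = NA_character_))
    if (any(hit$cardinality > 1L)) return(list(kind = "SPLIT", terminal = NA_character_))
    seen <- c(seen, id)
    id <- hit$cui2[1L]
    if (id %in% seen) stop("cycle in oracle chain")
  }
}
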