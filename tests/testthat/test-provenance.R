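# Deprecated-identifier tracking: detection, record classification,
# transitive closure, resolution.

fake_release <- function(rxcuis, retirements = NULL) {
  structure(list(
    version = list(label = "t", ordinal = 1L),
    atoms = tibble::tibble(rxcui = rxcuis, tty = "SCD",
                           name = paste0("drug ", rxcuis)),
    ndc_attributes = tibble::tibble(ndc = character(), rxcui = character(),
                                    version = character()),
    retirements = if (is.null(retirements)) {
      tibble::tibble(cui1 = character(), cui2 = character(),
                     cardinality = integer(), self_referential = logical(),
                     split = logical())
    } else {
      dplyr::mutate(retirements, self_referential = cui1 == cui2,
                    split = cardinality > 1L)
    },
    relationships = tibble::tibble(rxcui1 = character(), rela = character(),
                                   rxcui2 = character()),
    n_changes = 0L
  ), class = "dron_release")
}

test_that("detect_retired is the set difference against the concept file", {
  rel <- fake_release(c("A", "C"))
  expect_setequal(detect_retired(c("A", "B", "C"), rel), "B")
  expect_length(detect_retired(c("A", "C"), rel), 0L)
  # identifiers vanishing with no record become orphan candidates
  rel40 <- fake_release(character())
  expect_length(detect_retired(as.character(1:40), rel40), 40L)
})

test_that("retirement records classify keys as merged, error or split", {
  recs <- tibble::tibble(cui1 = c("100", "101", "102"),
                         cui2 = c("200", "101", "201"),
                         cardinality = c(1L, 1L, 2L),
                         self_referential = c(FALSE, TRUE, FALSE),
                         split = c(FALSE, FALSE, TRUE))
  prov <- provenance_init()
  prov$entries <- tibble::tibble(old_rxcui = c("100", "101", "102", "103"),
                                 new_rxcui = c("100", "101", "102", "103"),
                                 status = "ORPHANED")
  prov <- apply_retirements(prov, recs)
  e <- prov$entries
  expect_equal(e$status, c("MERGED", "ERROR", "SPLIT", "ORPHANED"))
  expect_equal(e$new_rxcui[1], "200")
  expect_true(is.na(e$new_rxcui[2]))
  # key without a record stays orphaned and self-referential
  expect_equal(e$new_rxcui[4], "103")
})

test_that("conflicting records for one identifier are a hard error", {
  recs <- tibble::tibble(cui1 = c("100", "100"), cui2 = c("200", "201"),
                         cardinality = c(1L, 1L),
                         self_referential = FALSE, split = FALSE)
  prov <- provenance_init()
  prov$entries <- tibble::tibble(old_rxcui = "100", new_rxcui = "100",
                                 status = "ORPHANED")
  expect_error(apply_retirements(prov, recs),
               class = "dronr_retirement_conflict")
})

make_prov <- function(entries, current = character()) {
  p <- provenance_init()
  p$entries <- entries
  p$observed_current <- current
  p$compacted <- FALSE
  p
}

test_that("compact_closure rewrites chains to their terminal identifier", {
  p <- make_prov(tibble::tibble(old_rxcui = c("A", "B"),
                                new_rxcui = c("B", "C"),
                                status = "MERGED"),
                 current = "C")
  p <- compact_closure(p)
  expect_equal(p$entries$new_rxcui[p$entries$old_rxcui == "A"], "C")
  expect_equal(p$entries$new_rxcui[p$entries$old_rxcui == "B"], "C")
  r <- resolve_rxcui(c("A", "B", "C", "Z"), p)
  expect_equal(r$kind, c("MERGED", "MERGED", "CURRENT", "CURRENT"))
  expect_equal(r$terminal, c("C", "C", "C", "Z"))
})

test_that("error and split statuses absorb along chains (vs chain oracle)", {
  # randomized acyclic chains ending in each terminal state
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- sample(3:12, 1L)
      ids <- paste0("N", sample(1000:9999, n))
      end_state <- sample(c("ERROR", "SPLIT", "ORPHANED", "MERGED"), 1L)
      entries <- tibble::tibble(
        old_rxcui = ids[-n],
        new_rxcui = ids[-1L],
        status = "MERGED"
      )
      terminal_entry <- switch(end_state,
        ERROR = tibble::tibble(old_rxcui = ids[n], new_rxcui = NA, status = "ERROR"),
        SPLIT = tibble::tibble(old_rxcui = ids[n], new_rxcui = NA, status = "SPLIT"),
        ORPHANED = tibble::tibble(old_rxcui = ids[n], new_rxcui = ids[n],
                                  status = "ORPHANED"),
        MERGED = NULL
      )
      current <- if (end_state == "MERGED") ids[n] else character()
      p <- make_prov(dplyr::bind_rows(entries, terminal_entry), current)
      p <- compact_closure(p)
      res <- resolve_rxcui(ids[1L], p)
      if (end_state %in% c("ERROR", "SPLIT")) {
        expect_equal(res$kind, end_state)
        expect_true(is.na(res$terminal))
      } else {
        expect_equal(res$kind, "MERGED")
        expect_equal(res$terminal, ids[n])
      }
    })
  }
})

test_that("compact_closure is idempotent and detects cycles", {
  p <- make_prov(tibble::tibble(old_rxcui = c("A", "B", "D"),
                                new_rxcui = c("B", "C", "D"),
                                status = c("MERGED", "MERGED", "ORPHANED")),
                 current = "C")
  once <- compact_closure(p)
  twice <- compact_closure(once)
  expect_identical(once$entries, twice$entries)
  # no key maps to itself except flagged orphans
  self_map <- once$entries$old_rxcui == once$entries$new_rxcui
  expect_true(all(once$entries$status[which(self_map)] == "ORPHANED"))

  cyc <- make_prov(tibble::tibble(old_rxcui = c("A", "B"),
                                  new_rxcui = c("B", "A"),
                                  status = "MERGED"))
  expect_error(compact_closure(cyc), class = "dronr_provenance_cycle")
  err <- tryCatch(compact_closure(cyc), error = identity)
  expect_match(conditionMessage(err), "A -> B|B -> A")
})

test_that("resolution statuses follow the stored conversion codes", {
  p <- make_prov(tibble::tibble(old_rxcui = c("A", "E", "S", "O"),
                                new_rxcui = c("C", NA, NA, "O"),
                                status = c("MERGED", "ERROR", "SPLIT", "ORPHANED")),
                 current = "C")
  p <- compact_closure(p)
  r <- resolve_rxcui(c("C", "A", "E", "S", "O"), p)
  expect_equal(r$kind, c("CURRENT", "MERGED", "ERROR", "SPLIT", "ORPHANED"))
  expect_equal(r$terminal, c("C", "C", NA, NA, "O"))
  expect_error(resolve_rxcui("A", make_prov(p$entries)),
               class = "dronr_uncompacted")
})

test_that("incremental maintenance equals a from-scratch chain-following pass", {
  for (seed in c(3L, 17L, 29L)) {
    cfg <- small_config(seed = seed)
    dir <- withr::local_tempdir()
    series <- generate_release_series(cfg, dir)
    releases <- lapply(seq_along(series$dirs),
                       function(i) read_release(series$dirs[[i]], ordinal = i))
    # incremental: per-release table maintenance
    prov <- provenance_init()
    known <- character()
    for (rel in releases) {
      prov <- update_provenance(prov, rel, known)
      known <- union(known, rel$atoms$rxcui)
    }
    # from scratch: chase every raw retirement chain with the oracle
    records <- dplyr::distinct(dplyr::bind_rows(lapply(releases, `[[`, "retirements")))
    final_atoms <- releases[[length(releases)]]$atoms$rxcui
    every_id <- unique(unlist(lapply(releases, function(r) r$atoms$rxcui)))
    got <- resolve_rxcui(every_id, prov)
    for (i in seq_along(every_id)) {
      exp <- chain_oracle(every_id[i], records, final_atoms, every_id)
      expect_equal(got$kind[i], exp$kind)
      expect_equal(got$terminal[i], exp$terminal)
    }
  }
})

test_that("a retired identifier that reappears is treated as current again", {
  r1 <- fake_release(c("A", "B"))
  r2 <- fake_release("A")
  r3 <- fake_release(c("A", "B"))
  prov <- provenance_init()
  prov <- update_provenance(prov, r2, known_ids = c("A", "B"))
  expect_equal(resolve_rxcui("B", prov)$kind, "ORPHANED")
  prov <- update_provenance(prov, r3, known_ids = c("A", "B"))
  expect_equal(resolve_rxcui("B", prov)$kind, "CURRENT")
})

test_that("the persisted form uses the literal status codes", {
  p <- make_prov(tibble::tibble(old_rxcui = c("A", "E", "S", "O"),
                                new_rxcui = c("C", NA, NA, "O"),
                                status = c("MERGED", "ERROR", "SPLIT", "ORPHANED")),
                 current = "C")
  p <- compact_closure(p)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_provenance(p, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(tab$new_rxcui[tab$old_rxcui == "E"], "ERROR")
  expect_equal(tab$new_rxcui[tab$old_rxcui == "S"], "S_RXNCUI")
  expect_true(tab$orphaned[tab$old_rxcui == "O"])
  expect_equal(tab$new_rxcui[tab$old_rxcui == "O"], "O")
})
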