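# Normalized entity graph: construction, NDC attachment, queries, export.

tiny_build <- function() {
  dir <- tiny_release_dir(file.path(tempdir(), "dronr-tiny"))
  build_dron(dir, chebi = NULL)
}

test_that("entities translate directly from atoms and relationships", {
  b <- tiny_build()
  g <- b$graph
  expect_equal(entity_counts(g),
               c(ingredient = 1L, disposition = 6L, cdf = 2L, cd = 3L,
                 bd = 1L, ndc = 5L))
  # SCD + isa relationship -> clinical drug with its parent form
  expect_equal(g$cds$cdf_rxcui[g$cds$rxcui == "31"], "21")
  expect_equal(g$bds$cd_rxcui[g$bds$rxcui == "41"], "33")
  expect_false(any(g$cds$dangling))
  v <- validate_graph(g)
  expect_true(v$valid)
})

test_that("hand-countable query: 1 ingredient, 2 forms, 3 drugs, 5 codes", {
  b <- tiny_build()
  # all five packaged products contain aspirin, whichever parent they hang from
  expect_equal(ndcs_by_ingredient(b$graph, "aspirin"), sprintf("%011d", 1:5))
  expect_equal(ndcs_by_ingredient(b$graph, "11"), sprintf("%011d", 1:5))
  expect_warning(out <- ndcs_by_ingredient(b$graph, "no such thing"),
                 "unknown ingredient")
  expect_length(out, 0L)
})

test_that("merged concepts collapse to one entity keyed by terminal identifier", {
  dir <- withr::local_tempdir()
  atoms1 <- tibble::tibble(
    rxcui = c("11", "21", "31", "32"),
    tty = c("IN", "SCDF", "SCD", "SCD"),
    name = c("drug a", "form a", "prod one", "prod two")
  )
  rels <- tibble::tibble(rxcui1 = c("21", "31", "32"),
                         rela = c("has_ingredient", "isa", "isa"),
                         rxcui2 = c("11", "21", "21"))
  write_release(file.path(dir, "1"), "V1", atoms1,
                tibble::tibble(ndc = "00000000001", rxcui = "31"),
                relationships = rels)
  # release 2: 31 merged into 32; its code follows
  write_release(file.path(dir, "2"), "V2", atoms1[atoms1$rxcui != "31", ],
                tibble::tibble(ndc = "00000000001", rxcui = "32"),
                retirements = tibble::tibble(cui1 = "31", cui2 = "32",
                                             cardinality = 1L),
                relationships = rels[rels$rxcui1 != "31", ])
  b <- build_dron(file.path(dir, c("1", "2")))
  expect_equal(nrow(b$graph$cds), 1L)
  expect_equal(b$graph$cds$rxcui, "32")
  inc <- ndc_included(b$registry)
  expect_equal(inc$resolved_rxcui, "32")
  expect_equal(b$graph$ndcs$parent_type, "CD")
})

test_that("a branded drug is re-parented when its clinical drug merges away", {
  dir <- withr::local_tempdir()
  atoms1 <- tibble::tibble(
    rxcui = c("11", "21", "31", "32", "41"),
    tty = c("IN", "SCDF", "SCD", "SCD", "SBD"),
    name = c("drug a", "form a", "prod one", "prod two", "brand one")
  )
  rels1 <- tibble::tibble(rxcui1 = c("21", "31", "32", "41"),
                          rela = c("has_ingredient", "isa", "isa", "tradename_of"),
                          rxcui2 = c("11", "21", "21", "31"))
  write_release(file.path(dir, "1"), "V1", atoms1, relationships = rels1)
  write_release(file.path(dir, "2"), "V2", atoms1[atoms1$rxcui != "31", ],
                retirements = tibble::tibble(cui1 = "31", cui2 = "32",
                                             cardinality = 1L),
                relationships = rels1[rels1$rxcui1 != "31", ])
  b <- build_dron(file.path(dir, c("1", "2")))
  expect_equal(b$graph$bds$cd_rxcui[b$graph$bds$rxcui == "41"], "32")
})

test_that("codes resolving to a non-product identifier are unattachable", {
  dir <- tempfile()
  atoms <- tibble::tibble(rxcui = c("11", "21", "31"),
                          tty = c("IN", "SCDF", "SCD"),
                          name = c("a", "b", "c"))
  rels <- tibble::tibble(rxcui1 = c("21", "31"), rela = c("has_ingredient", "isa"),
                         rxcui2 = c("11", "21"))
  # one code hangs off the ingredient: no CD/BD to attach to
  write_release(dir, "V1", atoms,
                tibble::tibble(ndc = c("00000000001", "00000000002"),
                               rxcui = c("31", "11")),
                relationships = rels)
  b <- build_dron(dir)
  expect_equal(sum(is.na(b$graph$ndcs$parent_type)), 1L)
  expect_equal(b$graph$ndcs$ndc[is.na(b$graph$ndcs$parent_type)], "00000000002")
  # attached = included - unattachable
  expect_equal(sum(!is.na(b$graph$ndcs$parent_type)),
               nrow(ndc_included(b$registry)) - 1L)
})

test_that("disposition queries are the union over bearing ingredients", {
  run <- cached_run()
  g <- run$build$graph
  for (d in g$dispositions$disposition) {
    bearers <- g$disposition_ingredient$in_rxcui[
      g$disposition_ingredient$disposition == d]
    expected <- sort(unique(unlist(lapply(bearers, function(b)
      ndcs_by_ingredient(g, b)))))
    expect_equal(ndcs_by_disposition(g, d), expected)
  }
  expect_warning(out <- ndcs_by_disposition(g, "no such disposition"),
                 "unknown disposition")
  expect_length(out, 0L)
})

test_that("entity counts on fixtures equal generator ground truth", {
  for (seed in c(101L, 5L)) {
    run <- cached_run(seed)
    expect_equal(entity_counts(run$build$graph), run$manifest$entity_counts)
    expect_true(validate_graph(run$build$graph)$valid)
  }
})

test_that("the store exports the normalized tables under their usual names", {
  run <- cached_run()
  dir <- withr::local_tempdir()
  export_store(run$build$graph, dir)
  files <- list.files(dir)
  expect_setequal(files, paste0(
    c("ingredient", "disposition", "clinical_drug_form", "clinical_drug",
      "branded_drug", "ndc", "rxcui", "rxnorm", "cdf_ingredient",
      "disposition_ingredient"), ".tsv"))
  rx <- readr::read_tsv(file.path(dir, "rxcui.tsv"), show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  # every identifier ever observed appears with its terminal mapping
  expect_true(all(run$build$provenance$entries$old_rxcui %in% rx$rxcui))
  rxnorm <- readr::read_tsv(file.path(dir, "rxnorm.tsv"), show_col_types = FALSE)
  expect_equal(nrow(rxnorm), run$config$n_releases)
})

test_that("store initialization requires a compacted provenance table", {
  p <- provenance_init()
  p$compacted <- FALSE
  expect_error(store_rxcui_table(p, tibble::tibble(ordinal = 1L, label = "V")),
               class = "dronr_uncompacted")
})
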