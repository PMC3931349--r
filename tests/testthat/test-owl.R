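# OWL document model, canonical serialization, module emission.

test_that("minted IRIs are zero-padded, sequential and overflow-checked", {
  expect_equal(mint_iris(1L, start = 1L),
               "http://purl.obolibrary.org/obo/DRON_00000001")
  expect_equal(mint_iris(3L, start = 20000L)[3],
               "http://purl.obolibrary.org/obo/DRON_00020002")
  expect_length(mint_iris(0L), 0L)
  expect_error(mint_iris(2L, start = 99999999L), class = "dronr_mint_overflow")
})

test_that("IRI assignment is invariant under input row permutation", {
  run <- cached_run()
  g <- run$build$graph
  perm <- g
  withr::with_seed(1, {
    for (nm in c("ingredients", "cdfs", "cds", "bds", "ndcs", "cdf_ingredient")) {
      perm[[nm]] <- perm[[nm]][sample(nrow(perm[[nm]])), ]
    }
  })
  m1 <- dron_modules(g, run$build$closure)
  m2 <- dron_modules(perm, run$build$closure)
  for (nm in names(m1)) expect_true(owl_equal(m1[[nm]], m2[[nm]]))
})

test_that("emission follows the six-step axiom patterns", {
  run <- cached_run()
  mods <- run$build$modules
  rxn <- mods[["dron-rxnorm"]]
  g <- run$build$graph
  obo <- "http://purl.obolibrary.org/obo/"
  hpp <- paste0(obo, "DRON_00010000")
  drug_product <- paste0(obo, "DRON_00000005")
  packaged <- paste0(obo, "DRON_00000010")

  iri_of <- function(rxcui) {
    rxn$annotations$iri[rxn$annotations$prop == paste0(obo, "DRON_00010001") &
                          rxn$annotations$value == rxcui][1]
  }
  # step 4: a clinical drug is a subclass of its form
  cd <- g$cds[!g$cds$dangling, ][1, ]
  expect_equal(rxn$subclass_named$super[rxn$subclass_named$sub == iri_of(cd$rxcui)],
               iri_of(cd$cdf_rxcui))
  # step 3: each form sits under 'drug product' with one part restriction
  # per ingredient
  cdf_iri <- iri_of(cd$cdf_rxcui)
  expect_true(drug_product %in%
                rxn$subclass_named$super[rxn$subclass_named$sub == cdf_iri])
  n_ing <- sum(g$cdf_ingredient$cdf_rxcui == cd$cdf_rxcui)
  expect_equal(sum(rxn$subclass_some$sub == cdf_iri &
                     rxn$subclass_some$prop == hpp), n_ing)
  # step 6: every packaged product under 'packaged drug product' with exactly
  # one part restriction on its drug
  pkg <- rxn$subclass_named$sub[rxn$subclass_named$super == packaged]
  expect_length(pkg, sum(!is.na(g$ndcs$parent_type)))
  counts <- table(factor(rxn$subclass_some$sub[rxn$subclass_some$prop == hpp &
                                                 rxn$subclass_some$sub %in% pkg],
                         levels = pkg))
  expect_true(all(counts == 1L))
  # every release-derived class carries exactly one identifier annotation
  has_rx <- rxn$annotations[rxn$annotations$prop == paste0(obo, "DRON_00010001"), ]
  expect_equal(sort(unique(has_rx$iri)), sort(rxn$classes$iri))
  expect_false(anyDuplicated(has_rx$iri) > 0)
})

test_that("classes are routed to modules by origin, per-module counts match", {
  run <- cached_run()
  counts <- module_class_counts(run$build$modules)
  expect_equal(counts, run$manifest$module_counts)
  expect_equal(nrow(run$build$modules[["dron-full"]]$classes), 0L)
  expect_length(run$build$modules[["dron-full"]]$imports, 4L)
  # a class lives in exactly one module
  all_iris <- unlist(lapply(run$build$modules, function(m) m$classes$iri))
  expect_false(anyDuplicated(all_iris) > 0)
})

test_that("serialize -> parse -> serialize is a byte-level fixed point", {
  run <- cached_run()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dron(run$build$modules, d1)
  back <- read_dron(d1)
  write_dron(back, d2)
  for (nm in names(run$build$modules)) {
    f1 <- file.path(d1, paste0(nm, ".owl")); f2 <- file.path(d2, paste0(nm, ".owl"))
    expect_identical(readLines(f1), readLines(f2))
    expect_true(owl_equal(run$build$modules[[nm]], back[[nm]]))
  }
})

test_that("emission is byte-identical across runs on identical input", {
  run <- cached_run()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dron(dron_modules(run$build$graph, run$build$closure), d1)
  write_dron(dron_modules(run$build$graph, run$build$closure), d2)
  for (nm in names(run$build$modules)) {
    expect_identical(readLines(file.path(d1, paste0(nm, ".owl"))),
                     readLines(file.path(d2, paste0(nm, ".owl"))))
  }
})

test_that("the structural consistency check accepts emitted sets and flags damage", {
  run <- cached_run()
  ck <- check_modules(run$build$modules)
  expect_true(ck$valid)
  expect_length(ck$unsatisfiable, 0L)
  # an undeclared superclass is caught
  broken <- run$build$modules
  broken[["dron-rxnorm"]]$subclass_named$super[1] <- "http://example.org/ghost"
  expect_false(check_modules(broken)$valid)
  # a subclass cycle is caught
  cyc <- run$build$modules
  up <- "http://purl.obolibrary.org/obo/DRON_00000005"
  cyc[["dron-upper"]]$subclass_named <- dplyr::bind_rows(
    cyc[["dron-upper"]]$subclass_named,
    tibble::tibble(sub = "http://purl.obolibrary.org/obo/BFO_0000040", super = up)
  )
  expect_false(check_modules(cyc)$valid)
})

test_that("an empty graph still yields a valid, loadable curated upper module", {
  atoms <- tibble::tibble(rxcui = character(), tty = character(),
                          name = character(), ordinal = integer())
  rels <- tibble::tibble(rxcui1 = character(), rela = character(),
                         rxcui2 = character())
  maps <- tibble::tibble(rxcui = character(), name = character(),
                         target_iri = character(), source = character(),
                         matched_via = character())
  g <- build_entity_graph(atoms, rels, provenance_init(), maps)
  g <- attach_ndcs(g, tibble::tibble(ndc = character(),
                                     resolved_rxcui = character(),
                                     orphaned = logical()))
  mods <- dron_modules(g)
  d <- withr::local_tempdir()
  write_dron(mods, d)
  upper <- read_owl(file.path(d, "dron-upper.owl"))
  expect_equal(nrow(upper$classes), nrow(dron_upper()$classes))
  expect_true(check_modules(read_dron(d))$valid)
})

test_that("labels with XML metacharacters survive a round trip", {
  doc <- owl_doc(
    ontology_iri = "http://example.org/x.owl",
    classes = tibble::tibble(iri = "http://example.org/A",
                             label = "5% dextrose <in> water & salt \"mix\"")
  )
  f <- withr::local_tempfile(fileext = ".owl")
  write_owl(doc, f)
  expect_true(owl_equal(doc, read_owl(f)))
})
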