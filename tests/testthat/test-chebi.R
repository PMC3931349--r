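# Lexical mapping against a ChEBI-style snapshot, closure import, role mining.

mini_snapshot <- function() {
  obo <- paste0("http://purl.obolibrary.org/obo/")
  doc <- owl_doc(
    ontology_iri = "http://example.org/mini.owl",
    object_properties = tibble::tibble(iri = paste0(obo, "RO_0000087"),
                                       label = "has role"),
    classes = tibble::tibble(
      iri = paste0(obo, c("CHEBI_47426", "CHEBI_35", "CHEBI_36", "CHEBI_24431",
                          "CHEBI_50906", "CHEBI_90", "CHEBI_91")),
      label = c("furosemide", "midgroup", "aspirin", "chemical entity",
                "role", "beta-adrenergic antagonist", "growth hormone")
    ),
    annotations = tibble::tibble(
      iri = paste0(obo, c("CHEBI_47426", "CHEBI_36", "CHEBI_91")),
      prop = c(paste0(NS_oboInOwl(), "hasRelatedSynonym"),
               paste0(NS_oboInOwl(), "hasExactSynonym"),
               paste0(NS_oboInOwl(), "hasRelatedSynonym")),
      value = c("frusemide", "acetylsalicylic acid", "somatropin"),
      is_resource = FALSE
    ),
    subclass_named = tibble::tibble(
      sub = paste0(obo, c("CHEBI_47426", "CHEBI_35", "CHEBI_36",
                          "CHEBI_90", "CHEBI_91")),
      super = paste0(obo, c("CHEBI_35", "CHEBI_24431", "CHEBI_24431",
                            "CHEBI_50906", "CHEBI_50906"))
    ),
    subclass_some = tibble::tibble(
      sub = paste0(obo, "CHEBI_36"), prop = paste0(obo, "RO_0000087"),
      filler = paste0(obo, "CHEBI_90")
    )
  )
  f <- tempfile(fileext = ".owl")
  write_owl(doc, f)
  read_ontology(f)
}

NS_oboInOwl <- function() "http://www.geneontology.org/formats/oboInOwl#"

test_that("the lexical index covers labels and both synonym types", {
  snap <- mini_snapshot()
  idx <- build_lexical_index(snap)
  obo <- "http://purl.obolibrary.org/obo/"
  hit <- idx[idx$key == "furosemide", ]
  expect_equal(hit$iri, paste0(obo, "CHEBI_47426"))
  expect_equal(hit$annotation_type, "label")
  # a related synonym is a second key to the same class
  expect_equal(idx$iri[idx$key == "frusemide"], paste0(obo, "CHEBI_47426"))
  expect_equal(idx$annotation_type[idx$key == "frusemide"], "related_synonym")
  expect_equal(idx$annotation_type[idx$key == "acetylsalicylic acid"], "exact_synonym")
  # empty ontology gives an empty index
  empty <- mini_snapshot()
  empty$classes <- empty$classes[0, ]
  empty$synonyms <- empty$synonyms[0, ]
  expect_equal(nrow(build_lexical_index(empty)), 0L)
})

test_that("ingredients match by normalized exact lookup with source partition", {
  snap <- mini_snapshot()
  idx <- build_lexical_index(snap)
  atoms <- tibble::tibble(
    rxcui = c("4603", "2", "3", "4"),
    tty = "IN",
    name = c("  FUROSEMIDE ", "Acetylsalicylic Acid", "ginger extract", "somatropin")
  )
  maps <- match_ingredients(atoms, idx)
  m <- function(r) maps[maps$rxcui == r, ]
  # worked example: furosemide lands on its canonical accession via label
  expect_equal(m("4603")$target_iri, "http://purl.obolibrary.org/obo/CHEBI_47426")
  expect_equal(m("4603")$matched_via, "label")
  expect_equal(m("2")$matched_via, "exact_synonym")
  # no match: minted later, parented under processed material
  expect_equal(m("3")$source, "DRON")
  expect_equal(m("3")$matched_via, "none")
  # the override beats the growth-hormone role decoy
  expect_equal(m("4")$source, "PRO")
  expect_equal(m("4")$matched_via, "override")
  expect_match(m("4")$target_iri, "PR_")
  # partition: every ingredient in exactly one source class
  expect_true(all(maps$source %in% c("CHEBI", "PRO", "DRON")))
  expect_equal(nrow(maps), 4L)
})

test_that("ambiguous names are reported for curation, not mapped", {
  snap <- mini_snapshot()
  snap$classes <- dplyr::bind_rows(
    snap$classes,
    tibble::tibble(iri = "http://purl.obolibrary.org/obo/CHEBI_999",
                   label = "furosemide")
  )
  idx <- build_lexical_index(snap)
  atoms <- tibble::tibble(rxcui = "4603", tty = "IN", name = "furosemide")
  maps <- match_ingredients(atoms, idx)
  expect_equal(maps$source, "DRON")
  expect_equal(maps$matched_via, "none")
  report <- attr(maps, "curation_report")
  expect_equal(nrow(report), 1L)
  expect_match(report$candidates, "CHEBI_47426")
  expect_match(report$candidates, "CHEBI_999")
})

test_that("import_closure equals brute-force reachability and is ancestor-closed", {
  snap <- mini_snapshot()
  obo <- "http://purl.obolibrary.org/obo/"
  cl <- import_closure(paste0(obo, c("CHEBI_47426", "CHEBI_36")), snap)
  # leaf -> mid -> root plus second leaf sharing the root: 4 classes, 3 edges
  expect_setequal(cl$classes$iri,
                  paste0(obo, c("CHEBI_47426", "CHEBI_35", "CHEBI_36", "CHEBI_24431")))
  expect_equal(nrow(cl$edges), 3L)
  # ancestor-closed: every parent of a returned class is returned
  expect_true(all(cl$edges$parent %in% cl$classes$iri))
  # brute-force reachability oracle over the raw edge list
  reach <- function(start, edges) {
    seen <- start
    repeat {
      nxt <- setdiff(edges$parent[edges$child %in% seen], seen)
      if (length(nxt) == 0L) return(seen)
      seen <- c(seen, nxt)
    }
  }
  expect_setequal(cl$classes$iri,
                  reach(paste0(obo, c("CHEBI_47426", "CHEBI_36")), snap$subclass))
})

test_that("role mining links bearers, honours exclusions and curated lists", {
  run <- cached_run()
  links <- run$build$disposition_links
  plan_ing <- dronr:::fixture_plan(run$config)$ingredients
  rx <- function(nm) plan_ing$rxcui[plan_ing$name == nm]
  l_type <- "function-inhibiting L-type voltage-gated calcium channel binding disposition"
  t_type <- "function-inhibiting T-type voltage-gated calcium channel binding disposition"
  beta <- "non-activating competitive beta-adrenergic receptor binding disposition"
  # mined from the role: verapamil yes; ethosuximide excluded from L-type
  expect_true(rx("verapamil") %in% links$rxcui[links$disposition == l_type])
  expect_false(rx("ethosuximide") %in% links$rxcui[links$disposition == l_type])
  # the curated list places ethosuximide under the T-type disposition
  expect_true(rx("ethosuximide") %in% links$rxcui[links$disposition == t_type])
  expect_setequal(links$rxcui[links$disposition == beta],
                  c(rx("metoprolol"), rx("propranolol")))
  # a missing role label is an error naming the role
  snap <- read_ontology(run$chebi)
  snap$classes <- snap$classes[snap$classes$label != "proton pump inhibitor" |
                                 is.na(snap$classes$label), ]
  expect_error(
    mine_disposition_links(snap, run$build$mappings,
                           dplyr::mutate(plan_ing, tty = "IN")),
    class = "dronr_missing_role"
  )
})

test_that("match tallies report counts per annotation type", {
  run <- cached_run()
  tally <- match_tally(run$build$mappings)
  expect_setequal(tally$matched_via,
                  run$manifest$match_tally$matched_via)
  expect_equal(tally$n[tally$matched_via == "override"], 1L)
  expect_equal(sum(tally$n), nrow(run$build$mappings))
})

test_that("the OBO serialization parses to the same snapshot tables", {
  f <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: CHEBI:47426", "name: furosemide",
    "synonym: \"frusemide\" RELATED []", "is_a: CHEBI:24431 ! chemical entity",
    "relationship: has_role CHEBI:90", "",
    "[Term]", "id: CHEBI:24431", "name: chemical entity", "",
    "[Term]", "id: CHEBI:90", "name: loop diuretic",
    "is_a: CHEBI:50906", "",
    "[Term]", "id: CHEBI:50906", "name: role", "",
    "[Term]", "id: CHEBI:99", "name: obsolete thing", "is_obsolete: true"
  ), f)
  snap <- read_ontology(f)
  obo <- "http://purl.obolibrary.org/obo/"
  expect_setequal(snap$classes$iri,
                  paste0(obo, c("CHEBI_47426", "CHEBI_24431", "CHEBI_90", "CHEBI_50906")))
  expect_equal(snap$synonyms$value, "frusemide")
  expect_equal(snap$synonyms$type, "related_synonym")
  expect_equal(snap$roles$iri, paste0(obo, "CHEBI_47426"))
  expect_equal(snap$roles$role_iri, paste0(obo, "CHEBI_90"))
  expect_equal(snap$role_form, "annotation")
})
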