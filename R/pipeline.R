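# End-to-end orchestration: chronological ingestion, provenance maintenance,
# NDC accumulation, ChEBI mapping, entity-graph construction and module
# emission.

#' Build the full drug ontology from a chronological release series
#'
#' Runs the three-stage pipeline: (1) extraction — each release directory is
#' parsed in order, atoms and relationships are accumulated, the provenance
#' table is updated (retirement detection, record classification, transitive
#' closure) and every NDC observation is recorded; (2) normalization — the
#' registry is finalized against the compacted provenance table, ingredients
#' are lexically matched against the ChEBI snapshot, disposition links are
#' mined, and the normalized entity graph is built and its packaged products
#' attached; (3) emission — the five OWL modules are generated (and written
#' when `out_dir` is given).
#'
#' @param release_dirs release directories in chronological order.
#' @param chebi ChEBI-style snapshot file (OWL RDF/XML or OBO), or `NULL` to
#'   skip mapping (all ingredients are then minted).
#' @param overrides ingredient-mapping overrides, defaults to the shipped
#'   curated file.
#' @param out_dir if non-`NULL`, the module files are written here.
#' @param strict parse mode for the release files.
#' @return A `dron_build` object: list with `releases` (version tibble),
#'   `provenance`, `registry`, `mappings`, `closure`, `disposition_links`,
#'   `graph` and `modules`.
#' @export
build_dron <- function(release_dirs, chebi = NULL,
                       overrides = dron_overrides(), out_dir = NULL,
                       strict = TRUE) {
  prov <- provenance_init()
  registry <- ndc_registry_init()
  known_ids <- character()
  atoms_acc <- tibble(rxcui = character(), tty = character(),
                      name = character(), ordinal = integer())
  rels_acc <- tibble(rxcui1 = character(), rela = character(), rxcui2 = character())

  for (i in seq_along(release_dirs)) {
    rel <- read_release(release_dirs[[i]], ordinal = i, strict = strict)
    prov <- update_provenance(prov, rel, known_ids)
    registry <- ndc_accumulate(registry, rel)
    atoms_acc <- bind_rows(atoms_acc, mutate(rel$atoms, ordinal = i))
    rels_acc <- distinct(bind_rows(rels_acc, rel$relationships))
    known_ids <- union(known_ids, c(rel$atoms$rxcui, rel$ndc_attributes$rxcui))
  }
  registry <- ndc_finalize(registry, prov)

  # one row per (rxcui, tty): the most recently observed name
  atoms <- atoms_acc |>
    arrange(.data$rxcui, .data$tty, desc(.data$ordinal)) |>
    group_by(.data$rxcui, .data$tty) |>
    summarise(name = .data$name[1L], ordinal = max(.data$ordinal), .groups = "drop")

  if (!is.null(chebi)) {
    snapshot <- read_ontology(chebi)
    index <- build_lexical_index(snapshot)
    mappings <- match_ingredients(atoms, index, overrides)
    closure <- import_closure(
      mappings$target_iri[mappings$source == "CHEBI" & !is.na(mappings$target_iri)],
      snapshot
    )
    links <- mine_disposition_links(snapshot, mappings, atoms)
  } else {
    ins <- atoms |> filter(.data$tty == "IN")
    mappings <- tibble(rxcui = ins$rxcui, name = ins$name,
                       target_iri = NA_character_, source = "DRON",
                       matched_via = "none")
    closure <- list(classes = empty_chr_tbl("iri", "label"),
                    edges = empty_chr_tbl("child", "parent"))
    links <- tibble(disposition = character(), rxcui = character())
  }

  graph <- build_entity_graph(atoms, rels_acc, prov, mappings, links,
                              versions = registry$versions)
  graph <- attach_ndcs(graph, ndc_included(registry))
  modules <- dron_modules(graph, closure)
  if (!is.null(out_dir)) write_dron(modules, out_dir)

  structure(
    list(releases = registry$versions, provenance = prov, registry = registry,
         mappings = mappings, closure = closure, disposition_links = links,
         graph = graph, modules = modules),
    class = "dron_build"
  )
}

#' @export
print.dron_build <- function(x, ...) {
  cat("<dron_build> ", nrow(x$releases), " release(s)\n", sep = "")
  print(x$graph)
  print(x$modules)
  invisible(x)
}

#' Entity counts of a built graph
#'
#' @param graph a `dron_graph`.
#' @return Named integer vector (ingredient, disposition, cdf, cd, bd, ndc;
#'   the ndc count is attached packaged products).
#' @export
entity_counts <- function(graph) {
  c(ingredient = nrow(graph$ingredients),
    disposition = nrow(graph$dispositions),
    cdf = nrow(graph$cdfs),
    cd = nrow(graph$cds),
    bd = nrow(graph$bds),
    ndc = sum(!is.na(graph$ndcs$parent_type)))
}
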