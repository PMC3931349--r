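# Emission of the five-module OWL 2 artifact: dron-upper (hand-curated),
# dron-chebi (matched ingredient classes + their is-a closure), dron-pro
# (protein classes), dron-rxnorm (everything mined from the release series)
# and dron-full (imports only).

DRON_BASE <- "http://purl.obolibrary.org/obo/dron/"
DRON_MODULE_NAMES <- c("dron-full", "dron-chebi", "dron-rxnorm", "dron-pro", "dron-upper")

dron_iri <- function(n) sprintf("%sDRON_%08d", OBO_PREFIX, n)

# curated upper-module IRIs (stable, hand-assigned in the low range)
IRI_DRUG_PRODUCT <- dron_iri(5)
IRI_PACKAGED <- dron_iri(10)
IRI_TABLET <- dron_iri(15)
IRI_CAPSULE <- dron_iri(20)
IRI_CLINICAL_ROLE <- dron_iri(25)
IRI_DISPOSITIONS <- setNames(vapply(31:36, dron_iri, character(1L)), NULL)
IRI_HAS_PROPER_PART <- dron_iri(10000)
IRI_HAS_RXCUI <- dron_iri(10001)
IRI_BEARER_OF <- paste0(OBO_PREFIX, "RO_0000053")
IRI_PROCESSED_MATERIAL <- paste0(OBO_PREFIX, "OBI_0000047")
IRI_MATERIAL_ENTITY <- paste0(OBO_PREFIX, "BFO_0000040")
IRI_ROLE <- paste0(OBO_PREFIX, "BFO_0000023")
IRI_DISPOSITION_BFO <- paste0(OBO_PREFIX, "BFO_0000016")
IRI_PROTEIN <- paste0(OBO_PREFIX, "PR_000000001")
IRI_DEFINITION <- paste0(OBO_PREFIX, "IAO_0000115")

# first identifier available to programmatic minting; everything below is
# reserved for curated content
MINT_START <- 20000L

#' Mint sequential DrOn class IRIs
#'
#' IRIs have the form `<obo-purl>/DRON_` followed by a zero-padded 8-digit
#' integer. The emitter assigns them after sorting entities by type, terminal
#' identifier and code, so the assignment is a pure function of the input
#' content, independent of row order.
#'
#' @param n how many IRIs to mint.
#' @param start first counter value.
#' @return Character vector of `n` IRIs.
#' @export
mint_iris <- function(n, start = MINT_START) {
  if (n == 0L) return(character())
  if (start + n - 1L > 99999999L) {
    dron_abort("IRI counter overflow", class = "dronr_mint_overflow")
  }
  vapply(seq.int(start, length.out = n), dron_iri, character(1L))
}

#' The hand-curated upper module
#'
#' Ships the static realist scaffold the generated modules hang from: 'drug
#' product' (defined as a material entity containing at least one scattered
#' molecular aggregate as part and bearing a clinical drug role), its unused
#' 'drug tablet' / 'drug capsule' subtypes, 'packaged drug product', 'clinical
#' drug role', the six molecular-disposition classes, stub declarations (IRI
#' plus label) for the external upper-level classes referenced ('material
#' entity', 'role', 'disposition', 'processed material', 'protein'), and the
#' three properties `has_proper_part`, `bearer_of` and `has_Rxcui`. All of
#' this content is static curation, never generated.
#'
#' @return A `dron_owl` document.
#' @export
dron_upper <- function() {
  disp <- dron_role_map()$disposition
  classes <- tibble(
    iri = c(IRI_DRUG_PRODUCT, IRI_PACKAGED, IRI_TABLET, IRI_CAPSULE,
            IRI_CLINICAL_ROLE, IRI_DISPOSITIONS,
            IRI_PROCESSED_MATERIAL, IRI_MATERIAL_ENTITY, IRI_ROLE,
            IRI_DISPOSITION_BFO),
    label = c("drug product", "packaged drug product", "drug tablet",
              "drug capsule", "clinical drug role", disp,
              "processed material", "material entity", "role", "disposition")
  )
  subclass_named <- tibble(
    sub = c(IRI_DRUG_PRODUCT, IRI_PACKAGED, IRI_TABLET, IRI_CAPSULE,
            IRI_CLINICAL_ROLE, IRI_DISPOSITIONS, IRI_PROCESSED_MATERIAL),
    super = c(IRI_MATERIAL_ENTITY, IRI_MATERIAL_ENTITY, IRI_DRUG_PRODUCT,
              IRI_DRUG_PRODUCT, IRI_ROLE,
              rep(IRI_DISPOSITION_BFO, length(IRI_DISPOSITIONS)),
              IRI_MATERIAL_ENTITY)
  )
  annotations <- tibble(
    iri = IRI_DRUG_PRODUCT,
    prop = IRI_DEFINITION,
    value = paste0("a material entity (1) containing at least one scattered ",
                   "molecular aggregate as part (the active ingredient) and ",
                   "(2) that is the bearer of a clinical drug role"),
    is_resource = FALSE
  )
  owl_doc(
    ontology_iri = paste0(DRON_BASE, "dron-upper.owl"),
    object_properties = tibble(iri = c(IRI_HAS_PROPER_PART, IRI_BEARER_OF),
                               label = c("has_proper_part", "bearer_of")),
    annotation_properties = tibble(iri = IRI_HAS_RXCUI, label = "has_Rxcui"),
    classes = classes,
    annotations = annotations,
    subclass_named = subclass_named
  )
}

disposition_iri <- function(labels) {
  IRI_DISPOSITIONS[match(labels, dron_role_map()$disposition)]
}

#' Emit the entity graph as the five-module ontology set
#'
#' Runs the six emission steps in their deliberate order: (1) ingredient
#' classes, reusing ChEBI and Protein Ontology IRIs where matched and minting
#' DrOn IRIs (children of 'processed material') otherwise; (2) disposition
#' links, as existential `bearer_of` restrictions on each bearing ingredient
#' class; (3) clinical drug forms under 'drug product' with one existential
#' `has_proper_part` restriction per ingredient; (4) clinical drugs as
#' subclasses of their form; (5) branded drugs as subclasses of their
#' clinical drug; (6) packaged products under 'packaged drug product', each
#' with exactly one `has_proper_part` restriction on its branded or clinical
#' drug. Every class derived from the release series carries exactly one
#' `has_Rxcui` annotation. Classes are routed to modules by origin: matched
#' ingredient classes and their is-a closure to dron-chebi, protein classes
#' to dron-pro, everything mined from the releases to dron-rxnorm, curated
#' content to dron-upper; dron-full only imports the other four.
#'
#' @param graph a validated `dron_graph` with NDCs attached.
#' @param closure ChEBI is-a closure from [import_closure()].
#' @return A `dron_modules` object: named list of five `dron_owl` documents.
#' @export
dron_modules <- function(graph, closure = list(classes = empty_chr_tbl("iri", "label"),
                                               edges = empty_chr_tbl("child", "parent"))) {
  v <- validate_graph(graph)
  if (!v$valid) {
    dron_abort(paste0("entity graph fails validation: ",
                      paste(v$problems, collapse = "; ")),
               class = "dronr_invalid_graph")
  }
  upper <- dron_upper()

  # deterministic IRI assignment: sort by entity type, then terminal
  # identifier, then code, before minting
  ing <- arrange(graph$ingredients, as.numeric(.data$rxcui))
  cdf <- arrange(graph$cdfs, as.numeric(.data$rxcui))
  cd <- arrange(graph$cds, as.numeric(.data$rxcui))
  bd <- arrange(graph$bds, as.numeric(.data$rxcui))
  ndc <- graph$ndcs |> filter(!is.na(.data$parent_type)) |>
    arrange(as.numeric(.data$rxcui), .data$ndc)

  minted_ing <- filter(ing, .data$source == "DRON")
  n_mint <- c(nrow(minted_ing), nrow(cdf), nrow(cd), nrow(bd), nrow(ndc))
  offs <- cumsum(c(0L, n_mint))
  minted_ing$iri <- mint_iris(n_mint[1L], MINT_START + offs[1L])
  cdf$iri <- mint_iris(n_mint[2L], MINT_START + offs[2L])
  cd$iri <- mint_iris(n_mint[3L], MINT_START + offs[3L])
  bd$iri <- mint_iris(n_mint[4L], MINT_START + offs[4L])
  ndc$iri <- mint_iris(n_mint[5L], MINT_START + offs[5L])

  ing <- ing |>
    left_join(select(minted_ing, "rxcui", minted = "iri"), by = "rxcui") |>
    mutate(iri = dplyr::coalesce(.data$target_iri, .data$minted))
  ing_iri <- setNames(ing$iri, ing$rxcui)
  cdf_iri <- setNames(cdf$iri, cdf$rxcui)
  cd_iri <- setNames(cd$iri, cd$rxcui)
  bd_iri <- setNames(bd$iri, bd$rxcui)

  rx_ann <- function(tbl) {
    tibble(iri = tbl$iri, prop = IRI_HAS_RXCUI, value = tbl$rxcui, is_resource = FALSE)
  }
  orphan_ann <- function(tbl) {
    t <- filter(tbl, .data$orphaned)
    tibble(iri = t$iri, prop = paste0(NS[["rdfs"]], "comment"),
           value = "orphaned: identifier disappeared with no retirement record",
           is_resource = FALSE)
  }

  # step 2: bearer_of restrictions, attached in the module of the ingredient
  bearer <- graph$disposition_ingredient |>
    mutate(sub = ing_iri[.data$in_rxcui],
           prop = IRI_BEARER_OF,
           filler = disposition_iri(.data$disposition)) |>
    select("sub", "prop", "filler")

  ing_chebi <- filter(ing, .data$source == "CHEBI")
  ing_pro <- filter(ing, .data$source == "PRO")
  ing_mint <- filter(ing, .data$source == "DRON")

  # dron-chebi: closure classes (snapshot labels win) + matched ingredients
  chebi_classes <- bind_rows(
    closure$classes,
    ing_chebi |> select("iri") |> mutate(label = NA_character_)
  ) |>
    group_by(.data$iri) |>
    summarise(label = if (any(!is.na(.data$label))) .data$label[!is.na(.data$label)][1L]
              else NA_character_, .groups = "drop")
  chebi_iris <- chebi_classes$iri
  chebi <- owl_doc(
    ontology_iri = paste0(DRON_BASE, "dron-chebi.owl"),
    classes = chebi_classes,
    annotations = bind_rows(rx_ann(ing_chebi), orphan_ann(ing_chebi)),
    subclass_named = select(closure$edges, sub = "child", super = "parent"),
    subclass_some = filter(bearer, .data$sub %in% chebi_iris)
  )

  pro_classes <- bind_rows(
    tibble(iri = IRI_PROTEIN, label = "protein"),
    select(ing_pro, "iri", label = "name")
  ) |> distinct(.data$iri, .keep_all = TRUE)
  pro <- owl_doc(
    ontology_iri = paste0(DRON_BASE, "dron-pro.owl"),
    classes = pro_classes,
    annotations = rx_ann(ing_pro),
    subclass_named = tibble(sub = ing_pro$iri, super = IRI_PROTEIN),
    subclass_some = filter(bearer, .data$sub %in% ing_pro$iri)
  )

  # dron-rxnorm: minted ingredients + CDFs + CDs + BDs + packaged products
  cdf_part <- graph$cdf_ingredient |>
    mutate(sub = cdf_iri[.data$cdf_rxcui], prop = IRI_HAS_PROPER_PART,
           filler = ing_iri[.data$in_rxcui]) |>
    select("sub", "prop", "filler")
  cd_sup <- tibble(sub = cd$iri,
                   super = if_else(cd$dangling, IRI_DRUG_PRODUCT,
                                   unname(cdf_iri[cd$cdf_rxcui])))
  bd_sup <- tibble(sub = bd$iri,
                   super = if_else(bd$dangling, IRI_DRUG_PRODUCT,
                                   unname(cd_iri[bd$cd_rxcui])))
  ndc_part <- tibble(sub = ndc$iri, prop = IRI_HAS_PROPER_PART,
                     filler = if_else(ndc$parent_type == "BD",
                                      unname(bd_iri[ndc$rxcui]),
                                      unname(cd_iri[ndc$rxcui])))
  rxnorm_classes <- bind_rows(
    select(ing_mint, "iri", label = "name"),
    select(cdf, "iri", label = "name"),
    select(cd, "iri", label = "name"),
    select(bd, "iri", label = "name"),
    ndc |> mutate(label = paste0("NDC ", .data$ndc)) |> select("iri", "label")
  )
  rxnorm <- owl_doc(
    ontology_iri = paste0(DRON_BASE, "dron-rxnorm.owl"),
    classes = rxnorm_classes,
    annotations = bind_rows(
      rx_ann(ing_mint), rx_ann(cdf), rx_ann(cd), rx_ann(bd), rx_ann(ndc),
      orphan_ann(ing_mint), orphan_ann(cdf), orphan_ann(cd), orphan_ann(bd),
      orphan_ann(ndc)
    ),
    subclass_named = bind_rows(
      tibble(sub = ing_mint$iri, super = IRI_PROCESSED_MATERIAL),
      tibble(sub = cdf$iri, super = IRI_DRUG_PRODUCT),
      cd_sup, bd_sup,
      tibble(sub = ndc$iri, super = IRI_PACKAGED)
    ),
    subclass_some = bind_rows(
      filter(bearer, .data$sub %in% ing_mint$iri),
      cdf_part, ndc_part
    )
  )

  full <- owl_doc(
    ontology_iri = paste0(DRON_BASE, "dron-full.owl"),
    imports = paste0(DRON_BASE, c("dron-chebi.owl", "dron-rxnorm.owl",
                                  "dron-pro.owl", "dron-upper.owl"))
  )
  structure(
    list(`dron-full` = full, `dron-chebi` = chebi, `dron-rxnorm` = rxnorm,
         `dron-pro` = pro, `dron-upper` = upper),
    class = "dron_modules"
  )
}

#' @export
print.dron_modules <- function(x, ...) {
  cat("<dron_modules>\n")
  for (nm in names(x)) {
    cat("  ", format(nm, width = 12), nrow(x[[nm]]$classes), "classes\n")
  }
  invisible(x)
}

#' Class counts per emitted module
#'
#' @param modules a `dron_modules` set.
#' @return Named integer vector of class counts.
#' @export
module_class_counts <- function(modules) {
  vapply(modules, function(m) nrow(m$classes), integer(1L))
}

#' Write the five ontology modules as RDF/XML files
#'
#' One file per module (`dron-full.owl`, `dron-chebi.owl`, `dron-rxnorm.owl`,
#' `dron-pro.owl`, `dron-upper.owl`); output is byte-deterministic for
#' identical input (see [write_owl()]).
#'
#' @param modules a `dron_modules` set.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dron <- function(modules, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(modules), function(nm) {
    write_owl(modules[[nm]], file.path(dir, paste0(nm, ".owl")))
  }, character(1L))
  invisible(paths)
}

#' Read a written module set back from disk
#'
#' @param dir directory holding the five `.owl` files.
#' @return A `dron_modules` set.
#' @export
read_dron <- function(dir) {
  mods <- lapply(DRON_MODULE_NAMES, function(nm) {
    read_owl(file.path(dir, paste0(nm, ".owl")))
  })
  structure(setNames(mods, DRON_MODULE_NAMES), class = "dron_modules")
}

#' Structural consistency check of an emitted module set
#'
#' The emitted ontologies use only class declarations, SubClassOf axioms with
#' named or existential-restriction superclasses, and annotations: a
#' bottom-free Horn fragment in which no class can be unsatisfiable. The
#' check verifies that profile holds and that the structure is coherent:
#' exactly five modules with dron-full importing (and only importing) the
#' other four; every class declared in exactly one module; every named
#' superclass, restriction filler and property reference declared somewhere
#' in the set; the named-subclass graph acyclic; and every packaged-product
#' class carrying exactly one `has_proper_part` restriction.
#'
#' @param modules a `dron_modules` set.
#' @return A list with `valid`, `problems` (character vector) and
#'   `unsatisfiable` (character vector of class IRIs, empty when the profile
#'   holds).
#' @export
check_modules <- function(modules) {
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(identical(sort(names(modules)), sort(DRON_MODULE_NAMES)),
      "module set must contain exactly the five modules")
  chk(length(modules[["dron-full"]]$imports) == 4L &&
        nrow(modules[["dron-full"]]$classes) == 0L,
      "dron-full must contain only the four imports")

  all_classes <- unlist(lapply(modules, function(m) m$classes$iri))
  chk(!anyDuplicated(all_classes), "class declared in more than one module")

  props <- unique(unlist(lapply(modules, function(m)
    c(m$object_properties$iri, m$annotation_properties$iri))))
  named <- bind_rows(lapply(modules, function(m) m$subclass_named))
  somes <- bind_rows(lapply(modules, function(m) m$subclass_some))
  chk(all(named$sub %in% all_classes) && all(named$super %in% all_classes),
      "subclass axiom references an undeclared class")
  chk(all(somes$filler %in% all_classes),
      "restriction filler references an undeclared class")
  chk(all(somes$prop %in% props),
      "restriction uses an undeclared object property")

  # acyclicity of the named-subclass graph (iterative leaf stripping)
  if (nrow(named) > 0L) {
    g <- named
    repeat {
      sinks <- setdiff(g$super, g$sub)
      keep <- !g$super %in% sinks
      if (all(keep)) break
      g <- g[keep, ]
      if (nrow(g) == 0L) break
    }
    chk(nrow(g) == 0L, "cycle in the subclass hierarchy")
  }

  pkg <- named$sub[named$super == IRI_PACKAGED]
  part_counts <- table(factor(somes$sub[somes$prop == IRI_HAS_PROPER_PART &
                                          somes$sub %in% pkg], levels = pkg))
  chk(all(part_counts == 1L),
      "packaged-product class without exactly one has_proper_part restriction")

  # every clinical/branded drug chain reaches 'drug product'
  rxn <- modules[["dron-rxnorm"]]
  up <- setNames(named$super, named$sub)
  reaches <- function(iri) {
    seen <- character()
    while (!is.na(iri)) {
      if (iri == IRI_DRUG_PRODUCT) return(TRUE)
      if (iri %in% seen) return(FALSE)
      seen <- c(seen, iri)
      iri <- unname(up[iri]) %||% NA_character_
    }
    FALSE
  }
  rxn_named <- rxn$subclass_named
  drug_subs <- rxn_named$sub[rxn_named$super == IRI_DRUG_PRODUCT |
                               rxn_named$super %in% rxn$classes$iri]
  chk(all(vapply(drug_subs, reaches, logical(1L))),
      "drug product class whose subclass chain does not reach 'drug product'")

  list(valid = length(problems) == 0L, problems = problems,
       unsatisfiable = character())
}
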