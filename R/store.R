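# The normalized entity model: ingredients, dispositions, clinical drug forms
# (CDF), clinical drugs (CD), branded drugs (BD) and packaged products (one
# per NDC), all keyed by terminal RXCUI so concepts merged by provenance
# collapse to a single entity.

#' Initialize the identifier and version tables of the normalized store
#'
#' Every identifier ever observed is listed with its terminal mapping and
#' status; identifiers entered in error or split are flagged here and excluded
#' from entity creation. The version table lists the ingested releases.
#'
#' @param prov a compacted `dron_provenance` table.
#' @param versions tibble with `ordinal`, `label` of the ingested releases.
#' @return A list with tibbles `rxcui` (`rxcui`, `terminal`, `status`) and
#'   `rxnorm` (`ordinal`, `label`).
#' @export
store_rxcui_table <- function(prov, versions) {
  if (!prov$compacted) {
    dron_abort("provenance table must be compacted before initializing the store",
               class = "dronr_uncompacted")
  }
  ids <- unique(c(prov$observed_current, prov$entries$old_rxcui))
  res <- resolve_rxcui(ids, prov)
  list(
    rxcui = res |> select(rxcui = "rxcui", terminal = "terminal", status = "kind") |>
      arrange(.data$rxcui),
    rxnorm = arrange(versions, .data$ordinal)
  )
}

# pick one representative row per terminal identifier: prefer the terminal
# concept's own atom, then the most recently observed name
collapse_entities <- function(atoms_res) {
  atoms_res |>
    mutate(self = .data$rxcui == .data$terminal) |>
    arrange(.data$terminal, desc(.data$self), desc(.data$ordinal), .data$rxcui) |>
    group_by(.data$terminal) |>
    summarise(name = .data$name[1L],
              orphaned = all(.data$kind == STATUS_ORPHANED), .groups = "drop") |>
    rename(rxcui = "terminal")
}

#' Build the normalized entity graph
#'
#' Creates one entity per terminal identifier per type (CDF from SCDF, CD
#' from SCD, BD from SBD, ingredient from IN), remapping every relationship
#' endpoint through provenance resolution so merged concepts collapse to one
#' entity. Relationship endpoints resolving to entered-in-error or split
#' identifiers are dropped with a log line. A CD whose CDF link never
#' appeared (or resolved away) is kept and flagged dangling; it is parented
#' directly under 'drug product' at emission so its NDCs are not lost.
#'
#' @param atoms accumulated atom tibble across all releases, with columns
#'   `rxcui`, `tty`, `name`, `ordinal` (release of observation).
#' @param relationships accumulated relationship tibble (`rxcui1`, `rela`,
#'   `rxcui2`).
#' @param prov a compacted `dron_provenance` table.
#' @param mappings ingredient mappings from [match_ingredients()].
#' @param disposition_links tibble `disposition`, `rxcui` from
#'   [mine_disposition_links()].
#' @param versions tibble `ordinal`, `label`.
#' @return A `dron_graph` object.
#' @export
build_entity_graph <- function(atoms, relationships, prov, mappings,
                               disposition_links = tibble(disposition = character(),
                                                          rxcui = character()),
                               versions = tibble(ordinal = integer(), label = character())) {
  res <- resolve_rxcui(unique(atoms$rxcui), prov)
  atoms_res <- atoms |>
    left_join(res, by = "rxcui") |>
    filter(!.data$kind %in% c(STATUS_ERROR, STATUS_SPLIT))

  ent <- function(tty) collapse_entities(filter(atoms_res, .data$tty == !!tty))
  ingredients <- ent("IN")
  cdfs <- ent("SCDF")
  cds <- ent("SCD")
  bds <- ent("SBD")

  ingredients <- ingredients |>
    left_join(select(mappings, "rxcui", "target_iri", "source", "matched_via"),
              by = "rxcui") |>
    mutate(source = dplyr::coalesce(.data$source, "DRON"),
           matched_via = dplyr::coalesce(.data$matched_via, "none"))

  # remap relationship endpoints to terminal identifiers
  rel_ids <- unique(c(relationships$rxcui1, relationships$rxcui2))
  rmap <- resolve_rxcui(rel_ids, prov)
  rel <- relationships |>
    left_join(rmap |> select(rxcui1 = "rxcui", t1 = "terminal", k1 = "kind"), by = "rxcui1") |>
    left_join(rmap |> select(rxcui2 = "rxcui", t2 = "terminal", k2 = "kind"), by = "rxcui2")
  dropped <- rel |> filter(.data$k1 %in% c(STATUS_ERROR, STATUS_SPLIT) |
                             .data$k2 %in% c(STATUS_ERROR, STATUS_SPLIT))
  if (nrow(dropped) > 0L) {
    dron_log(nrow(dropped), " relationship(s) with error/split endpoints dropped")
  }
  # a surviving concept's own assertions take precedence over relationships
  # inherited from concepts merged into it: otherwise a merge would graft the
  # victim's parent link onto the survivor alongside its own
  rel <- rel |>
    anti_join(dropped, by = c("rxcui1", "rela", "rxcui2")) |>
    mutate(self = .data$rxcui1 == .data$t1) |>
    group_by(.data$rela, .data$t1) |>
    filter(.data$self | !any(.data$self)) |>
    ungroup() |>
    distinct(rela = .data$rela, from = .data$t1, to = .data$t2)

  cdf_ingredient <- rel |>
    filter(.data$rela == "has_ingredient",
           .data$from %in% cdfs$rxcui, .data$to %in% ingredients$rxcui) |>
    distinct(cdf_rxcui = .data$from, in_rxcui = .data$to) |>
    arrange(.data$cdf_rxcui, .data$in_rxcui)

  one_parent <- function(children, rel_label, parent_pool, parent_col) {
    links <- rel |>
      filter(.data$rela == rel_label, .data$from %in% children$rxcui,
             .data$to %in% parent_pool) |>
      distinct(.data$from, .data$to)
    multi <- links |> dplyr::count(.data$from) |> filter(.data$n > 1L)
    if (nrow(multi) > 0L) {
      dron_log(nrow(multi), " entit(ies) with multiple ", rel_label,
               " parents after provenance remap; smallest terminal kept")
      links <- links |> arrange(.data$from, .data$to) |> group_by(.data$from) |>
        slice(1L) |> ungroup()
    }
    children |>
      left_join(setNames(links, c("rxcui", parent_col)), by = "rxcui") |>
      mutate(dangling = is.na(.data[[parent_col]]))
  }
  cds <- one_parent(cds, "isa", cdfs$rxcui, "cdf_rxcui")
  bds <- one_parent(bds, "tradename_of", cds$rxcui, "cd_rxcui")
  n_dang <- sum(cds$dangling) + sum(bds$dangling)
  if (n_dang > 0L) dron_log(n_dang, " drug product(s) without a parent link; flagged dangling")

  dispositions <- tibble(disposition = dron_role_map()$disposition)
  disposition_ingredient <- disposition_links |>
    filter(.data$rxcui %in% ingredients$rxcui) |>
    distinct(disposition = .data$disposition, in_rxcui = .data$rxcui) |>
    arrange(.data$disposition, .data$in_rxcui)

  structure(
    list(ingredients = arrange(ingredients, .data$rxcui),
         dispositions = dispositions,
         cdfs = arrange(cdfs, .data$rxcui),
         cds = arrange(cds, .data$rxcui),
         bds = arrange(bds, .data$rxcui),
         cdf_ingredient = cdf_ingredient,
         disposition_ingredient = disposition_ingredient,
         ndcs = tibble(ndc = character(), rxcui = character(),
                       parent_type = character(), orphaned = logical()),
         rxcui_table = store_rxcui_table(prov, versions),
         versions = versions),
    class = "dron_graph"
  )
}

#' @export
print.dron_graph <- function(x, ...) {
  cat("<dron_graph> ingredients: ", nrow(x$ingredients),
      "  dispositions: ", nrow(x$dispositions),
      "  CDFs: ", nrow(x$cdfs), "  CDs: ", nrow(x$cds),
      "  BDs: ", nrow(x$bds), "  packaged products: ",
      sum(!is.na(x$ndcs$parent_type)), "\n", sep = "")
  invisible(x)
}

#' Attach packaged products to their clinical or branded drugs
#'
#' Each included NDC becomes a packaged-product entity parented to the
#' branded or clinical drug whose terminal identifier equals the NDC's
#' resolved identifier. Codes resolving to an ingredient, a CDF, or to no
#' entity at all are flagged unattachable and reported, not silently dropped.
#'
#' @param graph a `dron_graph`.
#' @param included tibble from [ndc_included()] (`ndc`, `resolved_rxcui`,
#'   `orphaned`).
#' @return The graph with its `ndcs` table filled; unattachable rows have
#'   `parent_type` `NA`.
#' @export
attach_ndcs <- function(graph, included) {
  ndcs <- included |>
    mutate(parent_type = dplyr::case_when(
      .data$resolved_rxcui %in% graph$bds$rxcui ~ "BD",
      .data$resolved_rxcui %in% graph$cds$rxcui ~ "CD",
      TRUE ~ NA_character_
    )) |>
    select("ndc", rxcui = "resolved_rxcui", "parent_type", "orphaned") |>
    arrange(.data$ndc)
  n_un <- sum(is.na(ndcs$parent_type))
  if (n_un > 0L) {
    dron_log(n_un, " NDC(s) unattachable (no clinical or branded drug for their identifier)")
  }
  graph$ndcs <- ndcs
  graph
}

#' Validate the referential integrity of an entity graph
#'
#' Checks the structural invariants the emitter relies on: unique entity keys
#' per type; every non-dangling CD pointing at an existing CDF and every
#' non-dangling BD at an existing CD; every CDF with at least one ingredient;
#' ingredient/disposition link endpoints present; every attached packaged
#' product pointing at an existing CD or BD.
#'
#' @param graph a `dron_graph`.
#' @return A list with `valid` (logical) and `problems` (character vector).
#' @export
validate_graph <- function(graph) {
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(!anyDuplicated(graph$ingredients$rxcui), "duplicate ingredient keys")
  chk(!anyDuplicated(graph$cdfs$rxcui), "duplicate CDF keys")
  chk(!anyDuplicated(graph$cds$rxcui), "duplicate CD keys")
  chk(!anyDuplicated(graph$bds$rxcui), "duplicate BD keys")
  ok_cd <- graph$cds$dangling | graph$cds$cdf_rxcui %in% graph$cdfs$rxcui
  chk(all(ok_cd), "CD with missing parent CDF")
  ok_bd <- graph$bds$dangling | graph$bds$cd_rxcui %in% graph$cds$rxcui
  chk(all(ok_bd), "BD with missing parent CD")
  chk(all(graph$cdfs$rxcui %in% graph$cdf_ingredient$cdf_rxcui),
      "CDF without any ingredient")
  chk(all(graph$cdf_ingredient$in_rxcui %in% graph$ingredients$rxcui),
      "CDF-ingredient link to unknown ingredient")
  chk(all(graph$disposition_ingredient$disposition %in% graph$dispositions$disposition),
      "link to unknown disposition")
  attached <- graph$ndcs |> filter(!is.na(.data$parent_type))
  chk(all(attached$rxcui[attached$parent_type == "CD"] %in% graph$cds$rxcui),
      "packaged product with missing CD parent")
  chk(all(attached$rxcui[attached$parent_type == "BD"] %in% graph$bds$rxcui),
      "packaged product with missing BD parent")
  list(valid = length(problems) == 0L, problems = problems)
}

# entity-level reachability shared by the two query operations
cds_for_ingredient <- function(graph, in_rxcui) {
  cdfs <- graph$cdf_ingredient$cdf_rxcui[graph$cdf_ingredient$in_rxcui %in% in_rxcui]
  graph$cds$rxcui[!is.na(graph$cds$cdf_rxcui) & graph$cds$cdf_rxcui %in% cdfs]
}

#' Query all NDCs containing an ingredient
#'
#' Returns every packaged-product code whose clinical or branded drug descends
#' from a clinical drug form containing the ingredient. This is the primary
#' validation use case: pulling all historical claims codes for a given
#' active ingredient.
#'
#' @param graph a `dron_graph` with NDCs attached.
#' @param ingredient ingredient name (matched after normalization) or RXCUI.
#' @return Sorted character vector of NDC codes.
#' @export
ndcs_by_ingredient <- function(graph, ingredient) {
  ing <- graph$ingredients
  hit <- ing$rxcui[ing$rxcui == ingredient |
                     normalize_name(ing$name) == normalize_name(ingredient)]
  if (length(hit) == 0L) {
    rlang::warn(paste0("unknown ingredient: ", ingredient))
    return(character())
  }
  cds <- cds_for_ingredient(graph, hit)
  bds <- graph$bds$rxcui[!is.na(graph$bds$cd_rxcui) & graph$bds$cd_rxcui %in% cds]
  hits <- graph$ndcs |>
    filter(!is.na(.data$parent_type),
           (.data$parent_type == "CD" & .data$rxcui %in% cds) |
             (.data$parent_type == "BD" & .data$rxcui %in% bds))
  sort(unique(hits$ndc))
}

#' Query all NDCs whose ingredients bear a disposition
#'
#' The union of [ndcs_by_ingredient()] over every ingredient linked to the
#' disposition (e.g. all products whose ingredient bears beta-adrenergic
#' receptor blockade).
#'
#' @param graph a `dron_graph` with NDCs attached.
#' @param disposition disposition label.
#' @return Sorted character vector of NDC codes.
#' @export
ndcs_by_disposition <- function(graph, disposition) {
  bearers <- graph$disposition_ingredient$in_rxcui[
    graph$disposition_ingredient$disposition == disposition]
  if (length(bearers) == 0L) {
    if (!disposition %in% graph$dispositions$disposition) {
      rlang::warn(paste0("unknown disposition: ", disposition))
    }
    return(character())
  }
  sort(unique(unlist(lapply(bearers, function(b) ndcs_by_ingredient(graph, b)))))
}

#' Persist the normalized store as a directory of tab-separated tables
#'
#' Writes the normalized model with its conventional table names
#' (`ingredient`, `disposition`, `clinical_drug_form`, `clinical_drug`,
#' `branded_drug`, `ndc`, `rxcui`, `rxnorm`) plus the explicit many-to-many
#' tables `cdf_ingredient` and `disposition_ingredient`.
#'
#' @param graph a `dron_graph`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_store <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, name) readr::write_tsv(tbl, file.path(dir, paste0(name, ".tsv")),
                                            progress = FALSE)
  w(graph$ingredients, "ingredient")
  w(graph$dispositions, "disposition")
  w(graph$cdfs, "clinical_drug_form")
  w(graph$cds, "clinical_drug")
  w(graph$bds, "branded_drug")
  w(graph$ndcs, "ndc")
  w(graph$rxcui_table$rxcui, "rxcui")
  w(graph$rxcui_table$rxnorm, "rxnorm")
  w(graph$cdf_ingredient, "cdf_ingredient")
  w(graph$disposition_ingredient, "disposition_ingredient")
  invisible(dir)
}
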