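# Lexical mapping of ingredient names to ChEBI classes, closure import, and
# disposition-ingredient mining from ChEBI roles.

#' Build the lexical index of an ontology snapshot
#'
#' Indexes every class under its normalized label and all of its normalized
#' exact/related synonyms (see [normalize_name()]). A class without a label
#' is indexed by its synonyms only and logged.
#'
#' @param snapshot a `dron_ontology` snapshot from [read_ontology()].
#' @return A tibble with columns `key` (normalized name), `iri`,
#'   `annotation_type` (`label`, `exact_synonym`, `related_synonym`).
#' @export
build_lexical_index <- function(snapshot) {
  unlabeled <- sum(is.na(snapshot$classes$label))
  if (unlabeled > 0L) {
    dron_log(unlabeled, " class(es) without a label; indexed by synonyms only")
  }
  lab <- snapshot$classes |>
    filter(!is.na(.data$label)) |>
    mutate(key = normalize_name(.data$label), annotation_type = "label") |>
    select("key", "iri", "annotation_type")
  syn <- snapshot$synonyms |>
    mutate(key = normalize_name(.data$value)) |>
    select("key", "iri", annotation_type = "type")
  bind_rows(lab, syn) |>
    distinct() |>
    arrange(.data$key, .data$annotation_type, .data$iri)
}

iri_source <- function(iri) {
  dplyr::case_when(
    is.na(iri) ~ "DRON",
    startsWith(iri, paste0(OBO_PREFIX, "CHEBI_")) ~ "CHEBI",
    startsWith(iri, paste0(OBO_PREFIX, "PR_")) ~ "PRO",
    TRUE ~ "CHEBI"
  )
}

#' Map ingredient atoms to ontology classes by exact lexical match
#'
#' For each ingredient (term type IN): an override entry wins outright;
#' otherwise the normalized name is looked up in the lexical index, preferring
#' a label match over an exact-synonym match over a related-synonym match.
#' A name matching two or more distinct classes at its best annotation type is
#' not mapped automatically: it falls through to a minted identifier and the
#' candidates are written to the curation report (attribute
#' `curation_report`), mirroring how the somatropin mis-mapping had to be
#' fixed by hand. Names with no match at all receive a minted DrOn identifier
#' at emission time (`source = "DRON"`, `matched_via = "none"`).
#'
#' @param atoms tibble of atoms (only `tty == "IN"` rows are used).
#' @param index lexical index from [build_lexical_index()].
#' @param overrides tibble with `name`, `target_iri`; defaults to the shipped
#'   curated override file (see [dron_overrides()]).
#' @return A tibble with columns `rxcui`, `name`, `target_iri`, `source`
#'   (`CHEBI`, `PRO` or `DRON`), `matched_via` (`label`, `exact_synonym`,
#'   `related_synonym`, `override`, `none`), with the curation report of
#'   ambiguous candidates attached as attribute `curation_report`.
#' @export
match_ingredients <- function(atoms, index, overrides = dron_overrides()) {
  ins <- atoms |>
    filter(.data$tty == "IN") |>
    distinct(.data$rxcui, .data$name) |>
    mutate(key = normalize_name(.data$name))
  ov <- overrides |> mutate(key = normalize_name(.data$name)) |> select("key", "target_iri")

  hits <- ins |>
    select("rxcui", "key") |>
    left_join(index, by = "key", relationship = "many-to-many")
  pick <- hits |>
    filter(!is.na(.data$iri)) |>
    mutate(rank = match(.data$annotation_type,
                        c("label", "exact_synonym", "related_synonym"))) |>
    group_by(.data$rxcui) |>
    filter(.data$rank == min(.data$rank)) |>
    summarise(n_iri = dplyr::n_distinct(.data$iri),
              candidates = paste(sort(unique(.data$iri)), collapse = ";"),
              iri = sort(unique(.data$iri))[1L],
              matched_via = .data$annotation_type[1L], .groups = "drop")

  res <- ins |>
    left_join(pick, by = "rxcui") |>
    left_join(ov, by = "key")
  res <- res |>
    mutate(
      ambiguous = !is.na(.data$n_iri) & .data$n_iri > 1L & is.na(.data$target_iri),
      target_iri = dplyr::case_when(
        !is.na(.data$target_iri) ~ .data$target_iri,
        .data$ambiguous ~ NA_character_,
        !is.na(.data$iri) ~ .data$iri,
        TRUE ~ NA_character_
      ),
      matched_via = dplyr::case_when(
        !is.na(.data$key) & .data$key %in% ov$key ~ "override",
        .data$ambiguous ~ "none",
        !is.na(.data$iri) ~ .data$matched_via,
        TRUE ~ "none"
      ),
      source = dplyr::case_when(
        .data$matched_via == "override" ~ iri_source(.data$target_iri),
        .data$matched_via == "none" ~ "DRON",
        TRUE ~ iri_source(.data$target_iri)
      )
    )
  report <- res |>
    filter(.data$ambiguous) |>
    select("rxcui", "name", "candidates")
  if (nrow(report) > 0L) {
    dron_log(nrow(report), " ambiguous ingredient name(s) written to the curation report")
  }
  out <- res |>
    select("rxcui", "name", "target_iri", "source", "matched_via") |>
    arrange(.data$rxcui)
  attr(out, "curation_report") <- report
  out
}

#' Tally ingredient matches by annotation type
#'
#' @param mappings output of [match_ingredients()].
#' @return A tibble with columns `matched_via`, `n`.
#' @export
match_tally <- function(mappings) {
  mappings |>
    dplyr::count(.data$matched_via, name = "n") |>
    arrange(.data$matched_via)
}

#' Import the is-a closure of matched classes
#'
#' Returns the matched classes plus every ancestor reachable through asserted
#' is-a edges, with labels, and the is-a edges restricted to the returned
#' set. An edge whose parent is not declared in the snapshot is logged and
#' dropped, so the result is ancestor-closed: the parent of every returned
#' class is itself returned.
#'
#' @param iris character vector of matched class IRIs.
#' @param snapshot a `dron_ontology` snapshot.
#' @return A list with `classes` (tibble `iri`, `label`) and `edges` (tibble
#'   `child`, `parent`).
#' @export
import_closure <- function(iris, snapshot) {
  declared <- snapshot$classes$iri
  edges <- snapshot$subclass
  dangling <- !edges$parent %in% declared
  if (any(dangling)) {
    dron_log(sum(dangling), " is-a edge(s) with undeclared parent dropped")
    edges <- edges[!dangling, ]
  }
  seen <- unique(iris[iris %in% declared])
  frontier <- seen
  while (length(frontier) > 0L) {
    parents <- unique(edges$parent[edges$child %in% frontier])
    frontier <- setdiff(parents, seen)
    seen <- c(seen, frontier)
  }
  classes <- snapshot$classes |> filter(.data$iri %in% seen) |> arrange(.data$iri)
  kept <- edges |> filter(.data$child %in% seen, .data$parent %in% seen) |>
    arrange(.data$child, .data$parent)
  list(classes = classes, edges = kept)
}

#' Mine disposition-ingredient links from ontology roles
#'
#' For each disposition with an associated role, every mapped ingredient
#' whose class bears that role (directly or via a role subclass) yields a
#' link, minus the curated exclusions (a role can be broader than the
#' disposition: a generic calcium-channel-blocker role must not attach the
#' T-type-selective ethosuximide to the L-type disposition). The manually
#' curated dispositions contribute their curated ingredient lists verbatim,
#' resolved against ingredient names.
#'
#' @param snapshot a `dron_ontology` snapshot.
#' @param mappings output of [match_ingredients()].
#' @param atoms atom tibble (for resolving curated ingredient names).
#' @param role_map tibble `disposition`, `chebi_role` (label, `NA` for curated
#'   rows); defaults to the shipped six-disposition file.
#' @param curated tibble `disposition`, `ingredient_name`; defaults shipped.
#' @param exclusions tibble `disposition`, `ingredient_name`; defaults shipped.
#' @return A tibble with columns `disposition`, `rxcui`.
#' @export
mine_disposition_links <- function(snapshot, mappings, atoms,
                                   role_map = dron_role_map(),
                                   curated = dron_curated_links(),
                                   exclusions = dron_role_exclusions()) {
  labelled <- snapshot$classes |>
    filter(!is.na(.data$label)) |>
    mutate(key = normalize_name(.data$label))
  mined <- list()
  for (i in which(!is.na(role_map$chebi_role) & nzchar(role_map$chebi_role))) {
    role_key <- normalize_name(role_map$chebi_role[i])
    role_iri <- labelled$iri[labelled$key == role_key]
    if (length(role_iri) == 0L) {
      dron_abort(paste0("role not found in ontology snapshot: ",
                        role_map$chebi_role[i]), class = "dronr_missing_role")
    }
    # the named role plus all of its role subclasses
    role_set <- role_iri
    frontier <- role_set
    while (length(frontier) > 0L) {
      kids <- unique(snapshot$subclass$child[snapshot$subclass$parent %in% frontier])
      frontier <- setdiff(kids, role_set)
      role_set <- c(role_set, frontier)
    }
    bearers <- unique(snapshot$roles$iri[snapshot$roles$role_iri %in% role_set])
    linked <- mappings |>
      filter(.data$source == "CHEBI", .data$target_iri %in% bearers) |>
      mutate(disposition = role_map$disposition[i]) |>
      select("disposition", "rxcui", "name")
    mined[[length(mined) + 1L]] <- linked
  }
  mined <- bind_rows(mined)
  if (nrow(mined) > 0L && nrow(exclusions) > 0L) {
    excl <- exclusions |>
      mutate(key = normalize_name(.data$ingredient_name)) |>
      select("disposition", "key")
    mined <- mined |>
      mutate(key = normalize_name(.data$name)) |>
      anti_join(excl, by = c("disposition", "key"))
  }
  name_to_rxcui <- atoms |>
    filter(.data$tty == "IN") |>
    mutate(key = normalize_name(.data$name)) |>
    distinct(.data$key, .data$rxcui)
  cur <- curated |>
    mutate(key = normalize_name(.data$ingredient_name)) |>
    left_join(name_to_rxcui, by = "key")
  unresolved <- filter(cur, is.na(.data$rxcui))
  if (nrow(unresolved) > 0L) {
    dron_log(nrow(unresolved), " curated ingredient name(s) not present among IN atoms; skipped")
  }
  out <- bind_rows(
    select(mined, "disposition", "rxcui"),
    cur |> filter(!is.na(.data$rxcui)) |> select("disposition", "rxcui")
  ) |>
    distinct() |>
    arrange(.data$disposition, .data$rxcui)
  tibble(disposition = out$disposition, rxcui = out$rxcui)
}

read_config_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  comment = "#", trim_ws = TRUE)
}

extdata <- function(f) system.file("extdata", f, package = "dronr", mustWork = TRUE)

#' Shipped curated content
#'
#' Loaders for the plain-text curated configuration shipped with the package:
#' `dron_role_map()` gives the six dispositions and, for the three mined ones,
#' the role label each is mined from; `dron_curated_links()` the manually
#' curated disposition-ingredient lists for the other three;
#' `dron_role_exclusions()` ingredient names excluded from mining for a given
#' disposition; `dron_overrides()` the manual ingredient-mapping overrides
#' (one shipped entry: somatropin to the Protein Ontology somatotropin class,
#' instead of the growth-hormone role a naive lexical match lands on).
#'
#' @param path optional replacement file in the same format.
#' @return A tibble.
#' @export
dron_role_map <- function(path = extdata("dispositions.tsv")) {
  rm <- read_config_tsv(path)
  if (nrow(rm) != 6L) {
    dron_abort("disposition map must contain exactly six dispositions",
               class = "dronr_config_error")
  }
  if (sum(!is.na(rm$chebi_role) & nzchar(rm$chebi_role)) != 3L) {
    dron_abort("exactly three dispositions must carry a ChEBI role",
               class = "dronr_config_error")
  }
  rm
}

#' @rdname dron_role_map
#' @export
dron_curated_links <- function(path = extdata("curated_disposition_ingredients.tsv")) {
  read_config_tsv(path)
}

#' @rdname dron_role_map
#' @export
dron_role_exclusions <- function(path = extdata("role_mining_exclusions.tsv")) {
  read_config_tsv(path)
}

#' @rdname dron_role_map
#' @export
dron_overrides <- function(path = extdata("ingredient_overrides.tsv")) {
  read_config_tsv(path)
}
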