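# Seeded synthetic fixtures: a chronological RRF release series plus a
# mini-ChEBI snapshot with known ground truth, so the whole pipeline is
# testable without licensed terminology downloads. Synthetic identifiers are
# drawn from a high numeric range (9,0xx,xxx) disjoint from real RXCUIs;
# synthetic ChEBI accessions (other than canonical anchors like furosemide's)
# live above 9,100,000.

#' Fixture configuration for the synthetic release series
#'
#' The defaults define the study conditions used throughout the test suite:
#' five releases over roughly two hundred drug concepts, with merges, splits,
#' entry-in-error retirements and silent disappearances injected at known
#' points, and ChEBI-matchable ingredient fractions apportioned across the
#' three annotation types with label matches dominating and exact-synonym
#' matches rare, echoing the proportions seen on real terminology data.
#'
#' @param seed integer seed driving every random choice.
#' @param n_ingredients,n_cdfs,n_cds,n_bds,n_ndcs concept and code counts.
#' @param n_releases number of chronological releases (>= 2 when any events
#'   are configured).
#' @param n_merges,n_splits,n_errors,n_silent injected identifier events:
#'   merges (cardinality-1 retirement records), splits (cardinality > 1),
#'   entries-in-error (`cui1 == cui2`) and silent disappearances (no record).
#' @param chebi_label_frac,chebi_exact_frac,chebi_related_frac fractions of
#'   ingredients matchable in the mini-ChEBI via each annotation type.
#' @return A `dron_fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_ingredients = 40L, n_cdfs = 50L, n_cds = 70L,
                           n_bds = 30L, n_ndcs = 120L, n_releases = 5L,
                           n_merges = 6L, n_splits = 3L, n_errors = 3L,
                           n_silent = 3L,
                           chebi_label_frac = 0.30, chebi_exact_frac = 0.05,
                           chebi_related_frac = 0.15) {
  cfg <- list(seed = as.integer(seed), n_ingredients = as.integer(n_ingredients),
              n_cdfs = as.integer(n_cdfs), n_cds = as.integer(n_cds),
              n_bds = as.integer(n_bds), n_ndcs = as.integer(n_ndcs),
              n_releases = as.integer(n_releases), n_merges = as.integer(n_merges),
              n_splits = as.integer(n_splits), n_errors = as.integer(n_errors),
              n_silent = as.integer(n_silent),
              chebi_label_frac = chebi_label_frac,
              chebi_exact_frac = chebi_exact_frac,
              chebi_related_frac = chebi_related_frac)
  n_events <- cfg$n_merges + cfg$n_splits + cfg$n_errors + cfg$n_silent
  if (any(unlist(cfg[2:11]) < 0L)) {
    dron_abort("all fixture counts must be non-negative", class = "dronr_config_error")
  }
  if (cfg$n_ingredients < 10L || cfg$n_cdfs < 6L || cfg$n_bds < 1L) {
    dron_abort("fixture needs at least 10 ingredients, 6 CDFs and 1 BD",
               class = "dronr_config_error")
  }
  if (cfg$n_ndcs < n_events) {
    dron_abort("need at least one NDC per injected event", class = "dronr_config_error")
  }
  if (n_events > 0L && cfg$n_releases < 2L) {
    dron_abort("events require at least two releases", class = "dronr_config_error")
  }
  if (cfg$chebi_label_frac + cfg$chebi_exact_frac + cfg$chebi_related_frac > 1) {
    dron_abort("ChEBI match fractions must sum to at most 1", class = "dronr_config_error")
  }
  structure(cfg, class = "dron_fixture_config")
}

CHEBI_CHEM_ROOT <- paste0(OBO_PREFIX, "CHEBI_24431") # chemical entity
CHEBI_ROLE_ROOT <- paste0(OBO_PREFIX, "CHEBI_50906") # role
CHEBI_FUROSEMIDE <- paste0(OBO_PREFIX, "CHEBI_47426")
chebi_syn_iri <- function(n) sprintf("%sCHEBI_%d", OBO_PREFIX, 9100000L + n)

# fixed drug ingredients present in every fixture; the curated content
# (overrides, role-mining exclusions, curated disposition lists) keys on
# their names
special_ingredients <- function() {
  tibble(
    name = c("furosemide", "warfarin", "ethosuximide", "verapamil",
             "metoprolol", "propranolol", "omeprazole", "somatropin"),
    match_type = c(rep("label", 7L), "override"),
    role = c(NA, NA, "calcium channel blocker", "calcium channel blocker",
             "beta-adrenergic antagonist", "beta-adrenergic antagonist",
             "proton pump inhibitor", NA)
  )
}

# the full deterministic fixture plan: concepts, structure, events and the
# per-release timeline, derived from the config seed
fixture_plan <- function(config) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    sp <- special_ingredients()
    n_generic <- cfg$n_ingredients - nrow(sp)
    if (n_generic < 0L) {
      dron_abort("n_ingredients smaller than the fixed special set",
                 class = "dronr_config_error")
    }
    ing <- tibble(
      rxcui = as.character(9010000L + seq_len(cfg$n_ingredients)),
      name = c(sp$name, sprintf("synthin%04d", seq_len(n_generic))),
      match_type = c(sp$match_type, rep("none", n_generic)),
      role = c(sp$role, rep(NA_character_, n_generic))
    )
    # apportion generic ingredients across the annotation-type quotas
    n_label_g <- max(0L, round(cfg$chebi_label_frac * cfg$n_ingredients) - 7L)
    n_exact_g <- round(cfg$chebi_exact_frac * cfg$n_ingredients)
    n_rel_g <- round(cfg$chebi_related_frac * cfg$n_ingredients)
    quota <- c(rep("label", n_label_g), rep("exact_synonym", n_exact_g),
               rep("related_synonym", n_rel_g))
    quota <- head(quota, n_generic)
    gi <- which(ing$match_type == "none")
    ing$match_type[gi[seq_along(quota)]] <- quota
    matched <- ing$match_type %in% c("label", "exact_synonym", "related_synonym")
    ing$chebi_iri <- NA_character_
    ing$chebi_iri[matched] <- chebi_syn_iri(seq_len(sum(matched)))
    ing$chebi_iri[ing$name == "furosemide"] <- CHEBI_FUROSEMIDE
    ing$group <- NA_integer_
    ing$group[matched] <- (seq_len(sum(matched)) - 1L) %% 3L + 1L

    cdfs <- tibble(rxcui = as.character(9020000L + seq_len(cfg$n_cdfs)),
                   name = sprintf("synth form %04d", seq_len(cfg$n_cdfs)))
    # clinical drug forms and their ingredients; the first four forms anchor
    # the designated query answers (furosemide in two forms, one beta blocker
    # form each)
    rx_of <- function(nm) ing$rxcui[ing$name == nm]
    cdf_ing <- vector("list", cfg$n_cdfs)
    cdf_ing[[1L]] <- rx_of("furosemide")
    cdf_ing[[2L]] <- c(rx_of("furosemide"), sample(ing$rxcui, 1L))
    cdf_ing[[3L]] <- rx_of("metoprolol")
    cdf_ing[[4L]] <- rx_of("propranolol")
    for (i in 5:cfg$n_cdfs) {
      k <- 1L + (stats::runif(1L) < 0.3)
      cdf_ing[[i]] <- sample(ing$rxcui, k)
    }
    cdf_ingredient <- tibble(
      cdf_rxcui = rep(cdfs$rxcui, lengths(cdf_ing)),
      in_rxcui = unlist(cdf_ing)
    ) |> distinct()

    cds <- tibble(rxcui = as.character(9030000L + seq_len(cfg$n_cds)),
                  name = sprintf("synth drug %04d", seq_len(cfg$n_cds)),
                  cdf_rxcui = c(cdfs$rxcui[c(1L, 1L, 2L)],
                                sample(cdfs$rxcui, cfg$n_cds - 3L, replace = TRUE)))
    # branded drugs attach only to a protected pool of clinical drugs, so
    # event victims (drawn from the rest) never orphan a branded drug
    bd_pool <- cds$rxcui[seq_len(max(3L, cfg$n_cds %/% 3L))]
    bds <- tibble(rxcui = as.character(9040000L + seq_len(cfg$n_bds)),
                  name = sprintf("synth brand %04d", seq_len(cfg$n_bds)),
                  cd_rxcui = sample(bd_pool, cfg$n_bds, replace = TRUE))

    n_events <- cfg$n_merges + cfg$n_splits + cfg$n_errors + cfg$n_silent
    eligible <- setdiff(cds$rxcui, unique(bds$cd_rxcui))
    if (length(eligible) < n_events) {
      dron_abort(paste0("config infeasible: ", n_events, " events but only ",
                        length(eligible), " event-eligible clinical drugs"),
                 class = "dronr_config_error")
    }
    victims <- sample(eligible, n_events)
    events <- tibble(
      victim = victims,
      type = rep(c("merge", "split", "error", "silent"),
                 c(cfg$n_merges, cfg$n_splits, cfg$n_errors, cfg$n_silent)),
      release = if (n_events > 0L) 2L + (seq_len(n_events) - 1L) %% (cfg$n_releases - 1L)
                else integer()
    )
    # merge survivors: any clinical drug still alive at the event release;
    # when two merges land in different releases, chain the first into the
    # second's victim so every series exercises transitive closure
    events$survivor <- NA_character_
    events$child_a <- NA_character_
    events$child_b <- NA_character_
    stable <- setdiff(cds$rxcui, victims)
    mi <- which(events$type == "merge")
    for (i in mi) {
      alive <- setdiff(cds$rxcui,
                       c(events$victim[events$release <= events$release[i]]))
      events$survivor[i] <- sample(alive, 1L)
    }
    if (length(mi) >= 2L && events$release[mi[1L]] < events$release[mi[2L]]) {
      events$survivor[mi[1L]] <- events$victim[mi[2L]]
    }
    for (i in which(events$type == "split")) {
      events$child_a[i] <- sample(stable, 1L)
      events$child_b[i] <- sample(setdiff(stable, events$child_a[i]), 1L)
    }

    # NDC codes: random 11-digit strings; the first n_events are pinned one
    # per victim so every event type carries codes
    codes <- character(0)
    while (length(codes) < cfg$n_ndcs) {
      fresh <- paste0(sprintf("%05d", sample.int(99999L, cfg$n_ndcs, replace = TRUE)),
                      sprintf("%04d", sample.int(9999L, cfg$n_ndcs, replace = TRUE)),
                      sprintf("%02d", sample.int(99L, cfg$n_ndcs, replace = TRUE)))
      codes <- unique(c(codes, fresh))
    }
    codes <- codes[seq_len(cfg$n_ndcs)]
    products <- c(cds$rxcui, bds$rxcui)
    assigned <- c(victims,
                  sample(products, cfg$n_ndcs - n_events, replace = TRUE))
    ndcs <- tibble(ndc = codes, product_rxcui = assigned)

    list(config = cfg, ingredients = ing, cdfs = cdfs,
         cdf_ingredient = cdf_ingredient, cds = cds, bds = bds,
         events = events, ndcs = ndcs)
  })
}

# follow a concept's event chain to its terminal resolution
plan_resolution <- function(plan) {
  ev <- plan$events
  ev_idx <- setNames(seq_len(nrow(ev)), ev$victim)
  resolve1 <- function(id) {
    hops <- character()
    repeat {
      i <- ev_idx[id]
      if (is.na(i)) {
        return(list(kind = if (length(hops) == 0L) "CURRENT" else "MERGED",
                    terminal = id))
      }
      if (ev$type[i] == "error") return(list(kind = "ERROR", terminal = NA_character_))
      if (ev$type[i] == "split") return(list(kind = "SPLIT", terminal = NA_character_))
      if (ev$type[i] == "silent") {
        return(list(kind = if (length(hops) == 0L) "ORPHANED" else "MERGED",
                    terminal = id))
      }
      hops <- c(hops, id)
      id <- ev$survivor[i]
    }
  }
  resolve_all <- function(ids) {
    res <- lapply(ids, resolve1)
    tibble(rxcui = ids,
           kind = vapply(res, `[[`, character(1L), "kind"),
           terminal = vapply(res, `[[`, character(1L), "terminal"))
  }
  list(one = resolve1, all = resolve_all)
}

# per-NDC holder sequence: the identifier carrying the code in each release
# span, following merges until the chain ends
plan_ndc_pairs <- function(plan) {
  ev <- plan$events
  ev_idx <- setNames(seq_len(nrow(ev)), ev$victim)
  rows <- list()
  for (i in seq_len(nrow(plan$ndcs))) {
    ndc <- plan$ndcs$ndc[i]
    holder <- plan$ndcs$product_rxcui[i]
    from <- 1L
    repeat {
      j <- ev_idx[holder]
      if (is.na(j)) { # holder survives to the end
        rows[[length(rows) + 1L]] <- list(ndc, holder, from, plan$config$n_releases)
        break
      }
      r <- ev$release[j]
      rows[[length(rows) + 1L]] <- list(ndc, holder, from, r - 1L)
      if (ev$type[j] != "merge") break
      holder <- ev$survivor[j]
      from <- r
      if (from > plan$config$n_releases) break
    }
  }
  tibble(ndc = vapply(rows, `[[`, character(1L), 1L),
         original_rxcui = vapply(rows, `[[`, character(1L), 2L),
         first_seen = vapply(rows, function(r) r[[3L]], integer(1L)),
         last_seen = vapply(rows, function(r) r[[4L]], integer(1L)))
}

# the expected outcome of the whole pipeline on this plan
build_manifest <- function(plan) {
  cfg <- plan$config
  res <- plan_resolution(plan)
  all_ids <- c(plan$ingredients$rxcui, plan$cdfs$rxcui, plan$cds$rxcui,
               plan$bds$rxcui)
  terminal_map <- res$all(all_ids)

  pairs <- plan_ndc_pairs(plan)
  pres <- res$all(pairs$original_rxcui)
  ndc_status <- pairs |>
    mutate(status = dplyr::case_when(
      pres$kind == "ERROR" ~ NDC_EXCLUDED_ERROR,
      pres$kind == "SPLIT" ~ NDC_EXCLUDED_SPLIT,
      pres$kind == "ORPHANED" ~ NDC_ORPHANED,
      TRUE ~ NDC_INCLUDED
    ), resolved_rxcui = pres$terminal) |>
    select("ndc", "original_rxcui", "status", "resolved_rxcui")
  included <- ndc_status |>
    filter(.data$status %in% c(NDC_INCLUDED, NDC_ORPHANED)) |>
    left_join(select(pairs, "ndc", "original_rxcui", "last_seen"),
              by = c("ndc", "original_rxcui")) |>
    arrange(.data$ndc, desc(.data$last_seen)) |>
    group_by(.data$ndc) |>
    slice(1L) |>
    ungroup() |>
    mutate(orphaned = .data$status == NDC_ORPHANED) |>
    select("ndc", "resolved_rxcui", "orphaned") |>
    arrange(.data$ndc)

  n_cd_entities <- cfg$n_cds - cfg$n_merges - cfg$n_splits - cfg$n_errors
  entity_counts <- c(ingredient = cfg$n_ingredients, disposition = 6L,
                     cdf = cfg$n_cdfs, cd = n_cd_entities, bd = cfg$n_bds,
                     ndc = nrow(included))

  matched <- filter(plan$ingredients, !is.na(.data$chebi_iri))
  n_chebi <- nrow(matched) + dplyr::n_distinct(matched$group) + 1L
  n_minted <- sum(plan$ingredients$match_type == "none")
  module_counts <- c(
    `dron-full` = 0L,
    `dron-chebi` = n_chebi,
    `dron-rxnorm` = n_minted + cfg$n_cdfs + n_cd_entities + cfg$n_bds + nrow(included),
    `dron-pro` = 2L,
    `dron-upper` = nrow(dron_upper()$classes)
  )

  tally <- plan$ingredients |>
    dplyr::count(matched_via = .data$match_type, name = "n") |>
    arrange(.data$matched_via)

  role_map <- dron_role_map()
  disp_of_role <- setNames(role_map$disposition, role_map$chebi_role)
  mined <- plan$ingredients |>
    filter(!is.na(.data$role), !is.na(.data$chebi_iri),
           .data$name != "ethosuximide" | .data$role != "calcium channel blocker") |>
    mutate(disposition = unname(disp_of_role[.data$role])) |>
    select("disposition", "rxcui")
  curated <- dron_curated_links() |>
    left_join(plan$ingredients |> mutate(key = normalize_name(.data$name)) |>
                select("key", "rxcui"),
              by = c(ingredient_name = "key")) |>
    filter(!is.na(.data$rxcui)) |>
    select("disposition", "rxcui")
  disposition_links <- bind_rows(mined, curated) |> distinct() |>
    arrange(.data$disposition, .data$rxcui)

  # expected query answers for the designated ingredient and dispositions
  cd_parent <- setNames(plan$cds$cdf_rxcui, plan$cds$rxcui)
  bd_parent <- setNames(plan$bds$cd_rxcui, plan$bds$rxcui)
  prod_cd <- function(id) if (id %in% names(bd_parent)) unname(bd_parent[id]) else id
  inc_cd <- vapply(included$resolved_rxcui, prod_cd, character(1L))
  inc_cdf <- unname(cd_parent[inc_cd])
  ndcs_for_in <- function(in_rxcui) {
    forms <- plan$cdf_ingredient$cdf_rxcui[plan$cdf_ingredient$in_rxcui %in% in_rxcui]
    sort(included$ndc[inc_cdf %in% forms])
  }
  rx_of <- function(nm) plan$ingredients$rxcui[plan$ingredients$name == nm]
  nkcc2 <- role_map$disposition[grepl("NKCC2", role_map$disposition)]
  beta <- role_map$disposition[grepl("beta-adrenergic", role_map$disposition)]
  queries <- list(
    ingredient = list(furosemide = ndcs_for_in(rx_of("furosemide"))),
    disposition = setNames(
      list(ndcs_for_in(rx_of("furosemide")),
           ndcs_for_in(c(rx_of("metoprolol"), rx_of("propranolol")))),
      c(nkcc2, beta)
    )
  )

  structure(
    list(terminal_map = terminal_map, ndc_status = ndc_status,
         included = included, entity_counts = entity_counts,
         module_counts = module_counts, match_tally = tally,
         disposition_links = disposition_links, queries = queries,
         unattachable = 0L),
    class = "dron_manifest"
  )
}

#' Generate a synthetic release series with ground truth
#'
#' Writes `n_releases` release directories (named `01`, `02`, ...) in the RRF
#' dialect. Release 1 holds the base concept set; later releases inject the
#' configured events: a merge retires an identifier with a cardinality-1
#' record and moves its NDCs to the survivor; an entry-in-error writes a
#' record with `cui1 == cui2`; a split writes two records with cardinality 2;
#' a silent disappearance removes the atom with no record at all. A
#' machine-readable ground-truth manifest (`manifest.json`) describing the
#' expected terminal provenance map, NDC status partition, entity and module
#' class counts, match tally, disposition links and designated query answers
#' is written alongside and returned.
#'
#' @param config a [fixture_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with `dirs` (release directories in order) and
#'   `manifest` (a `dron_manifest`).
#' @export
generate_release_series <- function(config, out_dir) {
  plan <- fixture_plan(config)
  cfg <- plan$config
  manifest <- build_manifest(plan)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ev <- plan$events
  atoms_static <- bind_rows(
    plan$ingredients |> mutate(tty = "IN") |> select("rxcui", "tty", "name"),
    plan$cdfs |> mutate(tty = "SCDF") |> select("rxcui", "tty", "name"),
    plan$bds |> mutate(tty = "SBD") |> select("rxcui", "tty", "name")
  )
  rel_static <- bind_rows(
    tibble(rxcui1 = plan$cdf_ingredient$cdf_rxcui, rela = "has_ingredient",
           rxcui2 = plan$cdf_ingredient$in_rxcui),
    tibble(rxcui1 = plan$bds$rxcui, rela = "tradename_of",
           rxcui2 = plan$bds$cd_rxcui)
  )
  pairs <- plan_ndc_pairs(plan)

  dirs <- character(cfg$n_releases)
  for (o in seq_len(cfg$n_releases)) {
    alive_cds <- plan$cds |>
      anti_join(filter(ev, .data$release <= o), by = c(rxcui = "victim"))
    atoms <- bind_rows(
      atoms_static,
      alive_cds |> mutate(tty = "SCD") |> select("rxcui", "tty", "name")
    ) |> arrange(.data$rxcui, .data$tty)
    rels <- bind_rows(
      rel_static,
      tibble(rxcui1 = alive_cds$rxcui, rela = "isa", rxcui2 = alive_cds$cdf_rxcui)
    ) |> arrange(.data$rxcui1, .data$rela, .data$rxcui2)
    ndc_rows <- pairs |>
      filter(.data$first_seen <= o, .data$last_seen >= o) |>
      select(ndc = "ndc", rxcui = "original_rxcui") |>
      arrange(.data$ndc)
    # the retired-identifier file is cumulative, as in real releases
    past <- filter(ev, .data$release <= o, .data$type != "silent")
    ret <- bind_rows(
      past |> filter(.data$type == "merge") |>
        mutate(cui1 = .data$victim, cui2 = .data$survivor, cardinality = 1L),
      past |> filter(.data$type == "error") |>
        mutate(cui1 = .data$victim, cui2 = .data$victim, cardinality = 1L),
      past |> filter(.data$type == "split") |>
        mutate(cui1 = .data$victim, cui2 = .data$child_a, cardinality = 2L),
      past |> filter(.data$type == "split") |>
        mutate(cui1 = .data$victim, cui2 = .data$child_b, cardinality = 2L)
    ) |> select("cui1", "cui2", "cardinality") |> arrange(.data$cui1, .data$cui2)

    dirs[o] <- file.path(out_dir, sprintf("%02d", o))
    write_release(dirs[o], version = sprintf("SYN_%02d", o), atoms = atoms,
                  ndc_attributes = ndc_rows, retirements = ret,
                  relationships = rels)
  }
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(dirs = dirs, manifest = manifest))
}

#' Generate the mini-ChEBI snapshot for a fixture configuration
#'
#' Writes an OWL (RDF/XML) snapshot containing: the furosemide class at its
#' canonical accession under its canonical label; one chemical class per
#' matchable ingredient, exposed through the configured annotation type
#' (label, exact synonym or related synonym) and parented into a small
#' chemical-group is-a hierarchy under 'chemical entity'; a role hierarchy
#' with the three mined roles (beta-adrenergic antagonist, proton pump
#' inhibitor, calcium channel blocker) linked to the designated ingredient
#' classes via existential has-role restrictions; and a decoy 'growth
#' hormone' role carrying "somatropin" as a related synonym, which the
#' shipped override must beat.
#'
#' @param config a [fixture_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
generate_mini_chebi <- function(config, path) {
  plan <- fixture_plan(config)
  ing <- filter(plan$ingredients, !is.na(.data$chebi_iri))

  groups <- tibble(iri = chebi_syn_iri(9000L + 1:3),
                   label = sprintf("synthetic chemical group %d", 1:3))
  roles <- tibble(
    iri = chebi_syn_iri(9500L + 1:4),
    label = c("beta-adrenergic antagonist", "proton pump inhibitor",
              "calcium channel blocker", "growth hormone")
  )
  chem <- ing |>
    mutate(label = if_else(.data$match_type == "label", .data$name,
                           paste0("reference compound ", row_number())),
           group_iri = groups$iri[.data$group])
  classes <- bind_rows(
    tibble(iri = CHEBI_CHEM_ROOT, label = "chemical entity"),
    tibble(iri = CHEBI_ROLE_ROOT, label = "role"),
    groups[sort(unique(chem$group)), ],
    roles,
    select(chem, iri = "chebi_iri", "label")
  )
  syn <- bind_rows(
    chem |> filter(.data$match_type == "exact_synonym") |>
      mutate(prop = IRI_EXACT_SYN) |>
      select(iri = "chebi_iri", "prop", value = "name"),
    chem |> filter(.data$match_type == "related_synonym") |>
      mutate(prop = IRI_RELATED_SYN) |>
      select(iri = "chebi_iri", "prop", value = "name"),
    tibble(iri = roles$iri[roles$label == "growth hormone"],
           prop = IRI_RELATED_SYN, value = "somatropin")
  ) |> mutate(is_resource = FALSE)
  subclass <- bind_rows(
    tibble(sub = groups$iri[sort(unique(chem$group))], super = CHEBI_CHEM_ROOT),
    tibble(sub = roles$iri, super = CHEBI_ROLE_ROOT),
    tibble(sub = chem$chebi_iri, super = chem$group_iri)
  )
  role_iri <- setNames(roles$iri, roles$label)
  role_links <- plan$ingredients |>
    filter(!is.na(.data$role), !is.na(.data$chebi_iri)) |>
    mutate(sub = .data$chebi_iri, prop = IRI_HAS_ROLE,
           filler = unname(role_iri[.data$role])) |>
    select("sub", "prop", "filler")

  doc <- owl_doc(
    ontology_iri = paste0(OBO_PREFIX, "chebi/synthetic-mini-chebi.owl"),
    object_properties = tibble(iri = IRI_HAS_ROLE, label = "has role"),
    classes = classes,
    annotations = syn,
    subclass_named = subclass,
    subclass_some = role_links
  )
  write_owl(doc, path)
  invisible(path)
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest a `dron_manifest`.
#' @param path JSON file.
#' @return `path` (write) or the manifest (read).
#' @export
write_manifest <- function(manifest, path) {
  m <- unclass(manifest)
  # named count vectors must be objects, not arrays, to keep their names
  m$entity_counts <- as.list(m$entity_counts)
  m$module_counts <- as.list(m$module_counts)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("terminal_map", "ndc_status", "included", "match_tally",
               "disposition_links")) {
    m[[nm]] <- as_tibble(m[[nm]])
  }
  m$entity_counts <- unlist(m$entity_counts)
  m$module_counts <- unlist(m$module_counts)
  m$queries$ingredient <- lapply(m$queries$ingredient, as.character)
  m$queries$disposition <- lapply(m$queries$disposition, as.character)
  structure(m, class = "dron_manifest")
}
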