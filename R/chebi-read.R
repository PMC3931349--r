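# Loading a ChEBI-style ontology snapshot into the tables the lexical mapper
# needs: class labels, synonyms by annotation type, asserted is-a edges and
# role linkage (which ingredient class bears which role class).

new_ontology_snapshot <- function(classes, synonyms, subclass, roles, role_form) {
  structure(
    list(classes = arrange(distinct(classes), .data$iri),
         synonyms = arrange(distinct(synonyms), .data$iri, .data$type, .data$value),
         subclass = arrange(distinct(subclass), .data$child, .data$parent),
         roles = arrange(distinct(roles), .data$iri, .data$role_iri),
         role_form = role_form),
    class = "dron_ontology"
  )
}

#' @export
print.dron_ontology <- function(x, ...) {
  cat("<dron_ontology> ", nrow(x$classes), " classes, ", nrow(x$synonyms),
      " synonyms, ", nrow(x$subclass), " is-a edges, ", nrow(x$roles),
      " role links (", x$role_form, " form)\n", sep = "")
  invisible(x)
}

#' Load a ChEBI-style ontology snapshot
#'
#' Reads an OWL (RDF/XML) or OBO file into the tables the lexical mapper
#' consumes: classes with labels, exact/related synonyms, asserted is-a edges
#' among named classes, and role linkage. Role linkage is auto-detected:
#' existential has-role restrictions are tried first, falling back to
#' resource-valued has-role annotation assertions; the form found is recorded
#' and logged.
#'
#' @param path ontology file; `.obo` is parsed as OBO, anything else as
#'   RDF/XML.
#' @return A `dron_ontology` snapshot.
#' @export
read_ontology <- function(path) {
  if (grepl("\\.obo$", path, ignore.case = TRUE)) {
    read_ontology_obo(path)
  } else {
    snapshot_from_owl(read_owl(path))
  }
}

snapshot_from_owl <- function(doc) {
  syn <- doc$annotations |>
    filter(.data$prop %in% c(IRI_EXACT_SYN, IRI_RELATED_SYN), !.data$is_resource) |>
    mutate(type = if_else(.data$prop == IRI_EXACT_SYN, "exact_synonym", "related_synonym")) |>
    select("iri", "type", "value")
  restr_roles <- doc$subclass_some |>
    filter(.data$prop == IRI_HAS_ROLE) |>
    select(iri = "sub", role_iri = "filler")
  if (nrow(restr_roles) > 0L) {
    roles <- restr_roles
    role_form <- "restriction"
  } else {
    roles <- doc$annotations |>
      filter(.data$prop == IRI_HAS_ROLE, .data$is_resource) |>
      select("iri", role_iri = "value")
    role_form <- if (nrow(roles) > 0L) "annotation" else "none"
  }
  dron_log("ontology snapshot: role linkage in ", role_form, " form")
  new_ontology_snapshot(
    classes = doc$classes,
    synonyms = syn,
    subclass = select(doc$subclass_named, child = "sub", parent = "super"),
    roles = roles,
    role_form = role_form
  )
}

obo_id_to_iri <- function(id) {
  paste0(OBO_PREFIX, gsub(":", "_", id, fixed = TRUE))
}

read_ontology_obo <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  term_starts <- which(lines == "[Term]")
  classes <- list(); synonyms <- list(); subclass <- list(); roles <- list()
  bounds <- c(term_starts, length(lines) + 1L)
  for (t in seq_along(term_starts)) {
    block <- lines[(bounds[t] + 1L):(bounds[t + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    tag <- sub(":.*$", "", block)
    val <- stringr::str_trim(sub("^[^:]+: ?", "", block))
    if (any(tag == "is_obsolete" & val == "true")) next
    id <- val[tag == "id"][1L]
    if (is.na(id)) next
    iri <- obo_id_to_iri(id)
    nm <- val[tag == "name"]
    classes[[length(classes) + 1L]] <- c(iri, if (length(nm)) nm[1L] else NA_character_)
    for (s in val[tag == "synonym"]) {
      m <- stringr::str_match(s, '^"(.*)"\\s+(EXACT|RELATED)')
      if (!is.na(m[1, 1])) {
        type <- if (m[1, 3] == "EXACT") "exact_synonym" else "related_synonym"
        synonyms[[length(synonyms) + 1L]] <- c(iri, type, m[1, 2])
      }
    }
    for (p in val[tag == "is_a"]) {
      pid <- stringr::str_trim(sub("!.*$", "", p))
      subclass[[length(subclass) + 1L]] <- c(iri, obo_id_to_iri(pid))
    }
    for (r in val[tag == "relationship"]) {
      m <- stringr::str_match(r, "^has_role\\s+(\\S+)")
      if (!is.na(m[1, 1])) {
        roles[[length(roles) + 1L]] <- c(iri, obo_id_to_iri(m[1, 2]))
      }
    }
  }
  to_tbl <- function(lst, cols) {
    if (length(lst) == 0L) return(empty_chr_tbl(cols))
    m <- do.call(rbind, lst)
    as_tibble(setNames(lapply(seq_along(cols), function(j) m[, j]), cols))
  }
  roles_tbl <- to_tbl(roles, c("iri", "role_iri"))
  new_ontology_snapshot(
    classes = to_tbl(classes, c("iri", "label")),
    synonyms = to_tbl(synonyms, c("iri", "type", "value")),
    subclass = to_tbl(subclass, c("child", "parent")),
    roles = roles_tbl,
    role_form = if (nrow(roles_tbl) > 0L) "annotation" else "none"
  )
}
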