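# A small in-memory OWL 2 document model covering exactly the axiom shapes
# the ontology uses: class declarations with labels and annotations,
# SubClassOf a named class, SubClassOf an existential (someValuesFrom)
# restriction, object/annotation property declarations and ontology imports.
# Serialization is canonical RDF/XML: everything emitted in sorted order, so
# identical content gives byte-identical files and serialize -> parse ->
# serialize is a fixed point.

#' Construct an OWL document
#'
#' The in-memory representation of one ontology module: declared classes with
#' optional labels, literal or resource-valued annotations, named-superclass
#' axioms, existential-restriction superclass axioms, property declarations
#' and imports. All components are tibbles; [write_owl()] serializes the
#' document as canonical RDF/XML and [read_owl()] parses it back.
#'
#' @param ontology_iri IRI of the ontology itself.
#' @param imports character vector of imported ontology IRIs.
#' @param object_properties,annotation_properties tibbles with `iri`, `label`.
#' @param classes tibble with `iri`, `label` (`NA` allowed).
#' @param annotations tibble with `iri`, `prop`, `value`, `is_resource`:
#'   annotation assertions on classes; resource-valued when `is_resource`.
#' @param subclass_named tibble with `sub`, `super`: SubClassOf a named class.
#' @param subclass_some tibble with `sub`, `prop`, `filler`: SubClassOf an
#'   existential restriction on object property `prop`.
#' @return A `dron_owl` object.
#' @export
owl_doc <- function(ontology_iri,
                    imports = character(),
                    object_properties = empty_chr_tbl("iri", "label"),
                    annotation_properties = empty_chr_tbl("iri", "label"),
                    classes = empty_chr_tbl("iri", "label"),
                    annotations = NULL,
                    subclass_named = empty_chr_tbl("sub", "super"),
                    subclass_some = empty_chr_tbl("sub", "prop", "filler")) {
  if (is.null(annotations)) {
    annotations <- tibble(iri = character(), prop = character(),
                          value = character(), is_resource = logical())
  }
  if (!"is_resource" %in% names(annotations)) annotations$is_resource <- FALSE
  structure(
    list(ontology_iri = ontology_iri,
         imports = sort(unique(imports)),
         object_properties = arrange(distinct(object_properties), .data$iri),
         annotation_properties = arrange(distinct(annotation_properties), .data$iri),
         classes = arrange(distinct(classes), .data$iri),
         annotations = arrange(distinct(annotations), .data$iri, .data$prop, .data$value),
         subclass_named = arrange(distinct(subclass_named), .data$sub, .data$super),
         subclass_some = arrange(distinct(subclass_some), .data$sub, .data$prop, .data$filler)),
    class = "dron_owl"
  )
}

#' @export
print.dron_owl <- function(x, ...) {
  cat("<dron_owl> ", x$ontology_iri, "\n  classes: ", nrow(x$classes),
      "  subclass axioms: ", nrow(x$subclass_named) + nrow(x$subclass_some),
      "  annotations: ", nrow(x$annotations),
      "  imports: ", length(x$imports), "\n", sep = "")
  invisible(x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# map a property IRI to the QName used as its RDF/XML element name; only
# properties inside the declared namespaces are serializable
iri_to_qname <- function(iri) {
  out <- character(length(iri))
  for (p in c("oboInOwl", "obo", "rdfs", "owl")) {
    hit <- startsWith(iri, NS[[p]]) & out == ""
    out[hit] <- paste0(p, ":", substring(iri[hit], nchar(NS[[p]]) + 1L))
  }
  if (any(out == "")) {
    dron_abort(paste0("property IRI outside declared namespaces: ",
                      iri[out == ""][1L]), class = "dronr_owl_namespace")
  }
  out
}

#' Serialize an OWL document as canonical RDF/XML
#'
#' Classes, axioms and annotations are emitted in sorted order, so the output
#' is a deterministic, byte-stable function of the document content, and
#' serialize/parse/serialize is a fixed point.
#'
#' @param doc a `dron_owl` document.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_owl <- function(doc, path) {
  out <- character(0)
  add <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<rdf:RDF xmlns:rdf="', NS[["rdf"]], '"')
  add('         xmlns:rdfs="', NS[["rdfs"]], '"')
  add('         xmlns:owl="', NS[["owl"]], '"')
  add('         xmlns:oboInOwl="', NS[["oboInOwl"]], '"')
  add('         xmlns:obo="', NS[["obo"]], '">')
  add('  <owl:Ontology rdf:about="', xml_escape(doc$ontology_iri), '">')
  for (im in doc$imports) add('    <owl:imports rdf:resource="', xml_escape(im), '"/>')
  add('  </owl:Ontology>')

  decl <- function(tbl, kind) {
    for (i in seq_len(nrow(tbl))) {
      add('  <owl:', kind, ' rdf:about="', xml_escape(tbl$iri[i]), '">')
      if (!is.na(tbl$label[i])) add('    <rdfs:label>', xml_escape(tbl$label[i]), '</rdfs:label>')
      add('  </owl:', kind, '>')
    }
  }
  decl(doc$annotation_properties, "AnnotationProperty")
  decl(doc$object_properties, "ObjectProperty")

  ann_by <- split(seq_len(nrow(doc$annotations)), doc$annotations$iri)
  named_by <- split(seq_len(nrow(doc$subclass_named)), doc$subclass_named$sub)
  some_by <- split(seq_len(nrow(doc$subclass_some)), doc$subclass_some$sub)
  for (i in seq_len(nrow(doc$classes))) {
    iri <- doc$classes$iri[i]
    add('  <owl:Class rdf:about="', xml_escape(iri), '">')
    if (!is.na(doc$classes$label[i])) {
      add('    <rdfs:label>', xml_escape(doc$classes$label[i]), '</rdfs:label>')
    }
    for (j in ann_by[[iri]] %||% integer()) {
      qn <- iri_to_qname(doc$annotations$prop[j])
      if (doc$annotations$is_resource[j]) {
        add('    <', qn, ' rdf:resource="', xml_escape(doc$annotations$value[j]), '"/>')
      } else {
        add('    <', qn, '>', xml_escape(doc$annotations$value[j]), '</', qn, '>')
      }
    }
    for (j in named_by[[iri]] %||% integer()) {
      add('    <rdfs:subClassOf rdf:resource="',
          xml_escape(doc$subclass_named$super[j]), '"/>')
    }
    for (j in some_by[[iri]] %||% integer()) {
      add('    <rdfs:subClassOf>')
      add('      <owl:Restriction>')
      add('        <owl:onProperty rdf:resource="',
          xml_escape(doc$subclass_some$prop[j]), '"/>')
      add('        <owl:someValuesFrom rdf:resource="',
          xml_escape(doc$subclass_some$filler[j]), '"/>')
      add('      </owl:Restriction>')
      add('    </rdfs:subClassOf>')
    }
    add('  </owl:Class>')
  }
  add('</rdf:RDF>')
  # fixed newline convention keeps output byte-identical across platforms
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

expand_name <- function(qnames) {
  # "prefix:local" (prefixes from NS) -> full IRI
  vapply(qnames, function(qn) {
    bits <- strsplit(qn, ":", fixed = TRUE)[[1L]]
    if (length(bits) == 2L && bits[1L] %in% names(NS)) {
      paste0(NS[[bits[1L]]], bits[2L])
    } else {
      qn
    }
  }, character(1L), USE.NAMES = FALSE)
}

#' Parse an RDF/XML ontology file into an OWL document
#'
#' Reads the subset of RDF/XML the pipeline emits and that OBO-style
#' ontologies commonly use: class declarations, `rdfs:label`, literal and
#' resource-valued annotation assertions, named `rdfs:subClassOf` axioms and
#' existential restrictions, property declarations and ontology imports.
#'
#' @param path RDF/XML file.
#' @return A `dron_owl` document.
#' @export
read_owl <- function(path) {
  if (!file.exists(path)) {
    dron_abort(paste0("ontology file not found: ", path), class = "dronr_missing_file")
  }
  x <- xml2::read_xml(path)
  ns <- NS

  ont <- xml2::xml_find_first(x, "./owl:Ontology", ns)
  ontology_iri <- if (inherits(ont, "xml_missing")) "" else
    xml2::xml_attr(ont, "about") %||% ""
  imports <- if (inherits(ont, "xml_missing")) character() else
    xml2::xml_attr(xml2::xml_find_all(ont, "./owl:imports", ns), "about") %||% character()
  # rdf:resource attribute, namespaced
  res_attr <- function(nodes) xml2::xml_attr(nodes, "resource")
  if (length(imports) == 0L || all(is.na(imports))) {
    imports <- res_attr(xml2::xml_find_all(ont, "./owl:imports", ns))
  }

  read_decl <- function(xpath) {
    nodes <- xml2::xml_find_all(x, xpath, ns)
    tibble(
      iri = xml2::xml_attr(nodes, "about"),
      label = vapply(nodes, function(n) {
        l <- xml2::xml_find_first(n, "./rdfs:label", ns)
        if (inherits(l, "xml_missing")) NA_character_ else xml2::xml_text(l)
      }, character(1L))
    )
  }
  obj_props <- read_decl("./owl:ObjectProperty")
  ann_props <- read_decl("./owl:AnnotationProperty")

  cls_nodes <- xml2::xml_find_all(x, "./owl:Class", ns)
  classes <- vector("list", length(cls_nodes))
  anns <- list(); named <- list(); somes <- list()
  for (i in seq_along(cls_nodes)) {
    node <- cls_nodes[[i]]
    iri <- xml2::xml_attr(node, "about")
    label <- NA_character_
    for (ch in xml2::xml_children(node)) {
      nm <- xml2::xml_name(ch, ns = ns)
      if (nm == "rdfs:label") {
        label <- xml2::xml_text(ch)
      } else if (nm == "rdfs:subClassOf") {
        res <- xml2::xml_attr(ch, "resource")
        if (!is.na(res)) {
          named[[length(named) + 1L]] <- c(iri, res)
        } else {
          restr <- xml2::xml_find_first(ch, "./owl:Restriction", ns)
          if (!inherits(restr, "xml_missing")) {
            prop <- xml2::xml_attr(xml2::xml_find_first(restr, "./owl:onProperty", ns),
                                   "resource")
            fill <- xml2::xml_attr(xml2::xml_find_first(restr, "./owl:someValuesFrom", ns),
                                   "resource")
            if (!is.na(prop) && !is.na(fill)) {
              somes[[length(somes) + 1L]] <- c(iri, prop, fill)
            }
          }
        }
      } else {
        prop <- expand_name(nm)
        res <- xml2::xml_attr(ch, "resource")
        if (!is.na(res)) {
          anns[[length(anns) + 1L]] <- c(iri, prop, res, "TRUE")
        } else {
          anns[[length(anns) + 1L]] <- c(iri, prop, xml2::xml_text(ch), "FALSE")
        }
      }
    }
    classes[[i]] <- c(iri, label)
  }
  to_tbl <- function(lst, cols) {
    if (length(lst) == 0L) return(empty_chr_tbl(cols))
    m <- do.call(rbind, lst)
    as_tibble(setNames(lapply(seq_along(cols), function(j) m[, j]), cols))
  }
  cls_tbl <- to_tbl(classes, c("iri", "label"))
  ann_tbl <- to_tbl(anns, c("iri", "prop", "value", "is_resource"))
  ann_tbl$is_resource <- ann_tbl$is_resource == "TRUE"
  owl_doc(
    ontology_iri = ontology_iri,
    imports = imports[!is.na(imports)],
    object_properties = obj_props,
    annotation_properties = ann_props,
    classes = cls_tbl,
    annotations = ann_tbl,
    subclass_named = to_tbl(named, c("sub", "super")),
    subclass_some = to_tbl(somes, c("sub", "prop", "filler"))
  )
}

#' Compare two OWL documents as axiom sets
#'
#' @param a,b `dron_owl` documents.
#' @return `TRUE` when every component (classes, axioms, annotations,
#'   declarations, imports) is set-equal.
#' @export
owl_equal <- function(a, b) {
  identical(a$ontology_iri, b$ontology_iri) &&
    identical(a$imports, b$imports) &&
    identical(as.data.frame(a$object_properties), as.data.frame(b$object_properties)) &&
    identical(as.data.frame(a$annotation_properties), as.data.frame(b$annotation_properties)) &&
    identical(as.data.frame(a$classes), as.data.frame(b$classes)) &&
    identical(as.data.frame(a$annotations), as.data.frame(b$annotations)) &&
    identical(as.data.frame(a$subclass_named), as.data.frame(b$subclass_named)) &&
    identical(as.data.frame(a$subclass_some), as.data.frame(b$subclass_some))
}
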