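# Namespace table and IRI constants shared across the package (this file
# collates first).

NS <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#",
  oboInOwl = "http://www.geneontology.org/formats/oboInOwl#",
  obo = "http://purl.obolibrary.org/obo/"
)

OBO_PREFIX <- NS[["obo"]]
IRI_LABEL <- paste0(NS[["rdfs"]], "label")
IRI_HAS_ROLE <- paste0(OBO_PREFIX, "RO_0000087")
IRI_EXACT_SYN <- paste0(NS[["oboInOwl"]], "hasExactSynonym")
IRI_RELATED_SYN <- paste0(NS[["oboInOwl"]], "hasRelatedSynonym")

empty_chr_tbl <- function(...) {
  cols <- c(...)
  as_tibble(setNames(rep(list(character()), length(cols)), cols))
}
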