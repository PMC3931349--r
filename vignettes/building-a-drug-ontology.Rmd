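---
title: "Building a modular drug ontology from historical terminology releases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a modular drug ontology from historical terminology releases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dronr)
```

## The problem

Pharmacy claims data span a decade or more, so analyses keyed on National
Drug Codes (NDCs) need codes that were valid years ago. A drug terminology
release, however, lists only currently active codes, and its concept
identifiers (RXCUIs) are mutable: identifiers are retired when entered in
error, consolidated when two identifiers denote the same product, or split;
sometimes they simply vanish with no recorded reason, taking their NDCs with
them. `dronr` reconstructs a stable view from the full release history: every
code ever curated is kept, and every retired identifier is resolved to the
latest identifier denoting the same entity, so that a query such as "all
packaged products containing furosemide" reaches codes whose identifiers
died years earlier.

## The provenance model

The core structure is a two-column conversion table from retired identifier
to current identifier, maintained release by release:

1. **Detection.** The concept-names file of a release enumerates all current
   identifiers, so any previously observed identifier absent from it has been
   retired. (We take "previously observed" to be all identifiers seen as
   atoms or NDC holders in earlier releases.)
2. **Classification.** The release's retired-identifier file explains most
   retirements: a row with `cui1 == cui2` marks entry-in-error (stored
   literally as `ERROR`); cardinality above one marks a split (stored as
   `S_RXNCUI`); a single-target row marks a merge. Error and split
   identifiers — and their NDCs — are excluded from the ontology: an
   erroneous concept's information is untrustworthy, and a split concept's
   information cannot be attributed to a child without manual review.
3. **Transitive closure.** A merge target may itself be retired later. The
   table is therefore kept compacted: every chain points directly at its
   terminal identifier, and a chain ending in error/split absorbs that
   status. Compaction is idempotent, and an incremental per-release update
   provably matches a from-scratch chain-following pass (this is tested
   against an independent oracle).

Three situations the record format does not cover required design decisions:

* **Orphans.** Identifiers that disappear with no retirement record get a
  fourth status, `ORPHANED` (a flagged self-reference). Their NDCs are kept
  and carried into the ontology, flagged: the driving use case is historical
  claims lookup, where silently dropping codes loses recall. Whether an
  upstream build would emit classes for them is unknowable from the outside;
  our inclusion is a package choice, marked as such.
* **Re-activation.** A retired identifier that reappears in a newer release
  is treated as current again and its entry dropped (logged).
* **Cycles.** The update procedure assumes none exist; we verify that
  assumption and raise an error naming the cycle rather than looping.

The identifier-change file is parsed and counted but contributes nothing: the
mapping derives entirely from the retired-identifier table plus disappearance
detection, which is sufficient to reproduce the ground truth on every
synthetic series.

## The NDC registry

One entry per (NDC, identifier) pair ever observed, with its release span;
accumulation only ever extends spans or adds entries. After the final
release, each entry's identifier is resolved through the provenance table,
partitioning all entries into included / excluded-error / excluded-split /
orphaned — a partition the tests assert is conservative (counts sum to the
number of distinct pairs). When one code's entries resolve to different
identifiers (a reused code), the entry with the latest `last_seen` wins at
export and the losers are logged; the terminology never specifies a
tie-break, so we chose the most recent observation, with included beating
orphaned and larger identifier as final deterministic tie-breaks.

## Lexical mapping to ChEBI

Ingredient names are matched against three annotation types — label, exact
synonym, related synonym — using *normalized* exact equality: case-fold, trim
and collapse internal whitespace. Byte equality would be brittle across
sources that differ only in case or spacing; anything looser (fuzzy matching)
risks false ingredient identities, which in an ontology are worse than gaps.
Matching is resolved in priority order label > exact synonym > related
synonym. A name matching two distinct classes at its best rank is *not*
mapped: it is minted a new identifier and written to a curation report. That
policy is motivated by a real failure mode this pipeline must guard against:
a protein-hormone ingredient whose name is a synonym of a *role* class
("growth hormone") would be mapped to a role rather than a molecule. The
shipped override file pins that ingredient (somatropin) to the Protein
Ontology somatotropin class instead; the override table always beats the
index. Matched classes are imported together with their full is-a closure so
the fragment is ancestor-closed; unmatched ingredients become children of
'processed material' (most are plant extracts, i.e. products of processing).

Disposition–ingredient links (mechanism of action) are mined from ChEBI
roles for the three dispositions with a usable role (beta-adrenergic
antagonist, proton pump inhibitor, calcium channel blocker), including role
subclasses. Because a ChEBI role can be broader than the disposition — the
generic calcium-channel-blocker role covers both L-type blockers and the
T-type-selective anticonvulsant ethosuximide — a curated exclusion list
removes known over-matches, and three dispositions (vitamin K epoxide
reductase inhibition, NKCC2 inhibition, T-type calcium-channel inhibition)
are populated from curated lists only. Role linkage in the snapshot is
auto-detected: existential has-role restrictions first, falling back to
annotation-style assertions (the form OBO-serialized files use).

## The normalized entity graph

Entities are keyed by *terminal* identifier, so concepts merged by
provenance collapse to one entity automatically; each entity keeps the most
recently observed name, preferring the terminal concept's own atom.
Relationship endpoints are remapped through resolution, with two rules:

* edges touching an error/split identifier are dropped (logged);
* a surviving concept's **own** assertions take precedence over relationships
  inherited from concepts merged into it — otherwise a merge would graft the
  victim's parent link onto the survivor next to its own, leaving the
  survivor with two parent forms. Residual multi-parent conflicts (possible
  in principle with inconsistent inputs) fall back deterministically to the
  smallest terminal, logged.

A clinical drug whose form link never appeared is kept, flagged dangling, and
parented directly under 'drug product' at emission; dropping it would
silently lose its NDCs. Each included NDC becomes a packaged product under
the branded or clinical drug whose terminal identifier it resolves to; codes
resolving to an ingredient or form, or to nothing, are flagged unattachable
and reported. The store is held as a set of normalized tibbles named after
the conventional tables (`clinical_drug_form`, `clinical_drug`,
`branded_drug`, `ndc`, `ingredient`, `disposition`, `rxcui`, `rxnorm`, plus
explicit `cdf_ingredient` and `disposition_ingredient` many-to-many tables)
and can be persisted as a TSV directory with `export_store()`.

## OWL emission

Emission follows six ordered steps (ingredients, dispositions, forms,
clinical drugs, branded drugs, packaged products), each depending on its
predecessors, and routes classes to five modules by origin; `dron-full`
contains only the four imports. Choices the interface left open:

* **Serialization** is RDF/XML (the OBO convention), produced by a canonical
  writer: classes and axioms are emitted in sorted order, so identical
  content yields byte-identical files and serialize → parse → serialize is a
  fixed point. Minted identifiers (`DRON_` + zero-padded 8-digit counter,
  programmatic range starting at 20 000) are assigned after sorting entities
  by type, terminal identifier and code, making IRI assignment invariant
  under input row order.
* **Quantifiers**: existential (`someValuesFrom`) restrictions throughout;
  the modeled relations ("has some ingredient as proper part", "bears some
  disposition") are inherently existential.
* **Property IRIs**: `bearer_of` reuses RO_0000053 and role mining
  RO_0000087; `has_proper_part` and `has_Rxcui` get DrOn-namespace IRIs
  (no exact standard equivalent in the shape used). All three are declared in
  the upper module.
* **External upper-level classes** ('material entity', 'role', 'disposition',
  'processed material', 'protein') are stub declarations — IRI plus label —
  rather than full imports, keeping the build network-free.
* The 'drug product' definition is asserted as a definition annotation on
  the curated class; no per-product 'clinical drug role' axioms are emitted.
  'drug tablet' and 'drug capsule' are declared but unused: linking products
  to dose forms is out of scope (dose-form semantics in the source data are
  muddled, e.g. container-like "forms").

**Consistency checking.** The emitted ontologies stay inside a bottom-free
Horn fragment — class declarations, named SubClassOf, existential
restrictions, annotations; no negation, disjointness or cardinality — in
which every class is satisfiable by construction. `check_modules()` verifies
that profile and the structural obligations that make the artifact usable:
five modules with the connector importing exactly the other four, each class
declared in exactly one module, declaration closure for every reference, an
acyclic subclass graph, exactly one product restriction per packaged
product, and every drug-product chain reaching 'drug product'. This is the
package's satisfiability certificate; it is deliberately a profile argument,
not a call to an external reasoner.

## The synthetic fixture generator

`generate_release_series()` emulates exactly the phenomena the provenance
machinery exists for: merges (cardinality-1 records, with NDCs following the
survivor), splits (two cardinality-2 rows), entries-in-error
(`cui1 == cui2`), and silent disappearances (no record). Merge survivors are
drawn from concepts still alive at the event release, so chains of
re-retirement arise naturally, and when two merges land in different
releases the first is deliberately chained into the second's victim so every
series exercises transitive closure. Events target clinical drugs without
branded children, which keeps the ground-truth bookkeeping exact without
loss of coverage (branded-drug re-parenting is covered by dedicated tests).
The retired-identifier file is cumulative across releases, as in real data.
The companion mini-ChEBI contains the canonical furosemide class (accession
47426) under its standard label, per-annotation-type matchable classes in a
small is-a hierarchy, the three mined roles linked to designated
ingredients, and the 'growth hormone' decoy role carrying "somatropin" as a
related synonym — the trap the override must beat.

Default conditions: 40 ingredients, 50 forms, 70 clinical drugs, 30 branded
drugs, 120 codes over five releases (~190 concepts), with 6 merges, 3
splits, 3 errors and 3 silent disappearances; match fractions 0.30 / 0.05 /
0.15 for label / exact / related, echoing the label-dominant,
exact-synonym-rare proportions seen on real terminology data. The end-to-end
suite runs twenty seeds at this size; unit tests use a smaller variant
(12/8/16/4 concepts, four releases). Identifiers come from a high numeric
range disjoint from real identifiers, and codes are random 11-digit strings.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: realistic drug-name text (no lexical ambiguity
stress beyond the constructed cases), concept churn in ingredients and forms
(events target clinical drugs), the identifier-change file's semantics
(present but empty of meaning), licensed-scale volumes, and real releases'
occasional referential inconsistencies beyond the cases tolerated by design.
Reported headline figures from licensed historical data (hundreds of
thousands of classes) are consequently out of reach at fixture scale and are
not asserted anywhere in the suite.

## Known limitations

* Split concepts' information is never redistributed to children; like the
  upstream practice, that requires manual curation.
* Strength/unit parsing from drug names, dose-form linkage and
  packaging-level structure (bottles vs boxes) are out of scope.
* The OWL parser reads the RDF/XML subset the writer emits plus common
  OBO-style patterns; it is not a general RDF parser.
* Match-type tallies on fixtures reflect configured quotas, not the
  proportions any particular real ChEBI release would give.
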