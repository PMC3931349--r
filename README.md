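# dronr

`dronr` builds a modular OWL 2 drug ontology from a chronological series of
releases in the RxNorm Rich Release Format (RRF). It is aimed at researchers
who need a **historically comprehensive registry of National Drug Codes
(NDCs)** — for example to pull a decade of pharmacy claims for every product
containing a given active ingredient — which no single terminology release
provides: a release lists only currently active codes, and codes are routinely
lost when a drug-concept identifier (RXCUI) is retired.

## What it does

The pipeline has three stages:

1. **Extraction.** Each release is parsed from the pipe-delimited RRF dialect:
   drug-concept atoms of the four relevant term types (ingredient IN, clinical
   drug form SCDF, clinical drug SCD, branded drug SBD), RxNorm-curated NDC
   attributes, retirement records and the release version. Two cumulative
   structures are maintained across releases:
   * a **provenance table** mapping every retired identifier to its terminal
     resolution. Per release: identifiers missing from the concept file are
     detected as retired; retirement records classify them
     (`cui1 == cui2` → entered in error, stored as `ERROR`; cardinality > 1 →
     split, stored as `S_RXNCUI`; otherwise merged into `cui2`); identifiers
     that vanish with **no** record are flagged `ORPHANED`. The table is kept
     transitively closed, so chains of re-retired identifiers
     (`A → B`, `B → C`) compact to direct links (`A → C`), with error/split
     status absorbed along chains;
   * an **NDC registry** holding every (NDC, RXCUI) pair ever observed with
     its release span — nothing is ever deleted.
2. **Normalization.** Ingredients are mapped to ChEBI classes by exact
   lexical matching (after case/whitespace normalization) over `rdfs:label`,
   exact synonyms and related synonyms, with manual overrides and an
   ambiguity-to-curation-report policy; matched classes are imported with
   their is-a closure; disposition–ingredient links (mechanism of action,
   e.g. beta-adrenergic receptor blockade) are mined from ChEBI roles with
   curated additions and exclusions. Everything is then assembled into a
   normalized entity graph keyed by *terminal* identifier, so merged concepts
   collapse into one entity, and each included NDC is attached to its
   clinical or branded drug.
3. **Emission.** The graph is serialized as five OWL 2 modules in
   deterministic RDF/XML: `dron-upper` (hand-curated scaffold: 'drug
   product', 'packaged drug product', six molecular dispositions, the
   `has_proper_part` / `bearer_of` / `has_Rxcui` properties), `dron-chebi`,
   `dron-pro`, `dron-rxnorm`, and `dron-full` (imports only). Axiom patterns:
   CDF ⊑ 'drug product' ⊓ ∃has_proper_part.Ingredient;
   CD ⊑ CDF; BD ⊑ CD; each packaged product ⊑ 'packaged drug product' ⊓
   ∃has_proper_part.(CD ⊔ BD) with exactly one product restriction; bearing
   ingredients get ∃bearer_of.Disposition; every release-derived class
   carries one `has_Rxcui` annotation.

Because real releases are distributed under a UMLS license, the package ships
a seeded **synthetic-fixture generator** (`generate_release_series()`,
`generate_mini_chebi()`) that emulates the RRF dialect and a mini-ChEBI with
known ground truth (merges, splits, entry-in-error retirements, silent
disappearances, matchable names per annotation type), so every stage is
testable offline.

## Worked example

```r
library(dronr)

cfg    <- fixture_config(seed = 42)          # ~190 concepts, 5 releases
series <- generate_release_series(cfg, tempfile())
chebi  <- tempfile(fileext = ".owl")
generate_mini_chebi(cfg, chebi)

b <- build_dron(series$dirs, chebi, out_dir = "owl")
#> <dron_build> 5 release(s)
#> <dron_graph> ingredients: 40  dispositions: 6  CDFs: 50  CDs: 58  BDs: 30  packaged products: 101
#> <dron_modules>
#>    dron-full    0 classes
#>    dron-chebi   24 classes
#>    dron-rxnorm  258 classes
#>    dron-pro     2 classes
#>    dron-upper   15 classes
```

70 clinical drugs went in but 58 entities come out: 6 were merged away, 3
retired as entered in error and 3 split (both excluded, with their codes),
while 3 that disappeared silently are retained as flagged orphans. The
registry keeps every observation:

```r
glance(b$registry)
#>   n_pairs n_ndcs n_releases n_included n_excluded_error n_excluded_split n_orphaned
#> 1     136    120          5        105                8               17          6
```

120 distinct codes produced 136 historical (NDC, RXCUI) pairs; after
provenance resolution 105 are included (codes whose identifier merged follow
it to the terminal concept), 25 are excluded with their error/split
identifiers, and 6 ride along flagged. The validation queries:

```r
ndcs_by_ingredient(b$graph, "furosemide")
#> 10 codes: "06086430031" "14738984620" "33696828741" ...
ndcs_by_disposition(b$graph,
  "function-inhibiting Na-K-Cl cotransporter 2 (NKCC2) binding disposition")
#> the same 10 codes (furosemide is the curated bearer of NKCC2 inhibition)
```

and the lexical mapping tally over the 40 ingredients:

```r
match_tally(b$mappings)
#>   matched_via         n
#>   exact_synonym       2
#>   label              12
#>   none               19
#>   override            1      # somatropin -> Protein Ontology, not the
#>   related_synonym     6      # 'growth hormone' role its name matches
```

`write_dron(b$modules, dir)` writes the five `.owl` files; output is
byte-deterministic and `read_dron()` round-trips it exactly.

A thin command-line wrapper is installed at `inst/cli/dron.R`
(`synth`, `build`, `query`, `resolve`, `ndc-status` subcommands).

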