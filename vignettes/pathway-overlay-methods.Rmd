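---
title: "Methods: symbol normalization, pathway enrichment and icon-overlay rendering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbol normalization, pathway enrichment and icon-overlay rendering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathoverlay)
```

`pathoverlay` joins gene-keyed annotation tables onto pathway gene sets and
topologies, counts and tests per-pathway overlap, and renders static
icon-overlay diagrams. This vignette records the model, the parameters that
matter, the numerical choices, and what the synthetic-data generators do and
do not emulate.

## The normalization model

Human gene symbols in user files are noisy: aliases, retired names, mixed
case. Normalization is two-phase against an HGNC-style reference of
approved symbols with synonym lists:

1. **Phase 1 (approved).** The canonical form of the input — uppercased,
   whitespace-trimmed — is looked up among canonical forms of the approved
   symbols. A hit returns the approved symbol in reference casing.
2. **Phase 2 (synonym).** Only on a phase-1 miss is the synonym map
   consulted. The map is *disambiguated at build time*: any synonym listed
   under two or more approved symbols is removed outright and can never
   resolve, because silently picking one of several genes would corrupt
   every downstream count. A synonym whose canonical form equals an
   approved symbol is also excluded from the map — phase 1 would win anyway,
   and keeping it would make the map's invariants depend on lookup order.
3. Anything else is **unmatched** and lands in the downloadable report,
   partitioned into *invalid symbols* (no HGNC match) and *out-of-pathway*
   genes (valid, but absent from every loaded pathway, hence invisible in
   any view).

Design points that were genuinely open and how they were settled:

- **Case sensitivity.** The matching rule is case-insensitive. Human HGNC
  symbols are conventionally uppercase while user files vary (`p53`,
  `kras`); a case-sensitive match would mostly manufacture spurious
  unmatched entries. Output always uses reference casing so downstream
  joins are exact.
- **Previous symbols vs aliases.** HGNC distinguishes them; the reference
  format here folds both into one synonym list. The distinction does not
  change the resolution rule, only provenance, and keeping one list keeps
  the TSV dialect trivial (second column, `,` or `|` separated).
- **Duplicate synonyms under one gene** count once before ambiguity
  counting; multiplicity carries no information.

## Annotation ingestion

The input format is a tab-delimited table, gene symbol first column,
optional single `#`-prefixed header line. Choices: data lines with *fewer*
fields than the header are right-padded with empty strings under a warning
(ragged spreadsheet exports are common and recoverable), while *more*
fields is a hard error naming the line (silent column drift would misalign
every tooltip). Later lines starting with `#` are data — only the first
line has header semantics. Duplicate gene rows are all retained and the
gene index maps one gene to many rows; tooltips aggregate them. The upload
preview returns the first 10 *data* rows (the header is not counted — it is
displayed as column names, so counting it would show 9 rows of what the
user actually wants to check).

## Counting and enrichment

The counting unit is the **distinct gene**: `count_annotated()` returns
|P ∩ A| for pathway genes P and annotation genes A, so a gene with five
variant rows contributes once. Enrichment is the one-sided Fisher's exact
(hypergeometric upper-tail) probability of at least `k` annotated genes in
an `n`-gene pathway given `K` annotated genes among `N`:

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}$$

Two decisions the table's single p-value column leaves open:

- **Sidedness.** One-sided over-representation. "More annotated genes than
  expected by chance" is an upper-tail question; the two-sided test would
  also flag depletion, which is not what the column communicates.
- **Universe.** `N` is the union of genes over the loaded pathway
  collection, and annotation genes outside it are excluded from `K`. This
  matches how the unmatched report treats out-of-pathway genes as
  non-participating; a whole-genome universe would make every pathway look
  enriched against genes that can never appear in any row of the table.
  Both choices are visible in the API (`with_enrichment`, `adjust`) rather
  than buried.

Raw p-values are the primary output; Benjamini–Hochberg adjustment is
available behind `adjust = "BH"` and off by default, mirroring a display
that shows one p-value column per set.

**Numerics.** The tail is accumulated from `lchoose()` log-binomial terms.
For any `k` at or below the distribution's minimum support point
(`max(0, n - (N - K))`) the function returns exactly 1 rather than a
rounded sum, so degenerate margins (`k = 0`, `K = N`) are exact. On
universes up to 10^4 genes the largest relative error against exhaustive
subset enumeration (all C(N, n) subsets, N ≤ 12) measured in the acceptance
script is below 10^-14; `stats::phyper` and `stats::fisher.test` serve as
independent cross-checks in the suite, never as the implementation.

**Sorting.** The summary table sorts with a stable radix order, so ties
keep their collection order, repeated identical sorts are idempotent, and
ascending/descending are exact reversals exactly when keys are distinct.

## Topologies and rendering

XGMML is parsed leniently: coordinates come from the `graphics` child when
present, else from node-level `att` elements, else from a deterministic
row-major grid (140 × 70 cell) — a renderable diagram must never depend on
a coordinate gap. Coordinates are taken as continuous screen units, y
growing downward, matching both SVG and Cytoscape's export convention, so
no axis flip is applied. A node's gene identity comes from its label,
split on `/` and `,` before normalization so KEGG-style family boxes
(`CDK4/6`) map to every member; unresolvable labels (compounds, `ATP`)
stay as non-gene nodes and never receive icons.

Rendering conventions (the source material shows icons adjacent to genes
but prescribes no geometry):

- one icon per (node, set) hit, 14 × 14 units, in a horizontal strip
  anchored at the node box's top-right corner, left-to-right in set load
  order, wrapping after 4 icons;
- one tooltip block per hit, hidden by default and shown on hover via
  embedded CSS only — no scripts, so the SVG/HTML is fully offline-viewable;
  the same text is duplicated in a `<title>` element for SVG viewers
  without CSS hover;
- a legend listing every loaded set exactly once, hits or not;
- each gene node label wrapped in a hyperlink built from a configurable
  template, defaulting to the GeneCards display page for the approved
  symbol;
- a custom-pathway background image, when given, is drawn beneath the
  nodes with no registration or scaling logic: the XGMML coordinates are
  trusted, because no alignment procedure is defined for the image pair.

Output is deterministic by construction: fixed number formatting
(`%.2f`, trailing zeros stripped), no timestamps, no randomness — identical
inputs give byte-identical files, which the suite checks by re-running the
whole pipeline from the fixture files.

User icons are restricted to png/jpg/gif and are embedded as base64 data
URIs so the rendered file stays self-contained.

## What the fixture generators emulate

`fixture_spec()` fixes the study conditions for every test and for the
acceptance script. Defaults, chosen once as a realistic small working set:
60 approved symbols with 1–3 synonyms each, 2 deliberately ambiguous
synonyms, 10 pathways of 5–12 genes, 3 annotation files covering 30% of the
pathway universe with 2 value columns, 3 invalid symbols and 2 HGNC-valid
genes outside every pathway per file. These sizes make every code path
observable (ambiguity dropping, synonym spelling, case variants, both
unmatched partitions, multi-set overlaps) while keeping the full suite in
tens of seconds; the exhaustive enrichment check enumerates all ≈3,100
valid contingencies with N ≤ 12. The `out_of_pathway_count` knob exists
precisely so the second report partition is non-trivially exercised.

Each generator reseeds R's RNG from `seed` plus a fixed per-generator
offset, so individual files and the bundle as a whole are byte-identical
across reruns, and the annotation generator writes a ground-truth manifest
(true per-pathway overlaps, both unmatched lists) from its own bookkeeping,
independent of the parsers it is later checked against.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: realistic pathway topology (fixtures are grids
with a chain of edges, not curated maps), realistic symbol noise
(real files contain Excel-mangled dates, Entrez IDs, trailing annotations),
overlapping pathway collections with heavy gene sharing, scale (hundreds of
pathways, 10^4-gene universes) and real HGNC content with its
previous-symbol history. The parsers and the statistics are exercised on
the formats' full grammar, but performance and curation quirks of
production pathway sources are out of scope.

## Known limitations

- Only GMT and XGMML are read; KGML, BioPAX and SBML are not.
- No graph layout beyond the grid fallback; topology is drawn, not laid out.
- Enrichment is overlap-based; no rank-based (GSEA-style) or
  topology-aware testing.
- Gene identifiers other than symbols (Entrez, Ensembl) are not mapped.
- The CLI is stateless; there is no server mode, authentication or data
  sharing — those concerns belong to a hosting application, not this
  library.
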