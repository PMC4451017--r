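# pathoverlay

Headless R toolkit for interpreting **gene-centric annotation tables in the
context of biological pathways**. It is aimed at bioinformaticians who hand
filtered, gene-keyed results (somatic variants, expression hits, drug-gene
links, phenotype terms, ...) to clinical researchers or a tumor board: each
table becomes an *annotation set* with its own display icon, and pathways are
rendered as static SVG/HTML diagrams where every annotated gene carries one
icon per set, with a hover tooltip showing the underlying rows and a
GeneCards hyperlink on every gene.

The computational core:

- **Two-phase HGNC symbol normalization.** An input symbol is matched
  case-insensitively against HGNC *approved symbols* first; only on a miss is
  it matched against the *synonym* (alias) list. Synonyms associated with
  more than one approved symbol are removed from the reference at build time,
  so an ambiguous alias can never silently resolve. Symbols that match
  neither are reported, partitioned into invalid symbols and genes outside
  every loaded pathway.
- **Per-pathway counting and enrichment.** For each pathway and each
  annotation set, the number of *distinct* annotated member genes
  k = |P ∩ A| is tabulated (a gene with five variant rows counts once).
  Over-representation is tested with the one-sided Fisher's exact
  (hypergeometric upper-tail) probability

  p = Σ<sub>i=k</sub><sup>min(n,K)</sup> C(K,i) · C(N−K, n−i) / C(N,n)

  where n = |P| genes in the pathway, K annotated genes in the universe, and
  N the universe size — the union of genes over all loaded pathways.
  Benjamini–Hochberg adjustment is available behind a flag.
- **Pathway models.** Gene membership from GMT files; drawing topology
  (nodes, edges, coordinates) from Cytoscape XGMML exports, with family
  labels like `CDK4/6` resolved to every matched gene and a deterministic
  grid fallback for missing coordinates.
- **Deterministic rendering.** Identical inputs produce byte-identical SVG;
  tooltips are pure CSS (no scripts), so the output is viewable offline.
- **Seeded fixture generators** for HGNC tables, pathway collections and
  annotation files with a ground-truth manifest, so the whole pipeline is
  testable without any download.

## Worked example

```r
library(pathoverlay)

hgnc <- hgnc_table(c("TP53", "KRAS", "CCND1", "CDK4", "CDK6", "YAP1", "ATM"),
                   list(c("p53"), c("KRAS2", "K-RAS"), c("BCL1", "PRAD1"),
                        character(), character(), c("YAP"), character()))
norm <- build_normalizer(hgnc)

writeLines(c("G1_cycle\tcell cycle\tTP53\tCCND1\tCDK4\tCDK6",
             "Hippo\tsignaling\tYAP1\tCCND1\tTP53",
             "DDR\tdamage response\tTP53\tATM"), "demo.gmt")
coll <- pathway_collection(read_gmt("demo.gmt", norm = norm))

writeLines(c("#Gene\tvariant\tVAF",
             "p53\tsplice\t0.38", "CCND1\tP287T\t0.47", "YAP\tamplified\t0.61",
             "ATM\tc.7271T>G\t0.12"), "variants.tsv")
res <- normalize_annotation(attach_icon(parse_annotation_file("variants.tsv"),
                                        "circle"),
                            norm, coll$universe)
st <- build_summary_table(coll, list(res$set), with_enrichment = TRUE)
sort_table(st, "variants_p", "asc")
```

```
  pathway_id     name source n_genes variants_count variants_p
1      Hippo    Hippo   demo       3              3        0.2
2        DDR      DDR   demo       2              2        0.4
3   G1_cycle G1_cycle   demo       4              2        1.0
```

All three Hippo genes are annotated (`variants_count = 3` of `n_genes = 3`);
with 6 of the 7 universe genes annotated the upper-tail probability of that
overlap is 0.2. Note that `p53` and `YAP` were typed as aliases and counted
under their approved symbols. Rendering the same sets on a topology:

```r
topo <- read_xgmml("hippo.xgmml", norm = norm)
doc  <- compute_overlay(topo, list(res$set))
writeLines(render_html(doc), "hippo.html")   # icons + hover tooltips + links
```

## Command line

```sh
exec/pathoverlay fixtures  --seed 4 --out fx
exec/pathoverlay summarize --gmt fx/pathways.gmt --hgnc fx/hgnc.tsv \
    --annot fx/annot_1.tsv:pill --annot fx/annot_2.tsv --enrich --out table.tsv
exec/pathoverlay render    --xgmml fx/pathway_01.xgmml --hgnc fx/hgnc.tsv \
    --gmt fx/pathways.gmt --annot fx/annot_1.tsv --out pathway.svg
```

Exit codes: 0 success, 1 input/format error, 2 usage error. Outputs are
written atomically and contain no timestamps, so identical invocations give
identical files.

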