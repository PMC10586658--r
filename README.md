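# regcircuit

Differential regulatory-circuit analysis of two related epithelial cell
states (generically **A** and **B**, e.g. limbal stem cells and epidermal
keratinocytes) against a lineage-distant reference state (**REF**, e.g.
embryonic stem cells).

## The problem

Two closely related cell types often share most of their master regulators,
so a direct differential network comparison between them misses exactly the
transcription factors (TFs) that matter for both. This package implements a
reference-anchored comparison design: build a TF→gene binding network per
state, score each TF's *influence* in the two reference-anchored
differential networks (REF→A and REF→B), and read the shared program off
TFs that score high in **both**, while cell-type-specific TFs score high in
only one. On top of the networks, a delta-binding-score rule classifies
every TF→TF regulation as shared or state-specific, and two enrichment
statistics test whether a TF's genome-wide binding concentrates at disease
gene lists.

The pipeline stages:

1. **CRE catalogue** — pool the top-N accessibility peaks per state, merge
   overlapping summit windows transitively; quantify each chromatin mark in
   a mark-specific window around every summit (ATAC 200 bp, H3K4me3 and
   H3K27ac 2 kb, H3K27me3 5 kb); `log10(x+1)` + quantile normalization.
2. **Differential CRE classification** — a bespoke negative-binomial Wald
   test (median-of-ratios size factors, trend-shrunk method-of-moments
   dispersions) for the count-like marks; an activity-threshold (Otsu) plus
   variance selection for H3K4me3/H3K27me3. Reported as the percentage of
   the catalogue with differential signal in any mark (union semantics).
3. **Gene linking** — promoter links (closest TSS within 20 kb) and
   enhancer aggregates: all CREs within 100 kb of a TSS, summed with a
   logistic distance weight `w(d)` with `w = 1` up to 2 kb,
   `w(50 kb) = 0.5`, `w = 0` past 100 kb.
4. **Binding networks and influence** — per-CRE TF binding proxy
   = motif hit × min–max-scaled mean of ATAC and H3K27ac signal in the
   state; `B(tf, gene)` = min–max-scaled distance-weighted sum over the
   gene's enhancer window. Influence(tf) ∝ Σ over the top differential
   edges of `max(0, B_target − B_source) · max(0, log2FC)` over
   significantly up-regulated target genes, scaled to `[0, 1]`.
   Shared TFs: influence > 0.5 in both REF→A and REF→B; A-specific:
   > 0.5 in REF→A and ≤ 0.2 in REF→B.
5. **TF hierarchy** — per TF→TF edge, `ΔB(REF→A)`, `ΔB(REF→B)` and the
   direct `ΔB(A vs B)`; if the mean reference-anchored delta is at least
   `|direct|` the regulation is shared, otherwise the gaining state names it.
6. **Disease-gene binding enrichment** — per-gene distance-weighted binding
   scores feed a one-sided Mann–Whitney U test (disease genes bound more
   than the rest of the genome); an alternative maps each peak to its
   nearest TSS and applies a one-sided Fisher exact test; BH FDR across all
   TF × list pairs, significance at FDR < 0.1, top-5 bound loci reported.
7. **Expression** — gene filters (chrX/Y removed, < 10 total counts
   removed), NB Wald DE at padj ≤ 0.01 and |log2FC| ≥ 0.58, least-squares
   batch removal for visualization, and preranked GSEA (weighted
   Kolmogorov–Smirnov running sum with a permutation null).

A fully seeded synthetic-data generator (`simulate_landscape()`,
`simulate_expression()`, `simulate_tf_peaks()`) plants shared,
A-specific, B-specific and REF-specific regulatory programs plus excess
disease-gene binding, so every stage is testable without external data.

## Worked example

```r
library(regcircuit)
cfg <- pipeline_config(rng_seed = 42L)
run_pipeline(cfg, out_dir = "demo")          # simulate ... motif, ~10 s

cls <- read_table_tsv("demo/tf_classification.tsv")
head(cls[order(-cls$influence_ref_a)], 5)
#>        tf influence_ref_a influence_ref_b             class
#> 1:  TF002      1.00000000      0.91115718 shared-epithelial
#> 2:  TF005      0.98427165      0.07267217        A-specific
#> 3:  TF003      0.89839691      0.84350943 shared-epithelial
#> 4:  TF001      0.83167371      0.76551104 shared-epithelial
#> 5:  TF004      0.80112887      0.66637944 shared-epithelial
```

The generator planted TF001–TF004 as shared epithelial TFs and TF005 as the
A-specific master regulator; the pipeline recovers exactly that: the shared
TFs score above 0.5 in both reference-anchored comparisons, TF005 scores
0.98 in REF→A but 0.07 in REF→B.

```r
read_json_artifact("demo/differential_summary.json")
#> $n_differential 1575; $n_total 5000; $percent 31.5
```

31.5% of the 5000-CRE catalogue carries differential epigenetic signal in
at least one mark (the generator plants 30% per mark; the union over marks
plus test noise gives slightly more).

```r
enr <- read_table_tsv("demo/disease_enrichment.tsv")
enr[enr$significant, c("tf", "test", "p", "fdr")]
#>        tf        test            p          fdr
#> 1:  TF005      fisher 1.647208e-07 4.941624e-07
#> 2:  TF005 mannwhitney 3.297597e-14 9.892792e-14
```

Both statistics flag the planted disease TF (TF005 binds the simulated
disease gene list in excess) at FDR < 0.1, and neither flags the
size-matched random control list.

Command line (equivalent):

```sh
Rscript inst/scripts/regcircuit all --config cfg.json --seed 42 --out demo
```

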