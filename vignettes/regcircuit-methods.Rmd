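---
title: "regcircuit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regcircuit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical models, the
tunable parameters that matter, what the synthetic-data generator does and
does not emulate, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# The comparison design

Two related cell states A and B share most of their master regulators, so
a direct A-vs-B differential network hides the shared program. The package
therefore anchors both comparisons at a lineage-distant reference state
REF: influence scores are computed for the REF→A and REF→B differential
networks, and a TF is

* **shared** when influence > 0.5 in *both* anchored comparisons,
* **A-specific** when influence > 0.5 in REF→A and ≤ 0.2 (low or
  undetected) in REF→B, symmetrically for B,
* **neither** otherwise (e.g. 0.8/0.35: high in A but not convincingly
  absent in B).

The 0.5 and 0.2 cutoffs are exposed as
`influence_shared_threshold`/`influence_low_threshold` in
`pipeline_config()`.

# CRE catalogue and per-mark classification

The catalogue is built from accessibility peak *summits*: the `top_n_peaks`
(default 100,000) highest-scoring peaks per state are pooled and summits
whose `merge_radius_bp`-wide centred windows overlap are merged
transitively (merged summit = rounded mean). The merge radius defaults to
the ATAC quantification window (200 bp) because no explicit radius is
standard; it is configurable.

Mark signal is counted in mark-specific centred windows — ATAC 200 bp,
H3K4me3/H3K27ac 2 kb, H3K27me3 5 kb — by any-overlap of fragments with the
half-open window (a fragment abutting the window end is not counted;
0-based half-open coordinates throughout, converted to Bioconductor's
1-based convention in exactly one tested place).

Normalization is `log10(count + 1)` followed by quantile normalization:
the value at rank r in every column is replaced by the mean of rank-r
values across columns. **Ties** receive the mean of the reference values at
their tied positions; this deliberately breaks the "all sorted columns are
identical" property when tie patterns differ between columns, which is why
the exactness test uses continuous (tie-free) input.

Two classification routes:

* **ATAC and H3K27ac** (count-like): a bespoke negative-binomial Wald test —
  median-of-ratios size factors; per-feature method-of-moments dispersion
  corrected for the shot-noise component, shrunk on the log scale toward a
  parametric trend `a0 + a1/mu` with weight `df/(df+6)`; group means by
  vectorized Newton with sample offsets; Wald statistic referred to a *t*
  distribution with `df_residual + 6` degrees of freedom. The extra 6 df
  represent the information the trend contributes to the dispersion
  (moderated-t logic); under a pure NB null at n = 3 vs 3 and dispersion
  0.1 this brings the type-I fraction at p < 0.05 to ≈ 0.05 and raw
  p-values to approximate uniformity (verified by the acceptance suite).
  Exact equality with any external count-model package is not claimed.
* **H3K4me3 and H3K27me3**: step 1 discards CREs whose maximum normalized
  signal falls below an activity cutoff — by default the two-class
  variance-minimizing (Otsu) split of the pooled signal distribution,
  because the underlying histone-signal distributions are bimodal
  (signal vs no-signal) and no absolute cutoff is universal; an absolute
  override is exposed (`activity_cutoff`). Step 2 selects retained CREs
  whose between-state |mean difference| exceeds the q = 0.75 quantile of
  differences *and* whose two-sided rank-sum p < 0.05. Note the exact
  rank-sum test needs ≥ 4 samples per state to be able to fall below 0.05
  (the minimum two-sided p at 3 vs 3 is 0.1).

The headline reporting utility uses **union semantics**: a CRE counts as
differential once however many marks flag it
(`differential_cre_fraction()`).

# Gene linking

Promoter links: each CRE to its closest TSS within 20 kb; exact distance
ties resolve to the lexicographically smaller gene id. Enhancer
aggregates: all CREs with |TSS − summit| ≤ 100 kb contribute
`w(d) · signal`, where the weight is a logistic decay

\[ w(d) = \begin{cases} 1 & d \le r_0 \\
   \dfrac{2e^{-\mu (d-r_0)}}{1+e^{-\mu(d-r_0)}} & r_0 < d \le d_{max} \\
   0 & d > d_{max} \end{cases} \]

with \(r_0 = 2\) kb (promoter-proximal CREs count fully), \(\mu\) anchored
so \(w(50\,\mathrm{kb}) = 0.5\) (closed form \(\mu = \log 3 / (d_{1/2} -
r_0)\)), and a hard cutoff at 100 kb. The published functional form of the
upstream tool's weight is not printed anywhere we could verify, so this
anchored logistic is documented as an approximation with every parameter
configurable; a 50 kb window variant (mentioned in some result summaries)
is available via `enhancer_window_bp`. Distances are measured
summit-to-TSS, since the summit is the catalogue's coordinate.

# Binding networks, influence and hierarchy

The trained TF-binding models of the original network tool are *not*
reproduced. A transparent proxy with the same interfaces replaces them:
per CRE, binding propensity = motif-hit indicator × min–max-scaled mean of
the state's ATAC and H3K27ac signal; per (TF, gene) edge, the
distance-weighted sum of that propensity over the gene's enhancer window,
min–max scaled across the network so B ∈ [0, 1] and the top edge scores
exactly 1. The package's contributions — the reference-anchored design,
the 0.5 shared rule, the delta-binding hierarchy — sit on top of any
binding score; the proxy makes them testable.

Influence: edge differential score `max(0, B_target − B_source)`; the top
`max_differential_edges` (default 500,000) edges are kept; raw influence of
a TF is the sum of edge score × `max(0, log2FC)` over significantly
up-regulated target genes, and influence = raw / max(raw). Missing edges
score 0 (mirroring the "no missing values" backfill of the original
analysis). Target-gene log2FC enters influence; the hierarchy
classification below deliberately excludes expression.

Hierarchy: for each TF→TF edge, `ΔB(REF→A) = B_A − B_REF`,
`ΔB(REF→B) = B_B − B_REF`, direct `Δ = B_A − B_B`. If
`mean(ΔB(REF→A), ΔB(REF→B)) ≥ |Δ|` the regulation is shared (ties default
to shared, the conservative branch — including the degenerate `Δ = 0` with
negative mean, which the raw rule would leave unlabelled); otherwise the
state whose network gains the edge names it. Swapping A and B swaps the
specific labels and negates Δ (property-tested).

# Disease-gene binding enrichment

Per-gene binding score: peak intensities are log10(x+1)-transformed,
quantile normalized across replicates when more than one replicate column
exists, averaged, then distance-weighted and summed over peaks within
100 kb of the TSS; genes without a peak in range score 0.

Mann–Whitney variant: one-sided ("disease genes have more binding"),
mid-rank ties. The exact null distribution is used for tie-free data up to
n = 50; tied data is enumerated exhaustively when ≤ 2·10⁵ subsets exist,
otherwise (and always above n = 50) a normal approximation with
tie-corrected variance and continuity correction is used — full
enumeration at n = 50 (≈ 10¹⁴ subsets) is not computable, so the
enumeration bound is the honest implementable reading. The background is
*all* genes in the annotation, not only genes with nonzero scores.

Fisher variant: each peak maps to its single nearest TSS with no distance
cap (a cap flag exists); a gene is "mapped" if it receives ≥ 1 peak; the
2×2 table (disease vs rest) × (mapped vs not) is tested one-sided with the
hypergeometric tail; odds ratios use the Haldane 0.5 correction when a
cell is 0. FDR is computed per test type across the whole TF × list
family; significance at FDR < 0.1; the top 5 most-bound disease loci are
reported per test.

# Expression

DE uses the same NB Wald core (batch enters as an additive covariate via a
per-gene NB GLM when supplied); classes require padj ≤ 0.01 *and*
|log2FC| ≥ 0.58 (fold change 1.5 — the reading that reconciles a "log2 FC
> 1.5" figure caption with the stated 0.58 threshold). Shrunken fold
changes are *not* re-implemented; raw Wald log2FC is reported (documented
divergence). The variance-stabilizing transform is replaced by
`log2(count/sizefactor + 1)` for visualization (documented divergence).
Batch removal for visualization wraps `limma::removeBatchEffect` (the same
tool the original analysis used) behind an explicit full-rank check; it is
least-squares removal of the batch factor with the condition effect
protected, for plots only, never before testing.

Preranked GSEA: classic weighted Kolmogorov–Smirnov running sum with
weight exponent 1; ES is the extreme deviation (at an exact tie between
the positive and negative extremes the first-reached extreme is taken);
permutation p with the +1 rule over seeded random gene sets of the same
size (default 10,000 permutations in the pipeline; p is never 0).

# The synthetic world

The generator emulates the *statistical structure* the analysis assumes,
at desk scale, with every parameter in `sim_config()`:

* Genome: 2 × 50 Mb, 1000 genes — about one gene per 100 kb, the
  human-genome density, so 100 kb enhancer windows rarely span several
  genes. 5000 CREs, half gene-proximal and half uniform background
  (regulatory elements cluster near genes); catalogue density ≈ 5 CREs per
  gene.
* Counts: negative binomial, `Var = mu + alpha mu^2`, dispersion 0.1
  (typical bulk overdispersion), window-count scale 50, expression scale
  400 (bulk RNA-seq depth; at dispersion 0.1 the per-sample information
  saturates near mean 400, which is what makes the planted expression
  effects reliably detectable at n = 4).
* Differential CREs: exactly `round(frac · n_cres)` per mark (default
  30%), assigned deterministically by index before noise and split evenly
  A-high/B-high, with means `mu · 2^(±effect/2)` (effect 2.0 → 4-fold).
  Planted CREs are *closed* in REF (`ref_cre_effect_log2fc = 6`): a
  lineage-distant reference has no signal at epithelial CREs. REF carries
  its own planted program (REF-specific TFs with REF-active CREs) — a
  distant cell state is not an empty landscape, and without it the
  per-network min–max scaling inflates REF's weak edges and destabilizes
  every ΔB.
* Programs: 4 shared, 1 A-specific, 1 B-specific, 2 REF-specific TFs among
  30; 25 targets each, 4 planted CREs per (TF, target) within 50 kb of the
  target TSS (typical enhancers-per-gene count); motif hits at 80% in a
  TF's own planted CREs (motif presence in ChIP-validated bound regions)
  vs 1% background (strict-threshold PWM match rate).
* Expression: a cell-type-specific gene is up `effect/2` in its own state
  and down `effect/2` in *both* the sister state and REF (off is off), so
  the sister-vs-REF contrast for specific targets is null — this is what
  makes an A-specific master's REF→B influence collapse. Shared programs
  are up in A and B and down in REF at `shared_effect_log2fc = 1.8`,
  slightly below the specific effect 2.0: the master regulator of a state
  outranks the shared TFs in its own comparison while the shared TFs stay
  comfortably above the 0.5 influence rule. A two-level batch factor
  crossed with state adds `batch_effect_log2` on the log scale.
* Disease binding: the designated disease TF's peaks near disease-gene
  TSSs get placement probability *and* intensity multiplied by
  `disease_binding_effect` (default 4), so both the rank-based and the
  mapping-based test see signal; at effect 1 the process reduces exactly
  to the background, which is how the null-calibration tests are built.

What the generator does **not** emulate: read-level noise, GC/mappability
bias, peak-calling artefacts, correlated replicates, chromatin loops or
TAD structure, single-cell heterogeneity (pseudobulk only), and realistic
motif co-occurrence. A green recovery test therefore establishes that the
pipeline's logic recovers planted structure under its own model
assumptions — not that it is robust to every real-data pathology.

# Numerical choices and degenerate inputs

* All artifact writers emit `%.17g` doubles sorted in a deterministic
  order; identical config + seed reruns are byte-identical (tested).
* Config files are JSON (jsonlite): the pre-installed stack has no
  YAML/TOML parser, and JSON round-trips losslessly including the `NA`
  activity cutoff.
* `merge_top_peaks` with fewer than `top_n` peaks warns and takes all;
  empty input returns an empty catalogue with a warning.
* Zero-count features get log2FC 0 and p 1; a state with < 2 samples is an
  error (no dispersion estimate).
* `quantile_normalize` on a single column is the identity (with a warning
  in `normalize_signal`).
* Influence with no differentially up-regulated genes is all-zero with a
  warning; min–max scaling of a constant vector returns zeros.
* GSEA with an all-zero-weight member set falls back to equal hit weights.

# Known limitations

* The binding proxy is linear in motif presence and activity; it cannot
  capture TF-specific binding preferences beyond the motif matrix.
* The NB Wald p-values are approximate at very small n; calibration is
  verified at the simulated settings (n = 3–4, dispersion 0.1), not proven
  generally.
* Sensitivity at the strict DE thresholds (padj ≤ 0.01) requires planted
  fold changes ≳ 4 at n = 4 and dispersion 0.1; a 2-fold effect is below
  the information bound of any count test at that design (the per-sample
  Fisher information for a log-mean is capped at 1/dispersion), so the
  power tests plant effect 2.0 on the log2 scale.
* The Otsu activity cutoff assumes a bimodal pooled distribution; for
  unimodal data the absolute override should be used.
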