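---
title: "Methods: integrating binding sites with expression clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating binding sites with expression clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakgene)
```

This vignette documents the statistical procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults, and
what the synthetic-data generator does and does not emulate.

## The consolidation model

The package addresses one question in several coordinated pieces: given a
set of transcription-factor binding sites (ChIP-Seq peaks with summits) and
a table of differential-expression results across two contrasts, is binding
near transcription start sites overrepresented among the dysregulated
genes, and does the repressive histone mark the factor erases accumulate at
those sites when the factor is lost?

### Distance convention

All peak-to-gene distances are measured **summit to TSS** on the same
chromosome, unsigned for classification (`distance = |summit − tss|`) and
signed in gene orientation only for reporting (negative = upstream). The
summit is the anchor throughout — profiles, co-localization vectors and
proximity all use it — because the summit is the best single-base estimate
of the binding position, whereas peak edges depend on peak-caller width
heuristics. A site is *gene-proximal* when `distance ≤ 1000` bp
(inclusive; 1,000 is proximal, 1,001 is distal) and *gene-distal*
otherwise; the threshold is a parameter (`proximal_threshold`). Ties
between equidistant TSS break to the lexicographically smallest gene id so
results are independent of input order. Peaks on chromosomes without genes
are flagged unassigned rather than silently dropped or matched across
chromosomes.

### Expression thresholds and clusters

A gene is significant in a contrast when `|log2FC| ≥ log2(1.5)` and its
BH-adjusted p ≤ 0.01, both inclusive exactly as the thresholds are usually
printed. The expressed-gene filter retains genes with CPM ≥ 5 in ≥ 3
samples (CPM = counts × 10⁶ / column library size). Clusters are the six
up/down patterns across the pre-B and immature-B contrasts (I = up/up,
II = up/ns, III = ns/up, IV = down/down, V = down/ns, VI = ns/down). The
anchoring fact is that cluster V is the down-in-pre-B-only signature; the
numbering of the remaining patterns follows heatmap-ordering convention
(up-clusters first, within each block the both-contrasts pattern first,
then pre-B, then immature B). Genes up in one contrast and down in the
other fit none of the six patterns; they are counted, reported via an
attribute, and excluded — a design choice that keeps the six clusters a
partition of the concordantly significant genes.

### Enrichment against two nulls

For a cluster *C* of *n* genes and a window *w*, the statistic is the
fraction of *C* with at least one peak summit within *w* of the TSS
(`genes_with_site_within`, inclusive, monotone in *w* by construction).
Two nulls are constructed:

* **Random genes** — ten independent simple random samples of 300 genes
  from the full annotated universe, scored against the *real* peak set.
  The sampling frame is deliberately all annotated genes, not just
  expressed ones (an expressed-universe run is a one-argument change).
* **Random sites** — ten groups of uniform genomic locations (chromosome
  chosen proportional to length), materialized as intervals of the real
  peaks' median width, scored against the *cluster* genes.

Each comparison pools its ten groups into a single 2×2 table
(cluster with/without site vs pooled null with/without site) and applies a
two-sided Fisher exact test; per-group null fractions are attached for
transparency. Pooling uses all null draws and treats the two null types
symmetrically; with ten groups the pooled margin is large enough that the
test is effectively a comparison against the null proportion. The Fisher
p-value is the point-probability two-sided sum
`Σ {P(X) : P(X) ≤ P(observed)·(1 + 10⁻⁷)}` over the hypergeometric
support, capped at 1 — the same convention as `fisher.test`, which serves
as an independent cross-check in the test suite. Raw p-values are
reported (one test per cluster × window is the display unit); BH
adjustment is available via `bh_adjust` when a user wants it.

### Signal statistics

Coverage is stored in fixed 25 bp bins per chromosome with a library size,
and normalized by `10⁷ / libsize` — per 10 million reads, applied uniformly
to every track so wild-type and knockout are on one scale. Profile
matrices sample, for each column, the track bin containing the column
centre (nearest-bin rule); with matching bin sizes and bin-aligned anchors
this is exact, and at the default 25 bp resolution the approximation error
is below the bin quantization anyway. Columns outside the chromosome are
zero-padded and the anchor flagged, preserving matrix shape. Minus-strand
anchors are column-reversed so downstream is always rightward.
`region_intensity` is defined as the row mean of the profile matrix at the
track's own bin size, which makes it exactly consistent with profiles at
the same flank. The knockout-versus-wild-type comparison of per-site
± 2.5 kb mark intensities uses the Mann-Whitney U test with midrank tie
handling: exact for small untied samples (both n ≤ 20), otherwise the
normal approximation with continuity correction — the exact test is
quadratic in sample size and adds nothing at hundreds of sites.

### Co-localization

Per-site density vectors are means over ± 100 bp around summits; pairwise
Spearman ρ is Pearson correlation of midranks. A constant vector has no
rank variation, so its correlations are *defined* as 0 with a warning
rather than NaN, keeping the matrix total. Peak-set overlap uses ≥ 1 bp of
interval intersection; because overlap is many-to-many, both anchored
counts (A-hitting-B and B-hitting-A) are reported, and union merging keeps
the summit of the highest-scoring member of each merged run.

## The synthetic generator

The generator plants every feature the pipeline is supposed to detect, so
recovery is a falsifiable end-to-end check.

* **Genome and genes.** Equal-length chromosomes; TSS uniform; strand
  Bernoulli(½). The default configuration is mouse-scale — 20 × 125 Mb,
  24,421 genes, 13,163 peaks — so that proximity statistics live at the
  density where the method is used: at this density a uniform site has
  only ≈ 2% chance of landing within 1 kb of a TSS, which is why a planted
  proximal fraction of 0.74 is recovered as ≈ 0.745.
* **Peaks.** `proximal_fraction` of the sites get summits uniform within
  ± 1 kb of a TSS; the rest are uniform over the genome. The proximal
  sites are distributed gene-first over a background pool of
  `background_assoc_prob × n_genes` genes, each pool gene receiving at
  least one site (a sizing error otherwise). This gives the background
  association its exact gene-level meaning: a random gene is proximal with
  probability ≈ `background_assoc_prob`, which is what the enrichment
  null sees. Intervals are fixed 400 bp around the summit — profiles are
  summit-centered, so width only needs to contain the summit.
* **Coverage.** One inhomogeneous Poisson draw per bin: rate =
  `bg_rate` + Gaussian bump (sd 150 bp, a typical ChIP fragment-scale
  spread) of amplitude `bg_rate × (peak_fold − 1)` at each summit. The
  knockout histone-mark track multiplies the bump by `ko_mark_fold`
  (default 2 — a free simulation parameter chosen as a realistic
  mark-accumulation effect, since box-plot-level data fix no particular
  fold). Defaults `bg_rate = 2`, `peak_fold = 6` give site-level
  signal-to-noise at which 300 sites yield near-certain Mann-Whitney
  detection of a twofold mark change, with the fold-1 configuration
  identically distributed between genotypes for size calibration.
* **DE table.** Cluster genes are drawn from the proximal pool with their
  cluster's `association_prob` (per-gene Bernoulli), otherwise from the
  complement; planted significant entries get `|log2FC| ≥ log2(1.5)` and
  FDR ∈ (0, 0.01], null entries `|log2FC| < 0.585` and FDR ∈ [0.02, 1], so
  the threshold rules recover the planted labels *exactly* — adjusted
  p-values are planted, not fitted (no count-level dispersion model), and
  the defaults assign 916 genes across the six clusters with elevated
  association in the down-clusters (IV 0.4, V 0.6, VI 0.4 vs background
  0.2).
* **Determinism.** One master seed; each artifact derives a fixed child
  stream, so regenerating any single artifact reproduces it byte-for-byte
  and the caller's RNG state is never disturbed.

What the generator does **not** emulate: read-level data (no FASTQ,
fragment-length or mappability structure), replicate-level count
dispersion, peak-width variation, clustered gene families, or chromatin
domains. Passing tests therefore demonstrate that the statistics recover
planted structure at realistic densities — not that any particular
biological dataset will show such structure.

## Problem sizes

Three preset configurations fix the package's own study conditions:
`synthetic_config()` (mouse-scale, used for all coordinate-level
analyses — peak classification, clusters, enrichment), `signal_config()`
(2 × 2 Mb, 300 sites, used for all coverage-based analyses — full-genome
25 bp coverage vectors add memory, not information, to those statistics),
and `demo_config()` (3 × 5 Mb mid-scale, every stage in seconds). The
Fisher power/calibration runs use a sparse 4 × 50 Mb genome with 3,000
genes, a 20% proximal pool, one 300-gene cluster and 100 replicates per
condition: association 0.6 versus background 0.2 gives pooled-null Fisher
p below 10⁻⁶ essentially always, while the 0.2-versus-0.2 null
configuration rejects at the nominal rate.

## Numerical choices and degenerate inputs

* Fisher p capped at 1 after summation; the `1 + 10⁻⁷` relative slack
  absorbs floating-point ties in the hypergeometric mass.
* BH adjustment delegates to the standard step-up implementation and is
  property-tested against the explicit min-over-suffix definition.
* Parsers reject rather than clamp: out-of-bounds intervals, non-integer
  coordinates, overlapping bedGraph records and FDR outside [0, 1] all
  error with the offending line. Zero library size is an error at
  normalization time, not at track construction (an all-zero raw track is
  valid).
* Stable sorts everywhere ordering matters (distance ranking preserves
  input order on ties).
* An empty cluster, an empty annotation, and an all-zero 2×2 table are
  validation errors, not NaN propagation.

## Known limitations

Cross-chromosome nearest-TSS distance is undefined by design. The profile
nearest-bin sampling is approximate for anchors not aligned to the track
grid (sub-bin error). The enrichment test treats genes as exchangeable —
no correction for gene length, expression level or local gene density, as
the random-gene null inherits the universe's density structure only on
average. The Venn-style overlap counts depend on the ≥ 1 bp criterion; a
summit-distance criterion would give different shared counts for wide
peaks.
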