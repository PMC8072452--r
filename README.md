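# peakgene

Integration of transcription-factor ChIP-Seq binding sites with RNA-Seq
differential-expression clusters.

## The problem

A recurring question in regulatory genomics: are the genes that change
expression when a chromatin regulator is lost the same genes the regulator
physically binds? `peakgene` implements the consolidation analysis that
answers it for a factor/eraser such as a deubiquitinase acting on a
repressive histone mark (e.g. H2AK119ub) in B-cell precursors:

1. **Peak annotation.** Every binding site is assigned its nearest gene
   transcription start site (TSS); sites with the nearest TSS within 1 kb
   are *gene-proximal*, the rest *gene-distal*. Sites can be ranked by
   distance for heatmap-style displays.
2. **Expression clusters.** Genes significant at |FC| ≥ 1.5 and
   BH-adjusted p ≤ 0.01 in either of two contrasts (pre-B, immature B) are
   grouped into clusters I–VI by their up/down pattern: I = up in both,
   II = up in pre-B only, III = up in immature B only, IV = down in both,
   V = down in pre-B only, VI = down in immature B only.
3. **Enrichment.** For each cluster and TSS window *w*, the fraction of
   cluster genes with ≥ 1 peak summit within *w* of the TSS is compared
   against two nulls — ten random groups of 300 genes scored on the real
   peaks, and the cluster genes scored on ten random groups of genomic
   locations — with two-sided Fisher exact tests (point-probability
   method on the pooled null, `p = Σ {P(X) : P(X) ≤ P(obs)}` over the
   hypergeometric support).
4. **Signal.** Binned coverage tracks (scaled per 10 million reads) yield
   summit-centered average tag-density profiles, per-site ± 2.5 kb
   intensities, and a Mann-Whitney U comparison of knockout versus
   wild-type mark signal at binding sites.
5. **Co-localization.** Pairwise Spearman rank correlations of normalized
   densities ± 100 bp around summits across datasets, plus peak-set
   overlap/merge (Venn) counts.

Because the real sequencing data are not shipped, a seeded synthetic
generator plants all of this structure — a 74%-proximal peak set, Poisson
coverage with Gaussian summit enrichment, knockout mark elevation, and a
preferentially peak-proximal down-regulated cluster — so every stage is
validated against known ground truth.

## Worked example

```r
library(peakgene)
cfg   <- synthetic_config(seed = 1)        # 24,421 genes, 13,163 peaks
ann   <- generate_annotation(cfg)
peaks <- generate_peaks(cfg, ann)
a     <- classify_proximity(nearest_tss(peaks, ann), 1000)
proximity_counts(a)
#>   n_proximal     n_distal n_unassigned
#>         9804         3359            0
de  <- assign_clusters(generate_de_table(cfg, ann, peaks))
enr <- cluster_enrichment(de$gene_id[de$cluster == "V"], ann, peaks,
                          windows = 1000L, seed = 1001)
enr[, c("fraction", "null_gene_mean", "fisher_p_vs_random_genes")]
#>    fraction null_gene_mean fisher_p_vs_random_genes
#> 1 0.6433333          0.209             1.105771e-52
```

9,804 of 13,163 sites (74.5%) are gene-proximal — the planted 74% plus the
uniform background sites that happen to land near a TSS. Cluster V (down in
pre-B only, 300 genes) has a binding site within 1 kb of the TSS for 64% of
its genes versus 21% of random genes, and the Fisher test rejects the null
decisively.

The six numbered scripts under `analysis/` run the complete narrative
(simulate → annotate → cluster → profile → colocalize → enrich) and write
their tables under `results/`; `run_all(run_config(...))` does the same in
one call with a manifest.

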