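#!/usr/bin/env Rscript
# Stage 6 — the consolidation statistic: for every cluster and TSS window,
# the fraction of cluster genes with at least one binding site within the
# window, against ten random groups of 300 genes (scored on the real peaks)
# and ten random site groups (scored on the cluster genes), pooled into
# two-sided Fisher exact tests. The down-regulated clusters, V above all,
# should show the strongest overrepresentation.

suppressPackageStartupMessages(library(peakgene))

ann <- read_annotation("results/sim/annotation.tsv",
                       "results/sim/genome.chrom.sizes")
peaks <- read_peaks("results/sim/peaks.narrowPeak", ann$chrom_sizes)
de <- read_de_table("results/de_clusters.tsv")

report <- enrichment_report(de, ann, peaks,
                            windows = c(1000L, 2500L, 5000L, 10000L,
                                        25000L, 50000L, 100000L),
                            seed = 20260926)
utils::write.table(report, "results/enrichment_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

at1k <- report[report$window_bp == 1000L, ]
cat("fraction of genes with a site within 1 kb of the TSS:\n")
for (i in seq_len(nrow(at1k))) {
  cat(sprintf("  cluster %-3s %5.1f%%  (null genes %4.1f%%)  Fisher p = %.3g\n",
              at1k$cluster[i], 100 * at1k$fraction[i],
              100 * at1k$null_gene_mean[i],
              at1k$fisher_p_vs_random_genes[i]))
}
cat("wrote results/enrichment_report.tsv\n")
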