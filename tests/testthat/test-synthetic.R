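test_that("config validation rejects degenerate universes and bad proportions", {
  expect_error(synthetic_config(n_genes = 0), "n_genes")
  expect_error(synthetic_config(proximal_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(bg_rate = -1), "nonnegative")
  expect_error(synthetic_config(peak_fold = 0.5), ">= 1")
  expect_error(synthetic_config(n_genes = 100, cluster_sizes = c(V = 200)),
               "cluster sizes")
  # genes must fit the genome
  expect_error(synthetic_config(n_chroms = 1, chrom_length = 100,
                                n_genes = 1000, n_peaks = 10,
                                cluster_sizes = c()),
               "too small")
})

test_that("generation is deterministic given seed and config", {
  cfg <- demo_config(seed = 42)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  p1 <- generate_peaks(cfg, a1)
  p2 <- generate_peaks(cfg, a2)
  expect_identical(p1, p2)
  # byte-identical serialized form
  f1 <- tempfile(); f2 <- tempfile()
  write_peaks(p1, f1); write_peaks(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  d1 <- generate_de_table(cfg, a1, p1)
  d2 <- generate_de_table(cfg, a1, p1)
  expect_identical(d1, d2)
  t1 <- generate_coverage(cfg, p1, "WT", "factor")
  t2 <- generate_coverage(cfg, p1, "WT", "factor")
  expect_identical(t1, t2)
})

test_that("generated genes and peaks respect chromosome bounds", {
  cfg <- synthetic_config(seed = 3, n_chroms = 2, chrom_length = 1e6,
                          n_genes = 1000, n_peaks = 500,
                          cluster_sizes = c(V = 50))
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 1000)
  expect_true(all(ann$genes$tss >= 0))
  expect_true(all(ann$genes$tss < ann$chrom_sizes[ann$genes$chrom]))
  pk <- generate_peaks(cfg, ann)
  p <- pk$peaks
  expect_true(all(p$start >= 0 & p$end <= ann$chrom_sizes[p$chrom]))
  expect_true(all(p$start <= p$summit & p$summit < p$end))
})

test_that("planted proximal fraction is forced at 1.0 and recovered at 0.74", {
  # sparse genome: uniform background hits are negligible
  cfg1 <- synthetic_config(seed = 5, n_chroms = 2, chrom_length = 5e7,
                           n_genes = 200, n_peaks = 400,
                           proximal_fraction = 1,
                           background_assoc_prob = 0.5,
                           cluster_sizes = c())
  ann <- generate_annotation(cfg1)
  pk <- generate_peaks(cfg1, ann)
  a <- classify_proximity(nearest_tss(pk, ann), cfg1$proximal_threshold)
  expect_true(all(a$proximity == "proximal"))

  cfg2 <- synthetic_config(seed = 6, proximal_fraction = 0.74,
                           n_peaks = 13163, cluster_sizes = c())
  ann2 <- generate_annotation(cfg2)
  pk2 <- generate_peaks(cfg2, ann2)
  a2 <- classify_proximity(nearest_tss(pk2, ann2), 1000)
  f <- unname(proximity_counts(a2)["n_proximal"]) / n_peaks(pk2)
  sd3 <- 3 * sqrt(0.74 * 0.26 / 13163)
  expect_lt(abs(f - 0.74), sd3 + 0.26 * 0.025)  # slack for uniform-peak TSS hits
})

test_that("coverage background matches the Poisson rate and degenerates to zero", {
  cfg <- signal_config(seed = 9, peak_fold = 1)
  ann <- generate_annotation(cfg)
  pk <- generate_peaks(cfg, ann)
  tr <- generate_coverage(cfg, pk, "WT", "factor")
  v <- unlist(tr$values)
  se <- sqrt(cfg$bg_rate / length(v))
  expect_lt(abs(mean(v) - cfg$bg_rate), 3 * se)

  cfg0 <- signal_config(seed = 9, bg_rate = 0, peak_fold = 1)
  tr0 <- generate_coverage(cfg0, pk, "WT", "factor")
  expect_true(all(unlist(tr0$values) == 0))
})

test_that("knockout histone tracks carry the planted fold at factor sites", {
  cfg <- signal_config(seed = 13, ko_mark_fold = 2)
  ann <- generate_annotation(cfg)
  pk <- generate_peaks(cfg, ann)
  wt <- normalize_track(generate_coverage(cfg, pk, "WT", "histone_mark"))
  ko <- normalize_track(generate_coverage(cfg, pk, "KO", "histone_mark"))
  iwt <- region_intensity(wt, pk)
  iko <- region_intensity(ko, pk)
  # background-corrected site signal should double, within sampling noise
  bump_wt <- median(iwt) - cfg$bg_rate
  bump_ko <- median(iko) - cfg$bg_rate
  expect_gt(bump_wt, 0)
  expect_lt(abs(bump_ko / bump_wt - cfg$ko_mark_fold), 0.3)
})

test_that("DE table plants cluster patterns that the threshold rules recover", {
  cfg <- demo_config(seed = 21)
  ann <- generate_annotation(cfg)
  pk <- generate_peaks(cfg, ann)
  de <- generate_de_table(cfg, ann, pk)
  expect_equal(unname(table(de$cluster)[names(cfg$cluster_sizes)]),
               unname(cfg$cluster_sizes), ignore_attr = TRUE)
  # planted labels are exactly reproduced by the classification rules
  de2 <- assign_clusters(de)
  expect_identical(de2$cluster, de$cluster)
  # cluster magnitudes honour the significance contract
  sig <- de$cluster == "V"
  expect_true(all(abs(de$log2fc_preB[sig]) >= log2(1.5)))
  expect_true(all(de$fdr_preB[sig] <= 0.01))
  expect_true(all(de$fdr_immB[sig] > 0.01 | abs(de$log2fc_immB[sig]) < log2(1.5)))
})

test_that("empty cluster_sizes yields a DE table with no significant genes", {
  cfg <- demo_config(seed = 2, cluster_sizes = c())
  ann <- generate_annotation(cfg)
  pk <- generate_peaks(cfg, ann)
  de <- generate_de_table(cfg, ann, pk)
  expect_true(all(de$cluster == "none"))
  de2 <- assign_clusters(de)
  expect_true(all(de2$cluster == "none"))
})

test_that("oversized cluster demands raise a sizing error", {
  cfg <- synthetic_config(seed = 4, n_chroms = 1, chrom_length = 1e7,
                          n_genes = 100, n_peaks = 50, proximal_fraction = 1,
                          background_assoc_prob = 0.1,
                          cluster_sizes = c(V = 60),
                          association_prob = c(V = 1))
  ann <- generate_annotation(cfg)
  pk <- generate_peaks(cfg, ann)
  # needs ~60 proximal genes but the pool holds 10
  expect_error(generate_de_table(cfg, ann, pk), "exceed")
})
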