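test_that("summit density vectors equal region intensities at the half-width", {
  tr <- make_track(list(chr1 = rep(2.5, 400)), bin_size = 25L)
  pk <- make_peaks(c(3000L, 7000L))
  v <- summit_density_vector(tr, pk, half_width = 100L)
  expect_equal(unname(v), c(2.5, 2.5))
  expect_equal(v, region_intensity(tr, pk, flank = 100L))
})

test_that("pairwise Spearman reproduces hand-computed rho and handles constants", {
  v <- c(0.3, 1.2, 5, 2.2, 0.1)
  m <- pairwise_spearman(list(a = v, b = v))
  expect_equal(unname(m$rho["a", "b"]), 1)
  m2 <- pairwise_spearman(list(a = 1:5, b = 5:1))
  expect_equal(unname(m2$rho["a", "b"]), -1)
  m3 <- pairwise_spearman(list(a = c(1, 2, 3), b = c(3, 1, 2)))
  expect_equal(unname(m3$rho["a", "b"]), -0.5)  # 1 - 6*6 / (3*8)
  expect_warning(mc <- pairwise_spearman(list(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "constant")
  expect_equal(unname(mc$rho["a", "b"]), 0)
  expect_equal(diag(mc$rho), c(a = 1, b = 1))
  expect_error(pairwise_spearman(list(a = 1:4, b = 1:5)), "length")
})

test_that("Spearman matches the midrank-Pearson oracle on tied data", {
  set.seed(19)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    x <- sample(round(rexp(n), 1))   # heavy ties
    y <- x * sample(c(-1, 1), 1) + round(rnorm(n), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    m <- pairwise_spearman(list(x = x, y = y))
    expect_equal(unname(m$rho["x", "y"]), oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("co-enriched tracks correlate; independent tracks do not", {
  cfg <- signal_config(seed = 29)
  ann <- generate_annotation(cfg)
  pk <- generate_peaks(cfg, ann)
  t1 <- normalize_track(generate_coverage(cfg, pk, "WT", "factor"))
  t2 <- normalize_track(generate_coverage(cfg, pk, "WT", "histone_mark"))
  # same peak set, independent noise: strong positive rho
  v1 <- summit_density_vector(t1, pk)
  v2 <- summit_density_vector(t2, pk)
  rho_same <- pairwise_spearman(list(a = v1, b = v2))$rho["a", "b"]
  expect_gt(rho_same, 0.5)
  # a track built on an unrelated peak set decorrelates
  cfg3 <- signal_config(seed = 83)
  pk3 <- generate_peaks(cfg3, generate_annotation(cfg3))
  t3 <- normalize_track(generate_coverage(cfg3, pk3, "WT", "factor"))
  v3 <- summit_density_vector(t3, pk)
  rho_ind <- pairwise_spearman(list(a = v1, b = v3))$rho["a", "b"]
  expect_lt(abs(rho_ind), 0.15)
})

test_that("site-universe merging covers disjoint, identical, and nested sets", {
  a <- make_peaks(c(1000L, 5000L), score = c(1, 2))
  b <- make_peaks(c(20000L, 40000L), score = c(3, 4))
  u <- merge_site_universe(list(a, b), mode = "union")
  expect_equal(n_peaks(u), 4L)
  i <- merge_site_universe(list(a, b), mode = "intersection")
  expect_equal(n_peaks(i), 0L)

  u2 <- merge_site_universe(list(a, a), mode = "union")
  i2 <- merge_site_universe(list(a, a), mode = "intersection")
  expect_equal(n_peaks(u2), n_peaks(a))
  expect_equal(n_peaks(i2), n_peaks(a))
  expect_equal(u2$peaks$summit, a$peaks$summit)

  # overlapping intervals merge, keeping the strongest member's summit
  c1 <- make_peaks(c(1000L, 1300L), score = c(1, 9))
  m <- merge_site_universe(list(c1), mode = "union")
  expect_equal(n_peaks(m), 1L)
  expect_equal(m$peaks$summit, 1300L)
  expect_equal(m$peaks$start, 800L)
  expect_equal(m$peaks$end, 1500L)
})

test_that("overlap counts match a brute-force double loop on random sets", {
  overlaps <- function(p, q) p$start < q$end & q$start < p$end & p$chrom == q$chrom
  set.seed(37)
  for (rep in 1:25) {
    a <- make_peaks(sort(sample.int(95000, sample(5:40, 1))), width = 400L)
    b <- make_peaks(sort(sample.int(95000, sample(5:40, 1))), width = 400L)
    ov <- overlap_counts(a, b)
    brute_a <- vapply(seq_len(n_peaks(a)), function(i) {
      any(vapply(seq_len(n_peaks(b)), function(j) {
        overlaps(a$peaks[i, ], b$peaks[j, ])
      }, logical(1)))
    }, logical(1))
    expect_equal(ov$hit_a, brute_a)
    expect_equal(ov$shared_a, sum(brute_a))
    expect_equal(ov$a_only + ov$shared_a, n_peaks(a))
    expect_equal(ov$b_only + ov$shared_b, n_peaks(b))
  }
  # containment: every A peak inside some B peak
  a2 <- make_peaks(c(10000L, 30000L), width = 100L)
  b2 <- make_peaks(c(10000L, 30000L), width = 1000L)
  expect_equal(overlap_counts(a2, b2)$a_only, 0L)
  expect_equal(overlap_counts(a2, make_peaks(70000L))$shared_a, 0L)
})
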