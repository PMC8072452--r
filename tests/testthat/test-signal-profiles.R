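test_that("per-10-million normalization scales by 1e7 / libsize", {
  tr <- make_track(list(chr1 = c(3, 0, 6)), bin_size = 100L, libsize = 1e7)
  expect_equal(normalize_track(tr)$values$chr1, c(3, 0, 6))     # identity
  tr$libsize <- 5e6
  expect_equal(normalize_track(tr)$values$chr1, c(6, 0, 12))    # doubled
  tr$libsize <- 2e7
  expect_equal(normalize_track(tr)$values$chr1, c(1.5, 0, 3))
  tr$libsize <- 0
  expect_error(normalize_track(tr), "library size")
})

test_that("profile matrices are constant on constant tracks and validate flank", {
  tr <- make_track(list(chr1 = rep(4, 400)), bin_size = 25L)
  anchors <- data.frame(chrom = "chr1", pos = c(4000L, 6000L))
  pm <- profile_matrix(tr, anchors, flank = 500L, bin_size = 25L)
  expect_equal(dim(pm$matrix), c(2L, 40L))  # 2 * flank / bin_size columns
  expect_true(all(pm$matrix == 4))
  expect_false(any(pm$clipped))
  expect_error(profile_matrix(tr, anchors, flank = 510L, bin_size = 25L),
               "multiple")
})

test_that("out-of-range flanks are zero-padded and flagged", {
  tr <- make_track(list(chr1 = rep(2, 100)), bin_size = 25L)
  pm <- profile_matrix(tr, data.frame(chrom = "chr1", pos = 100L),
                       flank = 500L, bin_size = 25L)
  expect_true(pm$clipped[1])
  expect_true(all(pm$matrix[1, 1:16] == 0))   # bins left of the chromosome
  expect_true(all(pm$matrix[1, 17:40] == 2))
})

test_that("a planted Gaussian bump peaks within one bin of its summit", {
  cfg <- signal_config(seed = 17)
  ann <- generate_annotation(cfg)
  pk <- generate_peaks(cfg, ann)
  tr <- normalize_track(generate_coverage(cfg, pk, "WT", "factor"))
  ap <- average_profile(profile_matrix(tr, pk, flank = 2500L, bin_size = 25L))
  peak_bin <- ap$offset[which.max(ap$mean)]
  expect_lte(abs(peak_bin), 25)
  # unimodal decay: edges sit near background, centre well above
  expect_gt(max(ap$mean), 3 * mean(c(head(ap$mean, 5), tail(ap$mean, 5))))
})

test_that("minus-strand anchors flip the profile orientation", {
  v <- numeric(100); v[60] <- 10  # bump right of the anchor
  tr <- make_track(list(chr1 = v), bin_size = 25L)
  plus <- profile_matrix(tr, data.frame(chrom = "chr1", pos = 1250L, strand = "+"),
                         flank = 500L, bin_size = 25L)
  minus <- profile_matrix(tr, data.frame(chrom = "chr1", pos = 1250L, strand = "-"),
                          flank = 500L, bin_size = 25L)
  expect_equal(minus$matrix[1, ], rev(plus$matrix[1, ]))
})

test_that("average profiles reduce to column means with correct SE", {
  tr <- make_track(list(chr1 = 1:40), bin_size = 25L)
  one <- profile_matrix(tr, data.frame(chrom = "chr1", pos = 500L),
                        flank = 250L, bin_size = 25L)
  ap1 <- average_profile(one)
  expect_equal(ap1$mean, unname(one$matrix[1, ]))
  two <- profile_matrix(tr, data.frame(chrom = "chr1", pos = c(500L, 500L)),
                        flank = 250L, bin_size = 25L)
  expect_true(all(average_profile(two)$se == 0))
  set.seed(5)
  m <- matrix(runif(60), nrow = 6)
  pm <- structure(list(matrix = m, offsets = seq_len(10), flank = 125L,
                       bin_size = 25L, clipped = rep(FALSE, 6)),
                  class = "ProfileMatrix")
  expect_equal(average_profile(pm)$mean, colMeans(m))
  expect_equal(average_profile(pm)$se, apply(m, 2, sd) / sqrt(6))
})

test_that("region intensity is the profile row mean and is scale-equivariant", {
  tr <- make_track(list(chr1 = rep(7, 400)), bin_size = 25L)
  anchors <- data.frame(chrom = "chr1", pos = c(3000L, 5000L))
  ri <- region_intensity(tr, anchors, flank = 500L)
  expect_equal(unname(ri), c(7, 7))
  pm <- profile_matrix(tr, anchors, flank = 500L, bin_size = 25L)
  expect_equal(unname(ri), unname(rowMeans(pm$matrix)))
  tr2 <- tr; tr2$values$chr1 <- tr$values$chr1 * 3
  expect_equal(unname(region_intensity(tr2, anchors, flank = 500L)),
               unname(ri) * 3)
})

test_that("Mann-Whitney comparison matches enumeration on small samples", {
  same <- compare_intensities(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  sep <- compare_intensities(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(sep$U), 0)
  expect_equal(sep$p_value, 0.1)  # 2 / choose(6, 3) of 20 assignments
  set.seed(9)
  big <- compare_intensities(rnorm(200), rnorm(200, mean = 3))
  expect_lt(big$p_value, 1e-6)
  expect_error(compare_intensities(numeric(0), 1:3), "nonempty")
  # invariance under common monotone transforms
  a <- rexp(30); b <- rexp(40, rate = 0.5)
  expect_equal(compare_intensities(a, b)$p_value,
               compare_intensities(log(a), log(b))$p_value)
})
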