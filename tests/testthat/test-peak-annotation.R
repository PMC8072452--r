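test_that("nearest TSS picks the closer gene and reports oriented distance", {
  ann <- make_annotation(c(4000L, 7000L), strand = c("+", "-"))
  pk <- make_peaks(5000L)
  a <- nearest_tss(pk, ann)
  expect_equal(a$nearest_gene, "g001")
  expect_equal(a$distance, 1000L)
  expect_equal(a$signed_distance, 1000L)  # downstream of a + gene

  # minus-strand gene: summit beyond the TSS is upstream
  pk2 <- make_peaks(6500L)
  a2 <- nearest_tss(pk2, ann)
  expect_equal(a2$nearest_gene, "g002")
  expect_equal(a2$signed_distance, 500L)  # tss - summit for '-' strand
})

test_that("single-gene genomes assign every peak to that gene", {
  ann <- make_annotation(50000L)
  pk <- make_peaks(c(0L, 10000L, 99999L))
  a <- nearest_tss(pk, ann)
  expect_true(all(a$nearest_gene == "g001"))
  expect_equal(a$distance, abs(c(0L, 10000L, 99999L) - 50000L))
})

test_that("peaks on geneless chromosomes are flagged unassigned", {
  ann <- make_annotation(1000L)
  pk <- peak_set(data.frame(chrom = c("chr1", "chr2"), start = c(0L, 0L),
                            end = c(400L, 400L), name = c("p1", "p2"),
                            score = 1, summit = c(200L, 200L)))
  a <- nearest_tss(pk, ann)
  expect_false(is.na(a$nearest_gene[1]))
  expect_true(is.na(a$nearest_gene[2]))
  expect_equal(unname(proximity_counts(classify_proximity(a))["n_unassigned"]), 1L)
})

test_that("nearest-TSS ties break to the lexicographically smallest gene id", {
  ann <- make_annotation(c(4000L, 6000L))
  a <- nearest_tss(make_peaks(5000L), ann)  # equidistant
  expect_equal(a$nearest_gene, "g001")
  # duplicate TSS
  ann2 <- make_annotation(c(4000L, 4000L))
  a2 <- nearest_tss(make_peaks(4100L), ann2)
  expect_equal(a2$nearest_gene, "g001")
})

test_that("nearest-TSS assignment matches the exhaustive oracle", {
  set.seed(11)
  for (rep in 1:100) {
    n_g <- sample(3:50, 1)
    n_p <- sample(5:200, 1)
    tss <- sort(sample.int(1e5, n_g)) - 1L
    ann <- make_annotation(tss)
    summits <- sample.int(1e5, n_p) - 1L
    pk <- make_peaks(summits)
    a <- nearest_tss(pk, ann)
    oracle <- oracle_nearest(rep("chr1", n_p), summits, ann$genes)
    expect_identical(a$nearest_gene, oracle[, 1])
    expect_identical(a$distance, as.integer(oracle[, 2]))
  }
})

test_that("proximity classification is inclusive at the threshold", {
  ann <- make_annotation(10000L)
  pk <- make_peaks(c(11000L, 11001L))
  a <- classify_proximity(nearest_tss(pk, ann), 1000)
  expect_equal(a$proximity, c("proximal", "distal"))
  cnt <- proximity_counts(a)
  expect_equal(unname(cnt["n_proximal"] + cnt["n_distal"]), 2L)
  # threshold spanning the genome makes everything proximal
  a_all <- classify_proximity(nearest_tss(pk, ann), 1e5)
  expect_true(all(a_all$proximity == "proximal"))
})

test_that("distance ranking is a stable ascending sort", {
  ann <- make_annotation(10000L)
  pk <- make_peaks(c(15000L, 11000L, 9000L))  # distances 5000, 1000, 1000
  r <- rank_by_distance(nearest_tss(pk, ann))
  expect_equal(r$peak_id, c("p002", "p003", "p001"))  # ties keep input order
  expect_equal(rank_by_distance(r)$peak_id, r$peak_id)  # idempotent
  set.seed(3)
  for (rep in 1:20) {
    summits <- sample.int(1e5, 50) - 1L
    a <- nearest_tss(make_peaks(summits), ann)
    expect_equal(rank_by_distance(a)$distance, sort(a$distance))
  }
})

test_that("genes_with_site_within handles boundary windows and matches the oracle", {
  ann <- make_annotation(c(1000L, 5000L))
  pk <- make_peaks(c(1000L, 5200L))
  expect_equal(genes_with_site_within(ann, pk, 0), "g001")
  expect_setequal(genes_with_site_within(ann, pk, 1e5), c("g001", "g002"))
  set.seed(23)
  for (rep in 1:100) {
    n_g <- sample(3:40, 1)
    ann_r <- make_annotation(sort(sample.int(1e5, n_g)) - 1L)
    pk_r <- make_peaks(sample.int(1e5, sample(3:80, 1)) - 1L)
    w <- sample(c(0L, 100L, 1000L, 10000L), 1)
    expect_setequal(genes_with_site_within(ann_r, pk_r, w),
                    oracle_gwsw(ann_r$genes, pk_r$peaks, w))
  }
})

test_that("window monotonicity and proximal/nearest duality hold on random instances", {
  set.seed(41)
  for (rep in 1:20) {
    ann <- make_annotation(sort(sample.int(1e5, 20)) - 1L)
    pk <- make_peaks(sample.int(1e5, 40) - 1L)
    prev <- character(0)
    for (w in c(100L, 1000L, 5000L, 20000L)) {
      cur <- genes_with_site_within(ann, pk, w)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    # a proximal peak's nearest gene must appear in the same-window gene set
    a <- classify_proximity(nearest_tss(pk, ann), 1000)
    g1k <- genes_with_site_within(ann, pk, 1000)
    expect_true(all(a$nearest_gene[a$proximity == "proximal"] %in% g1k))
  }
})
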