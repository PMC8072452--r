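# brute-force oracles and tiny fixture builders shared across tests;
# every oracle is an independent direct computation, not a call into the
# code path it checks

# nearest gene by exhaustive scan; ties -> lexicographically smallest id
oracle_nearest <- function(chrom, summit, genes) {
  t(vapply(seq_along(summit), function(i) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (!nrow(g)) return(c(NA_character_, NA_character_))
    d <- abs(summit[i] - g$tss)
    cand <- g$gene_id[d == min(d)]
    c(sort(cand)[1], as.character(min(d)))
  }, character(2)))
}

# genes with >= 1 summit within window, by double loop
oracle_gwsw <- function(genes, peaks_df, window) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    any(peaks_df$chrom == genes$chrom[i] &
          abs(peaks_df$summit - genes$tss[i]) <= window)
  }, logical(1))
  genes$gene_id[hit]
}

# two-sided Fisher p by enumeration of the hypergeometric support using
# binomial coefficients directly
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  obs <- pr[xs == tab[1, 1]]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# BH by the explicit min-over-suffix definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# midranks by hand, then Pearson from raw sums
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# a CoverageTrack with given per-chromosome values
make_track <- function(values, bin_size = 25L, libsize = 1e7,
                       chrom_length = NULL) {
  if (is.null(chrom_length)) {
    chrom_length <- vapply(values, function(v) length(v) * bin_size, numeric(1))
  }
  coverage_track(values, bin_size = bin_size,
                 chrom_sizes = stats::setNames(chrom_length, names(values)),
                 libsize = libsize)
}

# a small annotation on one 100 kb chromosome
make_annotation <- function(tss, strand = NULL, chrom_length = 1e5) {
  n <- length(tss)
  genome_annotation(
    data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = "chr1",
               strand = strand %||% rep("+", n), tss = tss,
               stringsAsFactors = FALSE),
    c(chr1 = chrom_length))
}

# a peak set from summit positions on one chromosome
make_peaks <- function(summits, chrom = "chr1", width = 400L,
                       chrom_length = 1e5, score = NULL) {
  n <- length(summits)
  start <- pmax(summits - width %/% 2L, 0L)
  end <- pmin(summits + width %/% 2L, chrom_length)
  end <- pmax(end, summits + 1L)
  peak_set(data.frame(chrom = chrom, start = start, end = end,
                      name = sprintf("p%03d", seq_len(n)),
                      score = score %||% rep(1, n), summit = summits,
                      stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# config for Fisher power/calibration runs: sparse genome, every peak
# proximal, one 300-gene cluster over a 3000-gene universe with a 20%
# proximal background pool
calibration_config <- function(seed, assoc_v) {
  synthetic_config(seed = seed, n_chroms = 4L, chrom_length = 5e7,
                   n_genes = 3000L, n_peaks = 600L, proximal_fraction = 1,
                   background_assoc_prob = 0.2,
                   cluster_sizes = c(V = 300),
                   association_prob = c(V = assoc_v))
}
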