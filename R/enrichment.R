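# the consolidation statistic: per-cluster fraction of genes with a binding
# site within each TSS window, compared against random-gene and random-site
# null groups by two-sided Fisher exact tests

#' Random gene groups
#'
#' Simple random samples without replacement from the gene universe, drawn
#' independently per group — the random-gene null (default ten groups of
#' 300, mirroring sampling from the full annotated universe).
#'
#' @param universe character vector of gene ids.
#' @param n_groups number of groups (default 10).
#' @param group_size genes per group (default 300).
#' @param seed integer seed.
#' @return list of character vectors.
#' @export
random_gene_clusters <- function(universe, n_groups = 10L, group_size = 300L,
                                 seed = 1L) {
  assert_count(n_groups, "n_groups", min = 1L)
  assert_count(group_size, "group_size", min = 1L)
  if (length(universe) < group_size) {
    stop_fmt("universe (%d genes) smaller than group_size (%d)",
             length(universe), group_size)
  }
  with_seed(seed, lapply(seq_len(n_groups), function(i) {
    sample(universe, group_size)
  }))
}

#' Random binding-site groups
#'
#' Uniform genomic locations (chromosome chosen proportional to length,
#' position uniform within it), materialized as fixed-width intervals
#' clipped to chromosome bounds with the summit at the centre — the
#' random-site null (default ten groups of 10,000).
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param n_groups number of groups (default 10).
#' @param group_size sites per group (default 10000).
#' @param site_width interval width in bp (default 400).
#' @param seed integer seed.
#' @return list of [peak_set()] objects.
#' @export
random_binding_sites <- function(chrom_sizes, n_groups = 10L,
                                 group_size = 10000L, site_width = 400L,
                                 seed = 1L) {
  assert_count(n_groups, "n_groups", min = 1L)
  assert_count(group_size, "group_size", min = 1L)
  assert_count(site_width, "site_width", min = 2L)
  if (!length(chrom_sizes) || sum(as.numeric(chrom_sizes)) <= 0) {
    stop_fmt("genome length must be positive")
  }
  half <- site_width %/% 2L
  with_seed(seed, lapply(seq_len(n_groups), function(i) {
    chrom <- sample(names(chrom_sizes), group_size, replace = TRUE,
                    prob = as.numeric(chrom_sizes))
    summit <- as.integer(floor(stats::runif(group_size, 0, chrom_sizes[chrom])))
    start <- pmax(summit - half, 0L)
    end <- pmax(pmin(summit + half, chrom_sizes[chrom]), summit + 1L)
    peak_set(data.frame(chrom = chrom, start = start, end = end,
                        name = sprintf("r%02d_%05d", i, seq_len(group_size)),
                        score = 0, summit = summit, stringsAsFactors = FALSE),
             name = sprintf("random_sites_%02d", i), chrom_sizes = chrom_sizes)
  }))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Point-probability two-sided p: the sum of hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (up to a 1 + 1e-7 relative slack for floating
#' point).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop_fmt("`table` must be 2x2")
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop_fmt("table entries must be nonnegative integers")
  }
  if (sum(tab) == 0) stop_fmt("all-zero table")
  m <- sum(tab[1, ])          # row-1 margin
  n <- sum(tab[2, ])          # row-2 margin
  k <- sum(tab[, 1])          # column-1 margin
  x <- tab[1, 1]
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  d <- stats::dhyper(support, m, n, k)
  min(1, sum(d[d <= d[support == x] * (1 + 1e-7)]))
}

#' Per-cluster binding-site enrichment against two nulls
#'
#' For each TSS window `w`, counts the cluster genes with at least one peak
#' summit within `w` of their TSS and compares that fraction against (a)
#' random gene groups scored on the real peak set, and (b) the cluster genes
#' scored on random site groups, pooling the groups of each null into one
#' two-sided Fisher 2x2 test. Per-group null fractions are also reported.
#'
#' @param cluster_genes character vector of gene ids (subset of the
#'   universe).
#' @param annotation a [genome_annotation()] (defines the gene universe).
#' @param peaks the real [peak_set()].
#' @param windows ascending integer vector of TSS half-windows in bp.
#' @param n_null_groups,null_group_size random-gene null shape
#'   (default 10 x 300).
#' @param n_site_groups,site_group_size random-site null shape
#'   (default 10 x 10000).
#' @param site_width width of random sites; defaults to the median width of
#'   the real peaks.
#' @param seed integer seed for both nulls.
#' @return data.frame of class `EnrichmentReport` with one row per window:
#'   `window_bp`, `n_genes`, `n_with_site`, `fraction`, `null_gene_mean`,
#'   `null_site_mean`, `fisher_p_vs_random_genes`,
#'   `fisher_p_vs_random_sites`; per-group null fractions are attached as
#'   attributes `null_gene_fractions` and `null_site_fractions`
#'   (windows x groups matrices).
#' @export
cluster_enrichment <- function(cluster_genes, annotation, peaks, windows,
                               n_null_groups = 10L, null_group_size = 300L,
                               n_site_groups = 10L, site_group_size = 10000L,
                               site_width = NULL, seed = 1L) {
  stopifnot(inherits(annotation, "GenomeAnnotation"), inherits(peaks, "PeakSet"))
  if (!length(cluster_genes)) stop_fmt("empty cluster")
  universe <- annotation$genes$gene_id
  if (!all(cluster_genes %in% universe)) {
    stop_fmt("cluster genes absent from the annotation universe")
  }
  if (is.unsorted(windows)) stop_fmt("`windows` must be ascending")
  if (is.null(site_width)) {
    w <- peaks$peaks$end - peaks$peaks$start
    site_width <- if (length(w)) as.integer(stats::median(w)) else 400L
  }
  gene_nulls <- random_gene_clusters(universe, n_null_groups, null_group_size,
                                     seed = child_seed(seed, 31L))
  site_nulls <- random_binding_sites(annotation$chrom_sizes, n_site_groups,
                                     site_group_size, site_width,
                                     seed = child_seed(seed, 32L))
  n_c <- length(cluster_genes)
  ngf <- matrix(NA_real_, length(windows), n_null_groups)
  nsf <- matrix(NA_real_, length(windows), n_site_groups)
  out <- data.frame(window_bp = as.integer(windows),
                    n_genes = n_c, n_with_site = NA_integer_,
                    fraction = NA_real_, null_gene_mean = NA_real_,
                    null_site_mean = NA_real_,
                    fisher_p_vs_random_genes = NA_real_,
                    fisher_p_vs_random_sites = NA_real_)
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    with_site <- genes_with_site_within(annotation, peaks, w)
    n_with <- sum(cluster_genes %in% with_site)
    out$n_with_site[wi] <- n_with
    out$fraction[wi] <- n_with / n_c
    null_gene_hits <- vapply(gene_nulls, function(g) sum(g %in% with_site),
                             numeric(1))
    ngf[wi, ] <- null_gene_hits / null_group_size
    null_site_hits <- vapply(site_nulls, function(ps) {
      sum(cluster_genes %in% genes_with_site_within(annotation, ps, w))
    }, numeric(1))
    nsf[wi, ] <- null_site_hits / n_c
    pooled_g <- sum(null_gene_hits)
    tot_g <- n_null_groups * null_group_size
    out$null_gene_mean[wi] <- pooled_g / tot_g
    out$fisher_p_vs_random_genes[wi] <- fisher_exact(
      matrix(c(n_with, n_c - n_with, pooled_g, tot_g - pooled_g),
             nrow = 2, byrow = TRUE))
    pooled_s <- sum(null_site_hits)
    tot_s <- n_site_groups * n_c
    out$null_site_mean[wi] <- pooled_s / tot_s
    out$fisher_p_vs_random_sites[wi] <- fisher_exact(
      matrix(c(n_with, n_c - n_with, pooled_s, tot_s - pooled_s),
             nrow = 2, byrow = TRUE))
  }
  attr(out, "null_gene_fractions") <- ngf
  attr(out, "null_site_fractions") <- nsf
  class(out) <- c("EnrichmentReport", "data.frame")
  out
}

#' Enrichment report across all clusters of a DE table
#'
#' Runs [cluster_enrichment()] for every cluster label (I-VI) present in the
#' DE table and stacks the per-window rows.
#'
#' @param de DE data.frame with a `cluster` column.
#' @param annotation a [genome_annotation()].
#' @param peaks the real [peak_set()].
#' @param windows ascending TSS windows in bp (default 1, 2.5, 5, 10, 25,
#'   50, 100 kb).
#' @param ... passed to [cluster_enrichment()].
#' @return data.frame with a leading `cluster` column.
#' @export
enrichment_report <- function(de, annotation, peaks,
                              windows = c(1000L, 2500L, 5000L, 10000L,
                                          25000L, 50000L, 100000L), ...) {
  stopifnot("cluster" %in% names(de))
  labs <- intersect(.cluster_labels, unique(de$cluster))
  if (!length(labs)) stop_fmt("DE table contains no clustered genes")
  rows <- lapply(labs, function(lab) {
    rep_l <- cluster_enrichment(de$gene_id[de$cluster == lab],
                                annotation, peaks, windows, ...)
    cbind(cluster = lab, as.data.frame(rep_l))
  })
  do.call(rbind, rows)
}
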