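# cross-dataset co-localization: summit-centered density vectors, pairwise
# Spearman matrices, peak-set merging, and overlap (Venn) counts

#' Summit-centered density vector
#'
#' Mean normalized density over `[summit - half_width, summit + half_width)`
#' for every site — the per-site signal used for pairwise rank correlations
#' across datasets.
#'
#' @param track a [coverage_track()].
#' @param sites a [peak_set()] with summits.
#' @param half_width half-window in bp (default 100); must be a multiple of
#'   the track bin size.
#' @return named numeric vector, one value per site.
#' @export
summit_density_vector <- function(track, sites, half_width = 100L) {
  stopifnot(inherits(sites, "PeakSet"))
  region_intensity(track, sites, flank = half_width)
}

#' Pairwise Spearman correlation matrix
#'
#' Spearman rho via Pearson correlation of midranks, over a common site
#' universe. A constant vector has no rank variation; its correlations are
#' defined as 0 with a warning so the matrix stays total.
#'
#' @param vectors named list of equal-length numeric vectors (length >= 3).
#' @return an object of class `ColocMatrix`: symmetric matrix of rho with
#'   unit diagonal.
#' @export
pairwise_spearman <- function(vectors) {
  if (!is.list(vectors) || length(vectors) < 2L || is.null(names(vectors))) {
    stop_fmt("`vectors` must be a named list of at least two vectors")
  }
  n <- unique(lengths(vectors))
  if (length(n) != 1L) stop_fmt("vectors differ in length (%s)",
                                paste(n, collapse = ", "))
  if (n < 3L) stop_fmt("need at least 3 sites for rank correlation")
  labs <- names(vectors)
  const <- vapply(vectors, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) {
    warning(sprintf("constant density vector(s) %s: correlations set to 0",
                    paste(labs[const], collapse = ", ")))
  }
  ranks <- lapply(vectors, rank)  # midranks for ties
  k <- length(vectors)
  rho <- diag(1, k)
  dimnames(rho) <- list(labs, labs)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- if (const[i] || const[j]) 0 else stats::cor(ranks[[i]], ranks[[j]])
      rho[i, j] <- rho[j, i] <- r
    }
  }
  structure(list(rho = rho, n_sites = n), class = "ColocMatrix")
}

#' @export
print.ColocMatrix <- function(x, ...) {
  cat(sprintf("ColocMatrix over %d sites:\n", x$n_sites))
  print(round(x$rho, 3))
  invisible(x)
}

.peaks_to_iranges <- function(p) {
  # IRanges is 1-based closed; shift half-open starts by +1
  IRanges::IRanges(start = p$start + 1L, end = p$end)
}

#' Merge peak sets into a common site universe
#'
#' Union mode merges intervals overlapping by >= 1 bp across all sets; each
#' merged site keeps the summit of its highest-scoring member. Intersection
#' mode keeps the first set's peaks that overlap >= 1 bp with a peak in
#' every other set.
#'
#' @param peak_sets list of [peak_set()] objects.
#' @param mode `"union"` or `"intersection"`.
#' @return a [peak_set()].
#' @export
merge_site_universe <- function(peak_sets, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!length(peak_sets) || !all(vapply(peak_sets, inherits, logical(1), "PeakSet"))) {
    stop_fmt("`peak_sets` must be a nonempty list of PeakSet objects")
  }
  if (mode == "intersection") {
    keep <- rep(TRUE, nrow(peak_sets[[1]]$peaks))
    if (length(peak_sets) > 1) {
      for (other in peak_sets[-1]) {
        ov <- overlap_counts(peak_sets[[1]], other)
        keep <- keep & ov$hit_a
      }
    }
    return(peak_set(peak_sets[[1]]$peaks[keep, , drop = FALSE],
                    name = "intersection"))
  }
  all_p <- do.call(rbind, lapply(peak_sets, function(x) {
    x$peaks[, c("chrom", "start", "end", "name", "score", "summit")]
  }))
  merged <- list()
  for (ch in unique(all_p$chrom)) {
    p <- all_p[all_p$chrom == ch, , drop = FALSE]
    red <- IRanges::reduce(.peaks_to_iranges(p), with.revmap = TRUE)
    rev <- S4Vectors::mcols(red)$revmap
    best <- vapply(seq_along(red), function(i) {
      members <- rev[[i]]
      members[which.max(p$score[members])]
    }, integer(1))
    merged[[ch]] <- data.frame(chrom = ch,
                               start = IRanges::start(red) - 1L,
                               end = IRanges::end(red),
                               name = p$name[best],
                               score = p$score[best],
                               summit = p$summit[best],
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("m%05d", seq_len(nrow(out)))
  peak_set(out, name = "union")
}

#' Overlap counts between two peak sets
#'
#' Overlap is >= 1 bp of interval intersection. Because overlap is not a
#' bijection, both anchored counts are reported: `shared_a` (A peaks hitting
#' any B peak) and `shared_b` (B peaks hitting any A peak).
#'
#' @param set_a,set_b [peak_set()] objects.
#' @return list with `a_only`, `shared_a`, `shared_b`, `b_only`, and logical
#'   per-peak hit vectors `hit_a`, `hit_b`.
#' @export
overlap_counts <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "PeakSet"), inherits(set_b, "PeakSet"))
  pa <- set_a$peaks
  pb <- set_b$peaks
  hit_a <- logical(nrow(pa))
  hit_b <- logical(nrow(pb))
  for (ch in intersect(unique(pa$chrom), unique(pb$chrom))) {
    ia <- which(pa$chrom == ch)
    ib <- which(pb$chrom == ch)
    ra <- .peaks_to_iranges(pa[ia, , drop = FALSE])
    rb <- .peaks_to_iranges(pb[ib, , drop = FALSE])
    hit_a[ia] <- IRanges::countOverlaps(ra, rb) > 0
    hit_b[ib] <- IRanges::countOverlaps(rb, ra) > 0
  }
  list(a_only = sum(!hit_a), shared_a = sum(hit_a),
       shared_b = sum(hit_b), b_only = sum(!hit_b),
       hit_a = hit_a, hit_b = hit_b)
}
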