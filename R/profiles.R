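# anchor-centered signal: per-10-million normalization, profile matrices,
# region intensities, and the Mann-Whitney knockout-vs-wild-type comparison

#' Scale a track per 10 million reads
#'
#' Multiplies all values by `1e7 / libsize`, the normalization convention
#' applied uniformly to every track so wild-type and knockout libraries are
#' comparable.
#'
#' @param track a [coverage_track()].
#' @return the normalized track (`normalized = TRUE`; libsize retained).
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (track$libsize <= 0) stop_fmt("library size must be > 0 to normalize")
  f <- 1e7 / track$libsize
  track$values <- lapply(track$values, function(v) v * f)
  track$normalized <- TRUE
  track
}

.as_anchor_frame <- function(anchors) {
  if (inherits(anchors, "PeakSet")) {
    anchors <- data.frame(chrom = anchors$peaks$chrom,
                          pos = anchors$peaks$summit,
                          name = anchors$peaks$name,
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(anchors), all(c("chrom", "pos") %in% names(anchors)))
  if (is.null(anchors$strand)) anchors$strand <- "+"
  if (is.null(anchors$name)) anchors$name <- sprintf("a%05d", seq_len(nrow(anchors)))
  anchors
}

#' Anchor-centered profile matrix
#'
#' Row `a`, column `j` holds the track density over
#' `[pos - flank + (j-1) * bin_size, pos - flank + j * bin_size)`, read from
#' the track bin containing the column centre. Minus-strand anchors are
#' reversed so downstream of the anchor is always rightward. Columns falling
#' outside the chromosome are zero-padded and the anchor flagged.
#'
#' @param track a [coverage_track()] (normalize first for comparable scales).
#' @param anchors a `PeakSet` (summits are used) or data.frame with `chrom`,
#'   `pos` and optional `strand`, `name`.
#' @param flank half-window in bp; must be a multiple of `bin_size`.
#' @param bin_size profile bin width in bp.
#' @return an object of class `ProfileMatrix`: list with `matrix`
#'   (anchors x bins), `offsets` (bin-centre offsets from the anchor),
#'   `flank`, `bin_size`, and logical `clipped` per anchor.
#' @export
profile_matrix <- function(track, anchors, flank = 2500L, bin_size = 25L) {
  stopifnot(inherits(track, "CoverageTrack"))
  assert_count(flank, "flank", min = 1L)
  assert_count(bin_size, "bin_size", min = 1L)
  if (flank %% bin_size != 0) {
    stop_fmt("`flank` (%d) must be a multiple of `bin_size` (%d)",
             flank, bin_size)
  }
  anchors <- .as_anchor_frame(anchors)
  if (!all(anchors$chrom %in% names(track$chrom_sizes))) {
    stop_fmt("anchor chromosome absent from track")
  }
  n_bins <- as.integer(2 * flank / bin_size)
  centers <- -flank + (seq_len(n_bins) - 0.5) * bin_size
  mat <- matrix(0, nrow = nrow(anchors), ncol = n_bins)
  clipped <- logical(nrow(anchors))
  tb <- track$bin_size
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    v <- track$values[[ch]]
    pos_c <- anchors$pos[i] + centers
    idx <- floor(pos_c / tb) + 1L
    ok <- idx >= 1L & idx <= length(v) & pos_c >= 0 &
      pos_c < track$chrom_sizes[[ch]]
    row <- numeric(n_bins)
    row[ok] <- v[idx[ok]]
    if (!all(ok)) clipped[i] <- TRUE
    if (anchors$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  rownames(mat) <- anchors$name
  structure(list(matrix = mat, offsets = centers, flank = as.integer(flank),
                 bin_size = as.integer(bin_size), clipped = clipped),
            class = "ProfileMatrix")
}

#' Average profile across anchors
#'
#' @param pm a [profile_matrix()].
#' @return data.frame with `offset` (bin centre relative to the anchor),
#'   `mean`, and `se` (sd / sqrt(n)) per bin.
#' @export
average_profile <- function(pm) {
  stopifnot(inherits(pm, "ProfileMatrix"))
  m <- pm$matrix
  if (!nrow(m)) stop_fmt("profile matrix has no anchors")
  data.frame(offset = pm$offsets,
             mean = colMeans(m),
             se = apply(m, 2, stats::sd) / sqrt(nrow(m)))
}

#' Mean signal intensity around each anchor
#'
#' Mean track density over `[pos - flank, pos + flank)` per anchor, defined
#' as the row mean of [profile_matrix()] at the track's own bin size — the
#' per-site statistic compared between genotypes in the Mann-Whitney test.
#'
#' @inheritParams profile_matrix
#' @return named numeric vector, one value per anchor.
#' @export
region_intensity <- function(track, anchors, flank = 2500L) {
  pm <- profile_matrix(track, anchors, flank = flank,
                       bin_size = track$bin_size)
  stats::setNames(rowMeans(pm$matrix), rownames(pm$matrix))
}

#' Mann-Whitney comparison of two intensity groups
#'
#' Rank-sum U statistic with midrank tie handling; two-sided p-value, exact
#' for small untied samples (both n <= 20), otherwise a normal approximation
#' with continuity correction.
#'
#' @param group_a,group_b numeric vectors (e.g. knockout vs wild-type
#'   per-site intensities).
#' @return list with `U` (statistic for `group_a`), `p_value`, and `method`.
#' @export
compare_intensities <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop_fmt("both groups must be nonempty")
  }
  exact <- length(group_a) <= 20 && length(group_b) <= 20 &&
    !anyDuplicated(c(group_a, group_b))
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value, method = wt$method)
}
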