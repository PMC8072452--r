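# lightweight S3 containers shared across the pipeline; coordinates are
# 0-based half-open throughout, converted only at parse/serialize boundaries

#' Construct a genome annotation
#'
#' A gene universe with one transcription start site (TSS) per gene plus a
#' chromosome-size table; the reference frame for all peak-to-gene distance
#' computations.
#'
#' @param genes data.frame with columns `gene_id` (unique character),
#'   `chrom`, `strand` (`"+"`/`"-"`), `tss` (0-based bp).
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @return an object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    stop_fmt("`genes` must be a data.frame with columns %s",
             paste(need, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop_fmt("gene_id values must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop_fmt("strand must be '+' or '-'")
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop_fmt("`chrom_sizes` must be a named vector of positive lengths")
  }
  if (!all(genes$chrom %in% names(chrom_sizes))) {
    stop_fmt("gene chromosome absent from chrom_sizes")
  }
  bad <- genes$tss < 0 | genes$tss >= chrom_sizes[genes$chrom]
  if (any(bad)) {
    stop_fmt("TSS out of chromosome bounds for gene %s",
             genes$gene_id[which(bad)[1]])
  }
  genes <- genes[, need]
  genes$tss <- as.integer(genes$tss)
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 chrom_sizes = stats::setNames(as.integer(chrom_sizes),
                                               names(chrom_sizes))),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d genes on %d chromosome(s) (%s bp)\n",
              nrow(x$genes), length(x$chrom_sizes),
              format(sum(as.numeric(x$chrom_sizes)), big.mark = ",")))
  invisible(x)
}

#' Construct a peak set
#'
#' A named collection of genomic intervals with summits and scores, the unit
#' of ChIP-Seq binding evidence. Summits are absolute coordinates and must
#' fall inside their interval.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `summit` (absolute bp). `strand` optional.
#' @param name label for the set.
#' @param chrom_sizes optional named vector; when given, intervals are
#'   validated against chromosome bounds.
#' @return an object of class `PeakSet`.
#' @export
peak_set <- function(peaks, name = "peaks", chrom_sizes = NULL) {
  need <- c("chrom", "start", "end", "name", "score", "summit")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks))) {
    stop_fmt("`peaks` must be a data.frame with columns %s",
             paste(need, collapse = ", "))
  }
  if (nrow(peaks)) {
    if (any(peaks$start < 0 | peaks$end <= peaks$start)) {
      stop_fmt("peak intervals must satisfy 0 <= start < end")
    }
    if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end)) {
      stop_fmt("peak summit must satisfy start <= summit < end")
    }
    if (!is.null(chrom_sizes)) {
      if (!all(peaks$chrom %in% names(chrom_sizes))) {
        stop_fmt("peak chromosome absent from chrom_sizes")
      }
      bad <- peaks$end > chrom_sizes[peaks$chrom]
      if (any(bad)) {
        stop_fmt("peak '%s' extends beyond its chromosome",
                 peaks$name[which(bad)[1]])
      }
    }
  }
  peaks <- peaks[, c(need, intersect("strand", names(peaks)))]
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  peaks$summit <- as.integer(peaks$summit)
  rownames(peaks) <- NULL
  structure(list(name = name, peaks = peaks), class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d interval(s)\n", x$name, nrow(x$peaks)))
  invisible(x)
}

#' Number of peaks in a PeakSet
#' @param x a `PeakSet`.
#' @return integer count.
#' @export
n_peaks <- function(x) {
  stopifnot(inherits(x, "PeakSet"))
  nrow(x$peaks)
}

#' Construct a binned coverage track
#'
#' Per-chromosome signal in fixed-width bins plus the library size used for
#' per-10-million normalization. Bin `i` covers
#' `[(i-1) * bin_size, i * bin_size)`.
#'
#' @param values named list of nonnegative numeric vectors, one per
#'   chromosome, of length `ceiling(chrom_length / bin_size)`.
#' @param bin_size bin width in bp.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param libsize total reads in the library the track represents.
#' @param name track label.
#' @param normalized logical; whether per-10-million scaling was applied.
#' @return an object of class `CoverageTrack`.
#' @export
coverage_track <- function(values, bin_size, chrom_sizes, libsize,
                           name = "track", normalized = FALSE) {
  assert_count(bin_size, "bin_size", min = 1L)
  if (!is.list(values) || is.null(names(values))) {
    stop_fmt("`values` must be a named list of per-chromosome vectors")
  }
  if (!setequal(names(values), names(chrom_sizes))) {
    stop_fmt("chromosomes of `values` and `chrom_sizes` must match")
  }
  for (ch in names(values)) {
    nb <- ceiling(chrom_sizes[[ch]] / bin_size)
    if (length(values[[ch]]) != nb) {
      stop_fmt("chromosome '%s': expected %d bins, got %d",
               ch, nb, length(values[[ch]]))
    }
    if (any(values[[ch]] < 0)) stop_fmt("coverage values must be nonnegative")
  }
  if (!is.numeric(libsize) || length(libsize) != 1L || libsize < 0) {
    stop_fmt("`libsize` must be a single nonnegative number")
  }
  structure(list(name = name, bin_size = as.integer(bin_size),
                 values = values[names(chrom_sizes)],
                 chrom_sizes = stats::setNames(as.integer(chrom_sizes),
                                               names(chrom_sizes)),
                 libsize = libsize, normalized = normalized),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack '%s': %d chromosome(s), bin %d bp, libsize %s%s\n",
              x$name, length(x$values), x$bin_size,
              format(x$libsize, big.mark = ","),
              if (x$normalized) " (normalized per 1e7 reads)" else ""))
  invisible(x)
}
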