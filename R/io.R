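# readers/writers for the standard plain-text formats the pipeline touches:
# BED/narrowPeak, bedGraph, chrom.sizes, annotation and DE TSV tables.
# Internal coordinates are 0-based half-open (BED-native); parsers reject
# out-of-bounds records rather than clamping them.

#' Read a chromosome-sizes table
#'
#' Two whitespace-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @return named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  if (any(tab$size <= 0 | tab$size != floor(tab$size))) {
    stop_fmt("%s: chromosome sizes must be positive integers", path)
  }
  stats::setNames(as.integer(tab$size), tab$chrom)
}

#' Write a chromosome-sizes table
#' @param chrom_sizes named integer vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes), as.integer(chrom_sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation (TSS table plus chromosome sizes)
#'
#' The TSS table is a TSV with header `gene_id, chrom, strand, tss`.
#'
#' @param path TSS TSV path.
#' @param chrom_sizes_path chrom.sizes path.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(path, chrom_sizes_path) {
  genes <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  genome_annotation(genes, read_chrom_sizes(chrom_sizes_path))
}

#' Write a gene annotation
#' @param annotation a [genome_annotation()].
#' @param path TSS TSV output path.
#' @param chrom_sizes_path chrom.sizes output path.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(annotation, path, chrom_sizes_path) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  utils::write.table(annotation$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_chrom_sizes(annotation$chrom_sizes, chrom_sizes_path)
  invisible(path)
}

#' Read peaks from BED or narrowPeak
#'
#' Accepts 3-10 column BED dialects. With 10 columns (narrowPeak) the summit
#' is `start + column-10 offset`; when the offset is `-1`, and for plain BED,
#' the summit falls back to the interval midpoint (floor). Scores are taken
#' from the narrowPeak signalValue column when present, else BED column 5.
#' Out-of-bounds intervals and non-integer coordinates are rejected with the
#' offending line number.
#'
#' @param path file path.
#' @param chrom_sizes named integer vector for bounds validation.
#' @param name label for the resulting set.
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, chrom_sizes, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    return(peak_set(data.frame(chrom = character(0), start = integer(0),
                               end = integer(0), name = character(0),
                               score = numeric(0), summit = integer(0)),
                    name = name, chrom_sizes = chrom_sizes))
  }
  fields <- strsplit(lines, "[ \t]+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L) stop_fmt("%s: ragged rows (columns %s)",
                                   path, paste(ncol, collapse = ","))
  if (ncol < 3L) stop_fmt("%s: need at least 3 BED columns", path)
  get <- function(i) vapply(fields, `[[`, "", i)
  int_col <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    bad <- is.na(v) | v != floor(v)
    if (any(bad)) stop_fmt("%s line %d: non-integer %s '%s'",
                           path, which(bad)[1], what, get(i)[which(bad)[1]])
    as.integer(v)
  }
  chrom <- get(1)
  start <- int_col(2, "start")
  end <- int_col(3, "end")
  nm <- if (ncol >= 4L) get(4) else sprintf("peak%d", seq_along(chrom))
  score <- if (ncol >= 7L) {
    v <- suppressWarnings(as.numeric(get(7)))
    if (any(is.na(v))) stop_fmt("%s: non-numeric signalValue column", path)
    v
  } else if (ncol >= 5L) {
    suppressWarnings(as.numeric(get(5)))
  } else rep(0, length(chrom))
  score[is.na(score)] <- 0
  if (ncol >= 10L) {
    off <- int_col(10, "summit offset")
    summit <- ifelse(off >= 0L, start + off, (start + end) %/% 2L)
  } else {
    summit <- (start + end) %/% 2L
  }
  unknown <- !(chrom %in% names(chrom_sizes))
  if (any(unknown)) stop_fmt("%s line %d: unknown chromosome '%s'",
                             path, which(unknown)[1], chrom[which(unknown)[1]])
  bad <- start < 0 | end <= start | end > chrom_sizes[chrom]
  if (any(bad)) stop_fmt("%s line %d: interval %d-%d out of bounds for %s",
                         path, which(bad)[1], start[which(bad)[1]],
                         end[which(bad)[1]], chrom[which(bad)[1]])
  bad_s <- summit < start | summit >= end
  if (any(bad_s)) stop_fmt("%s line %d: summit outside interval",
                          path, which(bad_s)[1])
  peak_set(data.frame(chrom = chrom, start = start, end = end, name = nm,
                      score = score, summit = as.integer(summit),
                      stringsAsFactors = FALSE),
           name = name, chrom_sizes = chrom_sizes)
}

#' Write peaks as 10-column narrowPeak
#'
#' Columns 1-6 are BED (score column 5 written as 0, strand `.`), column 7
#' carries the score (signalValue), columns 8-9 are `-1`, and column 10 is
#' the summit offset from the interval start.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  p <- peaks$peaks
  df <- data.frame(p$chrom, p$start, p$end, p$name, 0L, ".",
                   format(p$score, trim = TRUE, digits = 10, scientific = FALSE),
                   -1L, -1L, p$summit - p$start)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file into a binned track
#'
#' Records are length-weight averaged into fixed-width bins; uncovered bases
#' count as zero. Overlapping records on a chromosome are a format error. A
#' `# libsize=N` comment line (written by [write_coverage()]) is honoured
#' unless `libsize` is supplied.
#'
#' @param path bedGraph path.
#' @param chrom_sizes named integer vector.
#' @param bin_size bin width in bp (default 25).
#' @param libsize library size override.
#' @param name track label.
#' @return a [coverage_track()].
#' @export
read_coverage <- function(path, chrom_sizes, bin_size = 25L, libsize = NULL,
                          name = basename(path)) {
  assert_count(bin_size, "bin_size", min = 1L)
  lines <- readLines(path)
  ls_line <- grep("^#\\s*libsize=", lines, value = TRUE)
  if (is.null(libsize)) {
    libsize <- if (length(ls_line)) {
      as.numeric(sub("^#\\s*libsize=", "", ls_line[1]))
    } else 0
  }
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  vals <- lapply(chrom_sizes, function(len) numeric(ceiling(len / bin_size)))
  if (length(lines)) {
    fields <- strsplit(lines, "[ \t]+")
    if (any(lengths(fields) < 4L)) stop_fmt("%s: bedGraph needs 4 columns", path)
    chrom <- vapply(fields, `[[`, "", 1)
    start <- as.numeric(vapply(fields, `[[`, "", 2))
    end <- as.numeric(vapply(fields, `[[`, "", 3))
    value <- as.numeric(vapply(fields, `[[`, "", 4))
    if (any(is.na(start) | is.na(end) | is.na(value))) {
      stop_fmt("%s: non-numeric bedGraph fields", path)
    }
    unknown <- !(chrom %in% names(chrom_sizes))
    if (any(unknown)) stop_fmt("%s line %d: unknown chromosome '%s'",
                               path, which(unknown)[1], chrom[which(unknown)[1]])
    if (any(start < 0 | end <= start | end > chrom_sizes[chrom])) {
      stop_fmt("%s: interval out of chromosome bounds", path)
    }
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      o <- order(start[sel])
      s <- start[sel][o]; e <- end[sel][o]; v <- value[sel][o]
      if (any(s[-1] < e[-length(e)])) {
        stop_fmt("%s: overlapping bedGraph records on %s", path, ch)
      }
      len <- chrom_sizes[[ch]]
      acc <- vals[[ch]]
      for (i in seq_along(s)) {
        b0 <- floor(s[i] / bin_size); b1 <- floor((e[i] - 1) / bin_size)
        for (b in b0:b1) {
          lo <- max(s[i], b * bin_size)
          hi <- min(e[i], (b + 1) * bin_size)
          width <- min(bin_size, len - b * bin_size)
          acc[b + 1L] <- acc[b + 1L] + v[i] * (hi - lo) / width
        }
      }
      vals[[ch]] <- acc
    }
  }
  coverage_track(vals, bin_size = bin_size, chrom_sizes = chrom_sizes,
                 libsize = libsize, name = name)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bins are merged into one record; zero bins are
#' omitted (uncovered). The library size is recorded as a `# libsize=`
#' comment so the track round-trips.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_coverage <- function(track, path) {
  stopifnot(inherits(track, "CoverageTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# libsize=%s",
                     format(track$libsize, scientific = FALSE, trim = TRUE)),
             con)
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    s <- starts_bin[keep] * bs
    e <- pmin(ends_bin[keep] * bs, track$chrom_sizes[[ch]])
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, s, e,
                       format(r$values[keep], digits = 12, trim = TRUE,
                              scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with header `gene_id, log2fc_preB, fdr_preB, log2fc_immB, fdr_immB`
#' and an optional `cluster` column.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  de <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc_preB", "fdr_preB", "log2fc_immB", "fdr_immB")
  if (!all(need %in% names(de))) {
    stop_fmt("%s: missing DE columns %s", path,
             paste(setdiff(need, names(de)), collapse = ", "))
  }
  for (cc in c("fdr_preB", "fdr_immB")) {
    if (any(de[[cc]] < 0 | de[[cc]] > 1)) {
      stop_fmt("%s: %s outside [0, 1]", path, cc)
    }
  }
  de
}

#' Write a differential-expression table
#' @param de data.frame as returned by [generate_de_table()] or
#'   [assign_clusters()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
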