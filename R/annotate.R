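# peak-to-TSS annotation: nearest gene, proximal/distal classification,
# distance ranking, and the gene-side "has a site within w of the TSS" query

#' Assign each peak its nearest TSS
#'
#' For every peak the gene minimizing `|summit - tss|` on the same
#' chromosome is reported; ties are broken by the lexicographically smallest
#' gene id. Peaks on chromosomes without genes are flagged unassigned
#' (`NA` nearest gene and distance).
#'
#' The signed distance is reported in gene orientation: negative means the
#' summit lies upstream of the TSS.
#'
#' @param peaks a [peak_set()].
#' @param annotation a [genome_annotation()].
#' @return data.frame with columns `peak_id`, `chrom`, `summit`,
#'   `nearest_gene`, `distance`, `signed_distance`.
#' @export
nearest_tss <- function(peaks, annotation) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(annotation, "GenomeAnnotation"))
  genes <- annotation$genes
  if (!nrow(genes)) stop_fmt("annotation contains no genes")
  pk <- peaks$peaks
  out <- data.frame(peak_id = pk$name, chrom = pk$chrom, summit = pk$summit,
                    nearest_gene = NA_character_, distance = NA_integer_,
                    signed_distance = NA_integer_, stringsAsFactors = FALSE)
  for (ch in unique(pk$chrom)) {
    gi <- genes[genes$chrom == ch, , drop = FALSE]
    rows <- which(pk$chrom == ch)
    if (!nrow(gi)) next
    ord <- order(gi$tss, gi$gene_id)
    gi <- gi[ord, , drop = FALSE]
    tss <- gi$tss
    s <- pk$summit[rows]
    j <- findInterval(s, tss)
    for (i in seq_along(rows)) {
      dl <- if (j[i] >= 1L) s[i] - tss[j[i]] else Inf
      dr <- if (j[i] < length(tss)) tss[j[i] + 1L] - s[i] else Inf
      d <- min(dl, dr)
      # all genes at the minimal distance (duplicate TSS or symmetric tie)
      cand <- which(tss == s[i] - d | tss == s[i] + d)
      gsel <- cand[order(gi$gene_id[cand])[1L]]
      r <- rows[i]
      out$nearest_gene[r] <- gi$gene_id[gsel]
      out$distance[r] <- as.integer(d)
      out$signed_distance[r] <- if (gi$strand[gsel] == "+") {
        as.integer(s[i] - tss[gsel])
      } else {
        as.integer(tss[gsel] - s[i])
      }
    }
  }
  out
}

#' Classify peaks as gene-proximal or gene-distal
#'
#' A peak is proximal when its nearest-TSS distance is at most
#' `proximal_threshold` (inclusive, so distance 1000 is proximal at the
#' default 1 kb and 1001 is distal). Unassigned peaks keep `NA`.
#'
#' @param annotated output of [nearest_tss()].
#' @param proximal_threshold distance threshold in bp.
#' @return `annotated` with an added `proximity` column
#'   (`"proximal"`/`"distal"`/`NA`).
#' @export
classify_proximity <- function(annotated, proximal_threshold = 1000L) {
  assert_count(proximal_threshold, "proximal_threshold")
  stopifnot(is.data.frame(annotated), "distance" %in% names(annotated))
  annotated$proximity <- ifelse(is.na(annotated$distance), NA_character_,
                                ifelse(annotated$distance <= proximal_threshold,
                                       "proximal", "distal"))
  annotated
}

#' Proximal/distal partition counts
#'
#' @param annotated output of [classify_proximity()].
#' @return named integer vector `c(n_proximal, n_distal, n_unassigned)`;
#'   proximal + distal equals the number of assigned peaks.
#' @export
proximity_counts <- function(annotated) {
  stopifnot(is.data.frame(annotated), "proximity" %in% names(annotated))
  c(n_proximal = sum(annotated$proximity == "proximal", na.rm = TRUE),
    n_distal = sum(annotated$proximity == "distal", na.rm = TRUE),
    n_unassigned = sum(is.na(annotated$proximity)))
}

#' Rank peaks by nearest-TSS distance
#'
#' Stable ascending sort by distance (ties keep input order); unassigned
#' peaks sort last.
#'
#' @param annotated output of [nearest_tss()].
#' @return `annotated` reordered.
#' @export
rank_by_distance <- function(annotated) {
  stopifnot(is.data.frame(annotated), "distance" %in% names(annotated))
  annotated[order(annotated$distance, na.last = TRUE), , drop = FALSE]
}

#' Genes with at least one binding site near their TSS
#'
#' A gene qualifies when at least one peak summit lies within `window` bp of
#' its TSS (inclusive on both sides).
#'
#' @param annotation a [genome_annotation()].
#' @param peaks a [peak_set()].
#' @param window half-width in bp (>= 0).
#' @return character vector of qualifying gene ids.
#' @export
genes_with_site_within <- function(annotation, peaks, window) {
  stopifnot(inherits(annotation, "GenomeAnnotation"), inherits(peaks, "PeakSet"))
  assert_count(window, "window")
  genes <- annotation$genes
  pk <- peaks$peaks
  hit <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gsel <- which(genes$chrom == ch)
    summits <- sort(pk$summit[pk$chrom == ch])
    if (!length(summits)) next
    tss <- genes$tss[gsel]
    n_in <- findInterval(tss + window, summits) -
      findInterval(tss - window - 1, summits)
    hit[gsel] <- n_in > 0
  }
  genes$gene_id[hit]
}
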