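# expression-side preparation: CPM, the expressed-gene filter, BH
# adjustment, significance calls at |FC| >= 1.5 & FDR <= 0.01, and the
# Cluster I-VI pattern assignment across the pre-B and immature-B contrasts

#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] * 1e6 / libsize[s]` with library size the
#' column sum.
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @return numeric matrix of the same shape.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_fmt("counts must be nonnegative")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop_fmt("zero library size in sample(s) %s",
                              paste(which(lib <= 0), collapse = ", "))
  sweep(counts, 2, lib, "/") * 1e6
}

#' Expressed-gene filter
#'
#' A gene is retained when its CPM is at least `min_cpm` in at least
#' `min_samples` samples (both thresholds inclusive).
#'
#' @param counts genes x samples count matrix with gene rownames.
#' @param min_cpm CPM threshold (default 5).
#' @param min_samples sample-count threshold (default 3).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, min_cpm = 5, min_samples = 3L) {
  if (min_cpm < 0 || min_samples < 0) stop_fmt("thresholds must be >= 0")
  x <- cpm(counts)
  keep <- rowSums(x >= min_cpm) >= min_samples
  rownames(counts)[keep] %||% which(keep)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, order-preserving.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop_fmt("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Significance call for one contrast
#'
#' `up` when `log2fc >= log2(fc_threshold)` and `fdr <= fdr_threshold`;
#' `down` for the mirrored fold change; otherwise `ns`. Boundaries are
#' inclusive.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param fdr numeric vector of adjusted p-values.
#' @param fc_threshold linear fold-change threshold (> 1, default 1.5).
#' @param fdr_threshold adjusted-p threshold (default 0.01).
#' @return character vector in `{"up", "down", "ns"}`.
#' @export
classify_significant <- function(log2fc, fdr, fc_threshold = 1.5,
                                 fdr_threshold = 0.01) {
  if (fc_threshold <= 1) stop_fmt("`fc_threshold` must be > 1")
  lmin <- log2(fc_threshold)
  ifelse(fdr <= fdr_threshold & log2fc >= lmin, "up",
         ifelse(fdr <= fdr_threshold & log2fc <= -lmin, "down", "ns"))
}

#' Assign expression-pattern clusters I-VI
#'
#' Clusters follow the up/down pattern across the two contrasts:
#' I = up in both, II = up in pre-B only, III = up in immature B only,
#' IV = down in both, V = down in pre-B only, VI = down in immature B only.
#' Genes significant in neither contrast, or up in one and down in the
#' other (discordant), receive `"none"`; the discordant count is reported
#' via a message.
#'
#' @param de DE data.frame with `log2fc_preB`, `fdr_preB`, `log2fc_immB`,
#'   `fdr_immB` columns.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param fdr_threshold adjusted-p threshold (default 0.01).
#' @return `de` with its `cluster` column (re)computed.
#' @export
assign_clusters <- function(de, fc_threshold = 1.5, fdr_threshold = 0.01) {
  need <- c("log2fc_preB", "fdr_preB", "log2fc_immB", "fdr_immB")
  if (!all(need %in% names(de))) {
    stop_fmt("DE table lacks columns %s",
             paste(setdiff(need, names(de)), collapse = ", "))
  }
  a <- classify_significant(de$log2fc_preB, de$fdr_preB,
                            fc_threshold, fdr_threshold)
  b <- classify_significant(de$log2fc_immB, de$fdr_immB,
                            fc_threshold, fdr_threshold)
  key <- paste(a, b, sep = ".")
  map <- c(up.up = "I", up.ns = "II", ns.up = "III",
           down.down = "IV", down.ns = "V", ns.down = "VI")
  de$cluster <- unname(ifelse(key %in% names(map), map[key], "none"))
  n_disc <- sum((a == "up" & b == "down") | (a == "down" & b == "up"))
  if (n_disc > 0) {
    message(sprintf("%d discordant gene(s) (up in one contrast, down in the other) left unclustered",
                    n_disc))
  }
  attr(de, "n_discordant") <- n_disc
  de
}
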