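# seeded synthetic-data generator with planted structure: a mostly
# TSS-proximal peak set, Poisson-background coverage with Gaussian summit
# enrichment, elevated repressive-mark signal at binding sites in knockout
# tracks, and a DE table whose down-in-pre-B cluster is preferentially
# peak-proximal

.cluster_labels <- c("I", "II", "III", "IV", "V", "VI")

# expression pattern per cluster: (pre-B class, immature-B class)
.cluster_patterns <- list(
  I   = c("up",   "up"),
  II  = c("up",   "ns"),
  III = c("ns",   "up"),
  IV  = c("down", "down"),
  V   = c("down", "ns"),
  VI  = c("ns",   "down")
)

#' Configuration for the synthetic-data generator
#'
#' Parameterizes a genome with planted peak-to-TSS proximity, cluster-level
#' peak association, and coverage signal structure. Identical seed and
#' configuration reproduce byte-identical artifacts.
#'
#' Defaults describe a mouse-scale universe: 24,421 genes and 13,163
#' binding sites of which 74% are placed within 1 kb of a TSS, matching the
#' proportions the downstream classification is designed to recover.
#'
#' @param seed master seed; per-artifact child streams are derived from it.
#' @param n_chroms number of chromosomes (equal length).
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes in the universe.
#' @param n_peaks number of binding sites.
#' @param proximal_fraction fraction of peaks whose summit is planted within
#'   `proximal_threshold` of a TSS.
#' @param proximal_threshold proximity threshold in bp (default 1000).
#' @param cluster_sizes named integer vector over cluster labels I-VI.
#' @param association_prob named vector: probability that a gene of that
#'   cluster is drawn from the peak-proximal pool; missing labels fall back
#'   to `background_assoc_prob`.
#' @param background_assoc_prob fraction of the gene universe given a
#'   proximal binding site (the null association level).
#' @param bg_rate Poisson background reads per bin.
#' @param peak_fold enrichment fold at summits (>= 1); the Gaussian bump
#'   amplitude is `bg_rate * (peak_fold - 1)`.
#' @param ko_mark_fold multiplier on the repressive-mark bump in knockout
#'   tracks (>= 1).
#' @param bin_size coverage bin width in bp.
#' @param libsize nominal library size recorded on generated tracks.
#' @param peak_width fixed peak interval width in bp.
#' @param enrich_sd standard deviation of the Gaussian summit bump in bp.
#' @return an object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 20L,
                             chrom_length = 125e6,
                             n_genes = 24421L,
                             n_peaks = 13163L,
                             proximal_fraction = 0.74,
                             proximal_threshold = 1000L,
                             cluster_sizes = c(I = 150, II = 120, III = 100,
                                               IV = 150, V = 300, VI = 96),
                             association_prob = c(I = 0.2, II = 0.2, III = 0.2,
                                                  IV = 0.4, V = 0.6, VI = 0.4),
                             background_assoc_prob = 0.2,
                             bg_rate = 2,
                             peak_fold = 6,
                             ko_mark_fold = 2,
                             bin_size = 25L,
                             libsize = 1e7,
                             peak_width = 400L,
                             enrich_sd = 150) {
  assert_count(seed, "seed")
  assert_count(n_chroms, "n_chroms", min = 1L)
  assert_count(chrom_length, "chrom_length", min = 1L)
  assert_count(n_genes, "n_genes", min = 1L)
  assert_count(n_peaks, "n_peaks", min = 0L)
  assert_proportion(proximal_fraction, "proximal_fraction")
  assert_count(proximal_threshold, "proximal_threshold")
  assert_proportion(background_assoc_prob, "background_assoc_prob")
  assert_scalar_number(bg_rate, "bg_rate")
  if (bg_rate < 0) stop_fmt("`bg_rate` must be nonnegative")
  assert_scalar_number(peak_fold, "peak_fold")
  if (peak_fold < 1) stop_fmt("`peak_fold` must be >= 1")
  assert_scalar_number(ko_mark_fold, "ko_mark_fold")
  if (ko_mark_fold < 1) stop_fmt("`ko_mark_fold` must be >= 1")
  assert_count(bin_size, "bin_size", min = 1L)
  assert_count(libsize, "libsize", min = 1L)
  assert_count(peak_width, "peak_width", min = 2L)
  assert_scalar_number(enrich_sd, "enrich_sd")
  if (length(cluster_sizes)) {
    if (is.null(names(cluster_sizes)) ||
        !all(names(cluster_sizes) %in% .cluster_labels)) {
      stop_fmt("cluster_sizes must be named with labels among %s",
               paste(.cluster_labels, collapse = ", "))
    }
    if (any(cluster_sizes < 0) || any(cluster_sizes != floor(cluster_sizes))) {
      stop_fmt("cluster sizes must be nonnegative integers")
    }
    if (sum(cluster_sizes) > n_genes) {
      stop_fmt("cluster sizes sum to %d but only %d genes exist",
               sum(cluster_sizes), n_genes)
    }
  }
  if (length(association_prob)) assert_proportion(association_prob, "association_prob")
  # gene placement must leave room: require >= 10 bp of genome per gene
  if (as.numeric(n_chroms) * chrom_length < 10 * n_genes) {
    stop_fmt("genome too small for %d genes (need >= 10 bp per gene)", n_genes)
  }
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
                 proximal_fraction = proximal_fraction,
                 proximal_threshold = as.integer(proximal_threshold),
                 cluster_sizes = cluster_sizes,
                 association_prob = association_prob,
                 background_assoc_prob = background_assoc_prob,
                 bg_rate = bg_rate, peak_fold = peak_fold,
                 ko_mark_fold = ko_mark_fold, bin_size = as.integer(bin_size),
                 libsize = libsize, peak_width = as.integer(peak_width),
                 enrich_sd = enrich_sd),
            class = "SyntheticConfig")
}

#' Signal-scale preset configuration
#'
#' A compact genome (2 chromosomes of 2 Mb, 300 sites) sized for
#' coverage-based analyses: metaprofiles, region intensities, and the
#' knockout-versus-wild-type Mann-Whitney comparison at 300 sites.
#'
#' @param seed master seed.
#' @param ... overrides passed to [synthetic_config()].
#' @return a `SyntheticConfig`.
#' @export
signal_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chroms = 2L, chrom_length = 2e6, n_genes = 400L,
               n_peaks = 300L, proximal_fraction = 1, background_assoc_prob = 0.5,
               cluster_sizes = c(V = 50),
               association_prob = c(V = 0.6))
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

#' Demo-scale preset configuration
#'
#' A mid-sized genome (3 chromosomes of 5 Mb, 1,500 genes, 1,200 peaks) that
#' exercises every pipeline stage, including coverage tracks, in seconds.
#'
#' @param seed master seed.
#' @param ... overrides passed to [synthetic_config()].
#' @return a `SyntheticConfig`.
#' @export
demo_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chroms = 3L, chrom_length = 5e6, n_genes = 1500L,
               n_peaks = 1200L,
               cluster_sizes = c(I = 40, II = 30, III = 30, IV = 40, V = 80, VI = 30))
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

#' Generate a gene annotation
#'
#' Places `n_genes` TSS uniformly over the genome with random strand, and
#' emits the chromosome-size table. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return a [genome_annotation()].
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms), chroms)
  genes <- with_seed(child_seed(config$seed, 1L), {
    chrom <- sample(chroms, config$n_genes, replace = TRUE)
    tss <- floor(stats::runif(config$n_genes, 0, config$chrom_length))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    data.frame(gene_id = sprintf("g%05d", seq_len(config$n_genes)),
               chrom = chrom, strand = strand, tss = as.integer(tss),
               stringsAsFactors = FALSE)
  })
  genes <- genes[order(genes$chrom, genes$tss, genes$gene_id), ]
  genome_annotation(genes, sizes)
}

#' Generate a peak set with planted TSS proximity
#'
#' A fraction `proximal_fraction` of the peaks receive summits within
#' `proximal_threshold` bp of a TSS; the remainder are uniform over the
#' genome. Proximal summits are distributed over a background pool of
#' `round(background_assoc_prob * n_genes)` genes so that each pool gene
#' carries at least one proximal site — the pool defines the null
#' association level downstream enrichment is tested against.
#'
#' @param config a [synthetic_config()].
#' @param annotation a [genome_annotation()] produced under the same config.
#' @return a [peak_set()] of `n_peaks` fixed-width intervals.
#' @export
generate_peaks <- function(config, annotation) {
  stopifnot(inherits(config, "SyntheticConfig"),
            inherits(annotation, "GenomeAnnotation"))
  genes <- annotation$genes
  if (!nrow(genes)) stop_fmt("annotation contains no genes")
  sizes <- annotation$chrom_sizes
  n <- config$n_peaks
  k <- round(config$proximal_fraction * n)
  pool_size <- round(config$background_assoc_prob * nrow(genes))
  if (k > 0 && pool_size == 0) {
    stop_fmt("background_assoc_prob yields an empty proximal gene pool")
  }
  if (k < pool_size) {
    stop_fmt(paste0("only %d proximal peaks for a background pool of %d genes; ",
                    "raise n_peaks or proximal_fraction, or lower ",
                    "background_assoc_prob"), k, pool_size)
  }
  thr <- config$proximal_threshold
  half <- config$peak_width %/% 2L
  with_seed(child_seed(config$seed, 2L), {
    if (k > 0) {
      pool <- sample(seq_len(nrow(genes)), pool_size)
      # every pool gene gets floor(k / pool_size) summits; leftovers spread
      base <- rep(pool, k %/% pool_size)
      extra <- if (k %% pool_size > 0) sample(pool, k %% pool_size) else integer(0)
      gidx <- c(base, extra)
      offs <- sample.int(2L * thr + 1L, k, replace = TRUE) - thr - 1L
      prox_chrom <- genes$chrom[gidx]
      prox_summit <- pmin(pmax(genes$tss[gidx] + offs, 0L),
                          sizes[prox_chrom] - 1L)
    } else {
      prox_chrom <- character(0); prox_summit <- integer(0)
    }
    m <- n - k
    if (m > 0) {
      bg_chrom <- sample(names(sizes), m, replace = TRUE,
                         prob = as.numeric(sizes))
      bg_summit <- floor(stats::runif(m, 0, sizes[bg_chrom]))
    } else {
      bg_chrom <- character(0); bg_summit <- integer(0)
    }
    chrom <- c(prox_chrom, bg_chrom)
    summit <- as.integer(c(prox_summit, bg_summit))
    perm <- sample.int(n)
    chrom <- chrom[perm]; summit <- summit[perm]
    start <- pmax(summit - half, 0L)
    end <- pmin(summit + half, sizes[chrom])
    end <- pmax(end, summit + 1L)
    score <- round(stats::runif(n, 5, 500), 2)
    peak_set(data.frame(chrom = chrom, start = start, end = end,
                        name = sprintf("p%05d", seq_len(n)),
                        score = score, summit = summit,
                        stringsAsFactors = FALSE),
             name = "synthetic", chrom_sizes = sizes)
  })
}

#' Generate a binned coverage track
#'
#' Per-bin counts are drawn from a Poisson distribution whose rate is the
#' background `bg_rate` plus a Gaussian bump (sd `enrich_sd`) of amplitude
#' `bg_rate * (peak_fold - 1)` centered at each factor summit. For the
#' knockout repressive-mark track the bump amplitude is multiplied by
#' `ko_mark_fold`, emulating mark accumulation at binding sites when the
#' eraser is lost. The configured nominal library size is recorded.
#'
#' @param config a [synthetic_config()].
#' @param peaks the factor [peak_set()] whose summits seed the enrichment.
#' @param condition `"WT"` or `"KO"`.
#' @param mark `"factor"` (the TF itself) or `"histone_mark"` (the
#'   repressive mark).
#' @return a [coverage_track()] of raw counts.
#' @export
generate_coverage <- function(config, peaks,
                              condition = c("WT", "KO"),
                              mark = c("factor", "histone_mark")) {
  stopifnot(inherits(config, "SyntheticConfig"), inherits(peaks, "PeakSet"))
  condition <- match.arg(condition)
  mark <- match.arg(mark)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms), chroms)
  if (nrow(peaks$peaks) && !all(peaks$peaks$chrom %in% chroms)) {
    stop_fmt("peaks lie on chromosomes absent from the configured genome")
  }
  amp <- config$bg_rate * (config$peak_fold - 1)
  if (mark == "histone_mark" && condition == "KO") amp <- amp * config$ko_mark_fold
  bs <- config$bin_size
  sd2 <- 2 * config$enrich_sd^2
  reach <- ceiling(4 * config$enrich_sd / bs)  # bump support: +/- 4 sd
  offs <- c(11L, 12L, 13L, 14L)
  names(offs) <- c("WT.factor", "WT.histone_mark", "KO.factor", "KO.histone_mark")
  vals <- with_seed(child_seed(config$seed, offs[[paste(condition, mark, sep = ".")]]), {
    out <- vector("list", length(chroms))
    names(out) <- chroms
    for (ch in chroms) {
      nb <- as.integer(ceiling(sizes[[ch]] / bs))
      rate <- rep(config$bg_rate, nb)
      if (amp > 0) {
        for (s in peaks$peaks$summit[peaks$peaks$chrom == ch]) {
          ctr <- floor(s / bs) + 1L
          idx <- max(1L, ctr - reach):min(nb, ctr + reach)
          d <- (idx - 0.5) * bs - s
          rate[idx] <- rate[idx] + amp * exp(-d^2 / sd2)
        }
      }
      out[[ch]] <- as.numeric(stats::rpois(nb, rate))
    }
    out
  })
  coverage_track(vals, bin_size = bs, chrom_sizes = sizes,
                 libsize = config$libsize,
                 name = paste(mark, condition, sep = "_"))
}

#' Generate a differential-expression table with planted clusters
#'
#' Each cluster gene receives log2 fold changes matching its cluster pattern
#' (magnitude at least log2(1.5)) and an adjusted p at most 0.01 in the
#' significant contrasts; all other entries are null (small fold change,
#' adjusted p above threshold). Genes in clusters with association
#' probability above background are preferentially drawn from the
#' peak-proximal gene pool.
#'
#' @param config a [synthetic_config()].
#' @param annotation a [genome_annotation()].
#' @param peaks the [peak_set()] defining gene proximity.
#' @return data.frame with columns `gene_id`, `log2fc_preB`, `fdr_preB`,
#'   `log2fc_immB`, `fdr_immB`, `cluster` (planted label, `"none"` for
#'   unassigned genes).
#' @export
generate_de_table <- function(config, annotation, peaks) {
  stopifnot(inherits(config, "SyntheticConfig"),
            inherits(annotation, "GenomeAnnotation"),
            inherits(peaks, "PeakSet"))
  ids <- annotation$genes$gene_id
  prox <- genes_with_site_within(annotation, peaks, config$proximal_threshold)
  de <- data.frame(gene_id = ids,
                   log2fc_preB = 0, fdr_preB = 1,
                   log2fc_immB = 0, fdr_immB = 1,
                   cluster = "none", stringsAsFactors = FALSE)
  rownames(de) <- ids
  lfc_min <- log2(1.5)
  with_seed(child_seed(config$seed, 21L), {
    avail_p <- intersect(ids, prox)
    avail_d <- setdiff(ids, prox)
    for (lab in names(config$cluster_sizes)) {
      sz <- config$cluster_sizes[[lab]]
      if (sz == 0) next
      a <- config$association_prob[lab]
      if (is.na(a)) a <- config$background_assoc_prob
      n_p <- stats::rbinom(1L, sz, a)
      if (n_p > length(avail_p) || (sz - n_p) > length(avail_d)) {
        stop_fmt("cluster %s: requested %d genes (%d proximal) exceed the available pools",
                 lab, sz, n_p)
      }
      g <- c(if (n_p > 0) sample(avail_p, n_p) else character(0),
             if (sz - n_p > 0) sample(avail_d, sz - n_p) else character(0))
      avail_p <- setdiff(avail_p, g)
      avail_d <- setdiff(avail_d, g)
      pat <- .cluster_patterns[[lab]]
      for (ci in 1:2) {
        fc_col <- c("log2fc_preB", "log2fc_immB")[ci]
        p_col <- c("fdr_preB", "fdr_immB")[ci]
        cls <- pat[ci]
        if (cls == "ns") {
          de[g, fc_col] <- stats::runif(length(g), -0.55, 0.55)
          de[g, p_col] <- stats::runif(length(g), 0.02, 1)
        } else {
          sign <- if (cls == "up") 1 else -1
          de[g, fc_col] <- sign * (lfc_min + stats::rexp(length(g), rate = 2))
          de[g, p_col] <- stats::runif(length(g), 0, 0.01)
        }
      }
      de[g, "cluster"] <- lab
    }
    rest <- de$cluster == "none"
    de$log2fc_preB[rest] <- stats::runif(sum(rest), -0.55, 0.55)
    de$fdr_preB[rest] <- stats::runif(sum(rest), 0.02, 1)
    de$log2fc_immB[rest] <- stats::runif(sum(rest), -0.55, 0.55)
    de$fdr_immB[rest] <- stats::runif(sum(rest), 0.02, 1)
  })
  rownames(de) <- NULL
  de
}
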