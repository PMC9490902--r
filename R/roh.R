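# Run-of-homozygosity detection (PLINK-style scanning window) and
# homozygosity / inbreeding summaries.

#' Default ROH scanning parameters
#'
#' The PLINK 1.9 `--homozyg` defaults: 50-SNP windows tolerating at most 1
#' heterozygote and 5 missing calls; a SNP is in-run when at least 5% of the
#' windows fully inside the chromosome that overlap it are homozygous;
#' candidate runs are split at gaps above 1000 kb and reported when they hold
#' at least 100 SNPs, span at least 1000 kb, and have at least one SNP per
#' 50 kb.
#'
#' @param window_snps window size in SNPs.
#' @param window_het_max maximum heterozygotes per homozygous window.
#' @param window_missing_max maximum missing calls per homozygous window.
#' @param hit_fraction minimum fraction of overlapping homozygous windows.
#' @param min_snps minimum SNPs per reported segment.
#' @param min_kb minimum segment length (kb).
#' @param max_gap_kb maximum within-segment gap (kb).
#' @param min_density_kb_per_snp density requirement: at most this many kb
#'   per SNP within a segment.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, window_het_max = 1,
                       window_missing_max = 5, hit_fraction = 0.05,
                       min_snps = 100, min_kb = 1000, max_gap_kb = 1000,
                       min_density_kb_per_snp = 50) {
  p <- list(window_snps = window_snps, window_het_max = window_het_max,
            window_missing_max = window_missing_max,
            hit_fraction = hit_fraction, min_snps = min_snps,
            min_kb = min_kb, max_gap_kb = max_gap_kb,
            min_density_kb_per_snp = min_density_kb_per_snp)
  if (any(unlist(p) <= 0)) stop("all ROH parameters must be positive")
  if (hit_fraction > 1) stop("hit_fraction must be in (0, 1]")
  class(p) <- "roh_params"
  p
}

#' Detect runs of homozygosity
#'
#' Per sample and chromosome: (1) a `window_snps`-SNP window slides one SNP
#' at a time; a window is homozygous when it contains at most
#' `window_het_max` heterozygotes and `window_missing_max` missing calls;
#' (2) each SNP receives the fraction of overlapping windows (only windows
#' fully inside the chromosome) that are homozygous, and is in-run when the
#' fraction is at least `hit_fraction`; (3) maximal stretches of in-run SNPs
#' are split at bp gaps above `max_gap_kb` and reported when they satisfy the
#' SNP-count, length and density thresholds.
#'
#' @param G a [genotype_matrix()], variants sorted by position within
#'   chromosome.
#' @param params a [roh_params()] list.
#' @return data.frame of segments: `sample`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_kb`; disjoint and sorted within sample/chromosome.
#' @export
detect_roh <- function(G, params = roh_params()) {
  vt <- G$variants
  segs <- list()
  for (ch in unique(vt$chrom)) {
    idx <- which(vt$chrom == ch)
    pos <- vt$pos[idx]
    if (is.unsorted(pos, strictly = TRUE)) stop("variants unsorted on ", ch)
    L <- length(idx)
    w <- params$window_snps
    for (si in seq_len(nrow(G$calls))) {
      g <- G$calls[si, idx]
      het <- as.integer(!is.na(g) & g == 1)
      mis <- as.integer(is.na(g))
      if (L >= w) {
        ch_cum <- c(0, cumsum(het))
        mi_cum <- c(0, cumsum(mis))
        nw <- L - w + 1L
        wh <- ch_cum[(w + 1):(L + 1)] - ch_cum[1:nw]  # hets per window
        wm <- mi_cum[(w + 1):(L + 1)] - mi_cum[1:nw]
        hom <- as.integer(wh <= params$window_het_max &
                          wm <= params$window_missing_max)
        # windows overlapping SNP j: starts max(1, j-w+1) .. min(j, nw)
        hom_cum <- c(0, cumsum(hom))
        j <- seq_len(L)
        lo <- pmax(1L, j - w + 1L)
        hi <- pmin(j, nw)
        n_over <- pmax(hi - lo + 1L, 0L)
        n_hom <- ifelse(n_over > 0, hom_cum[hi + 1L] - hom_cum[lo], 0L)
        inrun <- n_over > 0 & n_hom / pmax(n_over, 1L) >= params$hit_fraction
      } else inrun <- rep(FALSE, L)
      if (!any(inrun)) next
      r <- rle(inrun)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        run <- starts[k]:ends[k]
        # split at large bp gaps
        gaps <- which(diff(pos[run]) > params$max_gap_kb * 1000)
        pieces <- split(run, findInterval(seq_along(run), gaps + 1L))
        for (pc in pieces) {
          n_snps <- length(pc)
          len_kb <- (pos[pc[n_snps]] - pos[pc[1]] + 1) / 1000
          if (n_snps >= params$min_snps && len_kb >= params$min_kb &&
              len_kb / n_snps <= params$min_density_kb_per_snp)
            segs[[length(segs) + 1]] <- data.frame(
              sample = G$samples[si], chrom = ch,
              start_bp = pos[pc[1]], end_bp = pos[pc[n_snps]],
              n_snps = n_snps, length_kb = len_kb)
        }
      }
    }
  }
  if (!length(segs))
    return(data.frame(sample = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_kb = numeric(0)))
  out <- do.call(rbind, segs)
  out[order(out$sample, out$chrom, out$start_bp), , drop = FALSE]
}

#' Per-sample and per-cluster ROH summaries
#'
#' @param segments output of [detect_roh()].
#' @param samples character vector of all cohort sample ids (samples without
#'   segments get zeros).
#' @param genome_length_mb genotyped genome span in Mb (denominator of
#'   F_ROH); defaults should be the span of the variant table used.
#' @param clusters optional per-sample cluster labels (named or in `samples`
#'   order) for cluster means.
#' @return list with `per_sample` (sample, total_mb, n_segments, f_roh) and
#'   `per_cluster` (cluster means) when labels are given.
#' @export
roh_summary <- function(segments, samples, genome_length_mb, clusters = NULL) {
  tot <- setNames(rep(0, length(samples)), samples)
  nseg <- setNames(rep(0L, length(samples)), samples)
  if (nrow(segments)) {
    agg_t <- tapply(segments$length_kb / 1000, segments$sample, sum)
    agg_n <- tapply(segments$length_kb, segments$sample, length)
    tot[names(agg_t)] <- agg_t
    nseg[names(agg_n)] <- agg_n
  }
  per_sample <- data.frame(sample = samples, total_mb = as.numeric(tot),
                           n_segments = as.integer(nseg),
                           f_roh = as.numeric(tot) / genome_length_mb)
  out <- list(per_sample = per_sample)
  if (!is.null(clusters)) {
    cl <- if (!is.null(names(clusters))) clusters[samples] else clusters
    out$per_cluster <- data.frame(
      cluster = sort(unique(cl)),
      mean_total_mb = as.numeric(tapply(per_sample$total_mb, cl, mean)),
      mean_n_segments = as.numeric(tapply(per_sample$n_segments, cl, mean)),
      mean_f_roh = as.numeric(tapply(per_sample$f_roh, cl, mean)))
  }
  out
}

#' Method-of-moments inbreeding coefficient from excess homozygosity
#'
#' `F = (O_hom - E_hom) / (L_used - E_hom)` per sample, with
#' `E_hom = sum_l (1 - 2 p_l (1 - p_l) n_l / (n_l - 1))` over that sample's
#' non-missing polymorphic sites (`n_l` = allele count used to estimate
#' `p_l`). Monomorphic sites are excluded.
#'
#' @param G a [genotype_matrix()] with at least 2 samples.
#' @return named numeric vector of per-sample F.
#' @export
het_inbreeding <- function(G) {
  if (nrow(G$calls) < 2) stop("allele frequencies undefined with a single sample")
  p <- allele_freq(G)
  nl <- 2 * colSums(!is.na(G$calls))
  use <- is.finite(p) & p > 0 & p < 1 & nl > 2
  g <- G$calls[, use, drop = FALSE]
  e_site <- 1 - 2 * p[use] * (1 - p[use]) * nl[use] / (nl[use] - 1)
  sapply(seq_len(nrow(g)), function(i) {
    ok <- !is.na(g[i, ])
    o_hom <- sum(g[i, ok] != 1)
    e_hom <- sum(e_site[ok])
    (o_hom - e_hom) / (sum(ok) - e_hom)
  }) |> setNames(G$samples)
}
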