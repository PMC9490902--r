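# Genotype and sample quality control: relatedness pruning, site
# heterozygosity outliers, call-rate filters, exact Hardy-Weinberg test.

#' Flag sites with outlying heterozygosity
#'
#' Per-site heterozygosity rate = heterozygote count / non-missing calls;
#' sites with rate greater than `mean + k_sd * SD` of the rate distribution
#' are flagged (one-sided: only excess heterozygosity is an artefact
#' signature). All-missing sites are excluded from the mean/SD and flagged
#' separately.
#'
#' @param G a [genotype_matrix()].
#' @param k_sd SD multiplier (default 3).
#' @return list with logical `flagged` (per variant), `all_missing`, and the
#'   `mean`/`sd` of the rate distribution.
#' @export
site_het_outliers <- function(G, k_sd = 3) {
  n_obs <- colSums(!is.na(G$calls))
  het <- colSums(G$calls == 1, na.rm = TRUE)
  rate <- ifelse(n_obs > 0, het / n_obs, NA_real_)
  mu <- mean(rate, na.rm = TRUE)
  s <- sd(rate, na.rm = TRUE)
  flagged <- !is.na(rate) & s > 0 & rate > mu + k_sd * s
  list(flagged = flagged, all_missing = n_obs == 0, mean = mu, sd = s)
}

#' Call-rate filter flags (sites first, then samples)
#'
#' Sites with missing fraction strictly above `site_max_missing` are flagged;
#' sample missingness is then computed on the retained sites and samples
#' strictly above `sample_max_missing` are flagged (the PLINK
#' variants-before-samples order).
#'
#' @param G a [genotype_matrix()].
#' @param site_max_missing maximum tolerated per-site missing fraction.
#' @param sample_max_missing maximum tolerated per-sample missing fraction.
#' @return list with logical `site_flagged` and `sample_flagged`.
#' @export
call_rate_filter <- function(G, site_max_missing = 0.01,
                             sample_max_missing = 0.05) {
  miss <- is.na(G$calls)
  site_flagged <- colMeans(miss) > site_max_missing
  kept <- miss[, !site_flagged, drop = FALSE]
  sample_flagged <- if (ncol(kept) > 0) rowMeans(kept) > sample_max_missing
                    else rep(FALSE, nrow(miss))
  list(site_flagged = site_flagged, sample_flagged = sample_flagged)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the allele counts, the two-sided p-value is
#' the total probability of heterozygote counts whose conditional probability
#' does not exceed that of the observed count. Probabilities are built with
#' the standard recurrence over heterozygote counts (the approach PLINK's
#' `--hwe` uses), which is numerically stable without factorials.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return the exact p-value in (0, 1].
#' @export
hwe_exact <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be non-negative")
  n <- nAA + nAa + naa
  if (n < 1) stop("at least one genotype required")
  rare <- 2 * min(nAA, naa) + nAa        # count of the rarer allele
  # heterozygote counts compatible with the allele counts share rare's parity
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  probs <- numeric(length(hets))
  # start from the mid het count and apply the ratio recurrence both ways:
  # P(h+2)/P(h) = 4*homR(h)*homC(h) / ((h+2)*(h+1))
  mid_i <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  probs[mid_i] <- 1
  if (mid_i < length(hets)) for (i in mid_i:(length(hets) - 1)) {
    h <- hets[i]
    homR <- (rare - h) / 2
    homC <- n - h - homR
    probs[i + 1] <- probs[i] * 4 * homR * homC / ((h + 2) * (h + 1))
  }
  if (mid_i > 1) for (i in mid_i:2) {
    h <- hets[i]
    homR <- (rare - h) / 2
    homC <- n - h - homR
    probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (homR + 1) * (homC + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(nAa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Pairwise relatedness (PI_HAT) and pruning flags
#'
#' Method-of-moments genome-wide IBD estimation: per pair, observed IBS
#' 0/1/2 counts are combined with their Hardy-Weinberg expectations (given
#' estimated allele frequencies, treated as known) to estimate
#' P(IBD = 0, 1, 2); `PI_HAT = P(IBD=2) + P(IBD=1)/2`. For each pair above
#' `pi_hat_max`, the member with more missingness is flagged for removal.
#'
#' @param G a [genotype_matrix()].
#' @param pi_hat_max flagging threshold (default 0.185, midpoint between
#'   2nd- and 3rd-degree relatives).
#' @return list with `pairs` (data.frame: sample1, sample2, pi_hat) for pairs
#'   above threshold, `pi_hat` full symmetric matrix, and logical
#'   `sample_flagged`.
#' @export
relatedness_prune <- function(G, pi_hat_max = 0.185) {
  N <- nrow(G$calls)
  if (N < 2)
    return(list(pairs = data.frame(), pi_hat = matrix(NA_real_, N, N),
                sample_flagged = rep(FALSE, N)))
  p <- allele_freq(G)
  X <- colSums(G$calls, na.rm = TRUE)          # alt allele count
  T_ <- 2 * colSums(!is.na(G$calls))           # total alleles
  use <- is.finite(p) & p > 0 & p < 1 & T_ >= 4
  g <- G$calls[, use, drop = FALSE]
  X <- X[use]; T_ <- T_[use]
  Y <- T_ - X
  # HWE expectations of IBS states given IBD state, from unbiased
  # product-moment estimators of the allele-frequency powers (counts-based
  # finite-sample correction; frequencies are estimated from this cohort)
  d3 <- T_ * (T_ - 1) * (T_ - 2)
  d4 <- d3 * (T_ - 3)
  e0_ibs0 <- sum(2 * X * (X - 1) * Y * (Y - 1) / d4)
  e0_ibs1 <- sum(4 * (X * (X - 1) * (X - 2) * Y + X * Y * (Y - 1) * (Y - 2)) / d4)
  e1_ibs1 <- sum(2 * (X * (X - 1) * Y + X * Y * (Y - 1)) / d3)
  e0_ibs2 <- sum((X * (X - 1) * (X - 2) * (X - 3) + Y * (Y - 1) * (Y - 2) * (Y - 3) +
                  4 * X * (X - 1) * Y * (Y - 1)) / d4)
  e1_ibs2 <- sum((X * (X - 1) * (X - 2) + Y * (Y - 1) * (Y - 2) +
                  X * (X - 1) * Y + X * Y * (Y - 1)) / d3)
  miss_count <- rowSums(is.na(G$calls))
  pihat <- matrix(NA_real_, N, N, dimnames = list(G$samples, G$samples))
  pairs <- list()
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    d <- abs(g[i, ok] - g[j, ok])
    scale <- sum(ok) / length(X)   # prorate expectations to observed sites
    n_ibs0 <- sum(d == 2); n_ibs1 <- sum(d == 1); n_ibs2 <- sum(d == 0)
    P0 <- n_ibs0 / (e0_ibs0 * scale)
    P1 <- (n_ibs1 - P0 * e0_ibs1 * scale) / (e1_ibs1 * scale)
    P2 <- (n_ibs2 - P0 * e0_ibs2 * scale - P1 * e1_ibs2 * scale) / sum(ok)
    est <- pmax(c(P0, P1, P2), 0)
    est <- est / sum(est)
    ph <- est[3] + est[2] / 2
    pihat[i, j] <- pihat[j, i] <- ph
    if (ph > pi_hat_max) pairs[[length(pairs) + 1]] <-
      data.frame(sample1 = G$samples[i], sample2 = G$samples[j], pi_hat = ph)
  }
  flagged <- rep(FALSE, N)
  names(flagged) <- G$samples
  if (length(pairs)) {
    pairs <- do.call(rbind, pairs)
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs$sample1[r], G$samples)
      j <- match(pairs$sample2[r], G$samples)
      if (flagged[i] || flagged[j]) next
      drop <- if (miss_count[i] >= miss_count[j]) i else j
      flagged[drop] <- TRUE
    }
  } else pairs <- data.frame(sample1 = character(0), sample2 = character(0),
                             pi_hat = numeric(0))
  list(pairs = pairs, pi_hat = pihat, sample_flagged = flagged)
}

#' Run the full QC pipeline
#'
#' Applies, in order: relatedness pruning, site-heterozygosity outlier
#' removal, site call-rate, sample call-rate, exact Hardy-Weinberg filtering.
#' The pipeline is a pure function of its inputs and is idempotent on
#' already-clean data.
#'
#' @param G a [genotype_matrix()].
#' @param geno,mind site and sample maximum missing fractions.
#' @param hwe_alpha HWE exact-test removal threshold (`p < hwe_alpha`).
#' @param het_sd site-heterozygosity SD multiplier.
#' @param pi_hat relatedness PI_HAT threshold.
#' @return list with `genotypes` (the filtered matrix) and `report` (class
#'   `qc_report`): per-item removal reasons and the thresholds used; removal
#'   counts reconcile exactly with the dimension change.
#' @export
qc_pipeline <- function(G, geno = 0.01, mind = 0.05, hwe_alpha = 1e-6,
                        het_sd = 3, pi_hat = 0.185) {
  removed_samples <- data.frame(id = character(0), reason = character(0))
  removed_sites <- data.frame(id = character(0), reason = character(0))
  rel <- relatedness_prune(G, pi_hat_max = pi_hat)
  if (any(rel$sample_flagged)) {
    removed_samples <- rbind(removed_samples,
      data.frame(id = names(rel$sample_flagged)[rel$sample_flagged],
                 reason = "relatedness"))
    G <- subset_genotypes(G, samples = !rel$sample_flagged)
  }
  het <- site_het_outliers(G, k_sd = het_sd)
  drop_site <- het$flagged | het$all_missing
  if (any(drop_site)) {
    removed_sites <- rbind(removed_sites,
      data.frame(id = G$variants$id[drop_site],
                 reason = ifelse(het$all_missing[drop_site],
                                 "all_missing", "het_outlier")))
    G <- subset_genotypes(G, variants = !drop_site)
  }
  cr <- call_rate_filter(G, site_max_missing = geno, sample_max_missing = mind)
  if (any(cr$site_flagged)) {
    removed_sites <- rbind(removed_sites,
      data.frame(id = G$variants$id[cr$site_flagged], reason = "site_call_rate"))
    G <- subset_genotypes(G, variants = !cr$site_flagged)
  }
  if (any(cr$sample_flagged)) {
    removed_samples <- rbind(removed_samples,
      data.frame(id = G$samples[cr$sample_flagged], reason = "sample_call_rate"))
    G <- subset_genotypes(G, samples = !cr$sample_flagged)
  }
  hwe_p <- apply(G$calls, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_exact(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  drop_hwe <- hwe_p < hwe_alpha
  if (any(drop_hwe)) {
    removed_sites <- rbind(removed_sites,
      data.frame(id = G$variants$id[drop_hwe], reason = "hwe"))
    G <- subset_genotypes(G, variants = !drop_hwe)
  }
  report <- structure(list(removed_samples = removed_samples,
                           removed_sites = removed_sites,
                           thresholds = list(geno = geno, mind = mind,
                                             hwe = hwe_alpha, het_sd = het_sd,
                                             pi_hat = pi_hat),
                           order = c("relatedness", "het_outlier",
                                     "site_call_rate", "sample_call_rate", "hwe")),
                      class = "qc_report")
  list(genotypes = G, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", nrow(x$removed_samples), "samples and",
      nrow(x$removed_sites), "sites removed\n")
  if (nrow(x$removed_samples)) print(table(x$removed_samples$reason))
  if (nrow(x$removed_sites)) print(table(x$removed_sites$reason))
  invisible(x)
}
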