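# Synthetic admixed cohorts with known ground truth. Every downstream stage
# of the package is testable against these generators without any download.

#' Simulate a marker map for a synthetic cohort
#'
#' Lays out `L` biallelic variants uniformly over `n_chrom` chromosomes of
#' `chrom_length_bp` each, with a linear genetic map at `cM_per_Mb`.
#'
#' @param L total number of variants.
#' @param n_chrom number of chromosomes (variants split evenly).
#' @param chrom_length_bp chromosome length in bp (default 100 Mb = 1 Morgan
#'   at the default map rate).
#' @param cM_per_Mb constant recombination rate of the linear map.
#' @param seed integer seed.
#' @return a [variant_table()] with cM filled in.
#' @export
simulate_variant_table <- function(L, n_chrom = 1, chrom_length_bp = 1e8,
                                   cM_per_Mb = 1, seed = 1) {
  set.seed(seed)
  per <- diff(round(seq(0, L, length.out = n_chrom + 1)))
  parts <- lapply(seq_len(n_chrom), function(ch) {
    pos <- sort(sample.int(chrom_length_bp - 1L, per[ch])) + 1L
    data.frame(chrom = paste0("chr", ch), pos = pos)
  })
  df <- do.call(rbind, parts)
  variant_table(df$chrom, df$pos, cM = df$pos * 1e-6 * cM_per_Mb)
}

#' Simulate ancestral allele frequencies under the Balding-Nichols model
#'
#' Each of `K` ancestral populations receives per-variant frequencies drawn
#' from a Beta distribution with mean `p0[l]` (a shared ancestral frequency,
#' Uniform(0.05, 0.95)) and variance `F[k] * p0[l] * (1 - p0[l])`. `F` is the
#' population-specific differentiation parameter; `F -> 0` collapses the
#' population onto the shared frequencies.
#'
#' @param K number of ancestral populations.
#' @param L number of variants.
#' @param F differentiation parameter(s) in (0, 1); recycled to length `K`.
#'   `F = 0` is accepted as the exact zero-variance limit.
#' @param seed integer seed.
#' @param p0_range interval from which shared ancestral frequencies are drawn;
#'   bounded away from 0 and 1 to avoid degenerate monomorphic sites.
#' @return an object of class `ancestral_freqs`: list with `P` (K x L matrix),
#'   `F` (length K) and `p0` (length L).
#' @export
simulate_ancestral_freqs <- function(K, L, F = 0.1, seed = 1,
                                     p0_range = c(0.05, 0.95)) {
  if (K < 1 || L < 1) stop("K and L must be >= 1")
  F <- rep_len(as.numeric(F), K)
  if (any(!is.finite(F)) || any(F < 0) || any(F >= 1))
    stop("each F must be finite and in [0, 1)")
  set.seed(seed)
  p0 <- runif(L, p0_range[1], p0_range[2])
  P <- matrix(0, K, L)
  for (k in seq_len(K)) {
    if (F[k] == 0) {
      P[k, ] <- p0
    } else {
      # Beta(a, b) with a + b = (1 - F)/F gives mean p0, var F*p0*(1-p0)
      s <- (1 - F[k]) / F[k]
      P[k, ] <- rbeta(L, s * p0, s * (1 - p0))
    }
  }
  structure(list(P = P, F = F, p0 = p0), class = "ancestral_freqs")
}

#' Sample ancestry tracts for one haplotype under a single admixture pulse
#'
#' Breakpoints follow a Poisson process at rate `pulse_g` per Morgan along the
#' genetic map (the tract-length law `Exp(pulse_g)` of a pulse `pulse_g`
#' generations ago); each tract's ancestry is drawn independently from the
#' individual's ancestry proportions `q`.
#'
#' @param q length-K ancestry proportions (sums to 1).
#' @param cM variant genetic positions for one chromosome (non-decreasing).
#' @param pulse_g generations since the admixture pulse (breakpoint rate per
#'   Morgan); must be >= 1.
#' @return list with `ancestry` (per-variant ancestral population index) and
#'   `breaks_cM` (breakpoint positions).
#' @export
sample_ancestry_tracts <- function(q, cM, pulse_g) {
  if (pulse_g < 1) stop("pulse_g must be >= 1")
  span_M <- (max(cM) - min(cM)) / 100
  nb <- rpois(1, pulse_g * span_M)
  breaks <- sort(runif(nb, min(cM), max(cM)))
  seg <- findInterval(cM, breaks) + 1L   # tract index per variant
  anc <- sample.int(length(q), nb + 1L, replace = TRUE, prob = q)
  list(ancestry = anc[seg], breaks_cM = breaks)
}

#' Simulate an admixed diploid cohort from ancestral frequencies
#'
#' Each haplotype is painted as a mosaic of ancestry tracts
#' ([sample_ancestry_tracts()]) under one admixture pulse `pulse_g`
#' generations ago; alleles are then drawn `Bernoulli(P[ancestry, l])`
#' independently per site (no background LD within tracts). Genotypes are the
#' sums of the two haplotypes; allele 1 is derived by construction.
#'
#' @param freqs an `ancestral_freqs` object (see [simulate_ancestral_freqs()]).
#' @param Q `N x K` matrix of individual ancestry proportions; rows sum to 1.
#' @param variants a [variant_table()] with cM positions (the genetic map).
#' @param pulse_g generations since the admixture pulse.
#' @param seed integer seed.
#' @return list with `haplotypes` ([haplotype_set()]), `genotypes`
#'   ([genotype_matrix()]) and `truth` (list: `Q_true`, `pulse_g`,
#'   `tract_cM` interior tract lengths, `local_ancestry` 2N x L matrix,
#'   `roh_regions` empty, `seed`).
#' @export
simulate_admixed_cohort <- function(freqs, Q, variants, pulse_g, seed = 1) {
  Q <- as.matrix(Q)
  K <- nrow(freqs$P)
  L <- ncol(freqs$P)
  if (ncol(Q) != K) stop("Q has ", ncol(Q), " columns but freqs has ", K, " populations")
  if (nrow(variants) != L) stop("variants/freqs dimension mismatch")
  if (any(abs(rowSums(Q) - 1) > 1e-9)) stop("rows of Q must sum to 1")
  set.seed(seed)
  N <- nrow(Q)
  chroms <- unique(variants$chrom)
  H <- matrix(0L, 2L * N, L)
  anc_mat <- matrix(0L, 2L * N, L)
  tract_cM <- numeric(0)
  for (ch in chroms) {
    idx <- which(variants$chrom == ch)
    cM <- variants$cM[idx]
    if (anyNA(cM)) stop("variants must carry cM positions (empty genetic map?)")
    for (h in seq_len(2L * N)) {
      i <- (h + 1L) %/% 2L
      tr <- sample_ancestry_tracts(Q[i, ], cM, pulse_g)
      anc_mat[h, idx] <- tr$ancestry
      H[h, idx] <- rbinom(length(idx), 1L, freqs$P[cbind(tr$ancestry, idx)])
      if (length(tr$breaks_cM) >= 2)
        tract_cM <- c(tract_cM, diff(tr$breaks_cM))
    }
  }
  samples <- sprintf("S%03d", seq_len(N))
  hs <- haplotype_set(H, samples, variants)
  truth <- list(Q_true = Q, pulse_g = pulse_g, tract_cM = tract_cM,
                local_ancestry = anc_mat, roh_regions = list(), seed = seed)
  list(haplotypes = hs, genotypes = haplotypes_to_genotypes(hs), truth = truth)
}

#' Draw Dirichlet ancestry proportions
#'
#' @param N number of individuals.
#' @param alpha Dirichlet concentration, length K (or scalar recycled).
#' @param K number of components (taken from `alpha` when it has length > 1).
#' @param seed integer seed.
#' @return `N x K` matrix with rows summing to 1.
#' @export
simulate_Q <- function(N, alpha = 1, K = length(alpha), seed = 1) {
  if (length(alpha) == 1) alpha <- rep(alpha, K)
  set.seed(seed)
  g <- matrix(rgamma(N * K, shape = rep(alpha, each = N)), N, K)
  g / rowSums(g)
}

#' Simulate a two-pulse admixed cohort by mixing two painted layers
#'
#' Half of the samples are painted with breakpoint rate `g1`, half with `g2`,
#' all from the same ancestry-proportion distribution, so the cohort's
#' admixture LD decays as a mixture of the two exponentials while expected
#' allele frequencies are common to both layers.
#'
#' @inheritParams simulate_admixed_cohort
#' @param g1,g2 generations since the older and the more recent pulse.
#' @return as [simulate_admixed_cohort()]; `truth$pulse_g` is `c(g1, g2)` and
#'   `truth$layer` records each sample's pulse.
#' @export
simulate_two_pulse_cohort <- function(freqs, Q, variants, g1, g2, seed = 1) {
  N <- nrow(Q)
  n1 <- N %/% 2L
  c1 <- simulate_admixed_cohort(freqs, Q[seq_len(n1), , drop = FALSE],
                                variants, g1, seed = seed)
  c2 <- simulate_admixed_cohort(freqs, Q[(n1 + 1L):N, , drop = FALSE],
                                variants, g2, seed = seed + 1L)
  H <- rbind(c1$haplotypes$H, c2$haplotypes$H)
  samples <- sprintf("S%03d", seq_len(N))
  hs <- haplotype_set(H, samples, variants)
  truth <- list(Q_true = Q, pulse_g = c(g1, g2),
                layer = rep(c(g1, g2), c(n1, N - n1)), seed = seed)
  list(haplotypes = hs, genotypes = haplotypes_to_genotypes(hs), truth = truth)
}

#' Inject a run of homozygosity into one sample
#'
#' Within `region`, the sample's second haplotype is overwritten by its first,
#' so every genotype in the region becomes homozygous (the signature of a
#' recent-consanguinity autozygous tract). Idempotent.
#'
#' @param cohort list with `haplotypes`, `genotypes`, `truth` as returned by
#'   [simulate_admixed_cohort()].
#' @param sample sample id.
#' @param chrom chromosome label.
#' @param region length-2 bp interval `c(start, end)`, 1-based inclusive.
#' @return the updated cohort; the injected region is appended to
#'   `truth$roh_regions`.
#' @export
inject_roh <- function(cohort, sample, chrom, region) {
  hs <- cohort$haplotypes
  i <- match(sample, hs$samples)
  if (is.na(i)) stop("unknown sample: ", sample)
  vt <- hs$variants
  if (!chrom %in% vt$chrom) stop("unknown chromosome: ", chrom)
  cmax <- max(vt$pos[vt$chrom == chrom])
  if (region[1] < 1 || region[2] > cmax || region[2] < region[1])
    stop("region outside chromosome bounds")
  idx <- which(vt$chrom == chrom & vt$pos >= region[1] & vt$pos <= region[2])
  hs$H[2L * i, idx] <- hs$H[2L * i - 1L, idx]
  cohort$haplotypes <- hs
  cohort$genotypes <- haplotypes_to_genotypes(hs)
  cohort$truth$roh_regions <- c(cohort$truth$roh_regions,
                                list(list(sample = sample, chrom = chrom,
                                          start = region[1], end = region[2])))
  cohort
}

#' Simulate a variant annotation table
#'
#' Stands in for consequence/deleteriousness/trait annotation of real
#' cohorts. A fraction `lof_fraction` of variants become putative
#' loss-of-function: most are annotated `stop_gained`, and an overlapping
#' subset is flagged as members of a curated LOF list (so the
#' curated-list/stop-gain union is exercised). LOF deleteriousness scores are
#' drawn to span both the high (>= 25) and low (<= 5) bins of a 0-50
#' CADD-like scale; non-LOF variants receive benign consequences and low
#' scores. A fraction `trait_fraction` of variants get a trait label.
#'
#' @param variants a [variant_table()].
#' @param lof_fraction fraction of variants that are putative LOF.
#' @param trait_fraction fraction of variants carrying a trait association.
#' @param seed integer seed.
#' @param high_frac fraction of LOF variants placed in the high-deleteriousness
#'   score bin (the rest go to the low bin).
#' @return `data.frame` of class `annotation_table`: `id`, `consequence`,
#'   `score`, `curated` (logical), `trait` ("" when none).
#' @export
simulate_annotations <- function(variants, lof_fraction = 0.05,
                                 trait_fraction = 0.1, seed = 1,
                                 high_frac = 0.5) {
  if (lof_fraction < 0 || lof_fraction > 1) stop("lof_fraction must be in [0, 1]")
  set.seed(seed)
  L <- nrow(variants)
  n_lof <- round(lof_fraction * L)
  lof_idx <- sort(sample.int(L, n_lof))
  cons <- sample(c("intron_variant", "intergenic_variant", "synonymous_variant"),
                 L, replace = TRUE)
  score <- round(runif(L, 0, 15), 2)
  curated <- rep(FALSE, L)
  if (n_lof > 0) {
    # ~80% of LOFs are stop-gains, ~50% are on the curated list (overlapping),
    # so both routes into the union and their overlap are populated.
    cons[lof_idx] <- ifelse(runif(n_lof) < 0.8, "stop_gained", "missense_variant")
    curated[lof_idx] <- runif(n_lof) < 0.5
    curated[lof_idx[cons[lof_idx] != "stop_gained"]] <- TRUE
    nh <- round(high_frac * n_lof)
    hi <- seq_len(n_lof) <= nh
    score[lof_idx[hi]] <- round(runif(nh, 25, 50), 2)
    score[lof_idx[!hi]] <- round(runif(n_lof - nh, 0, 5), 2)
  }
  trait <- rep("", L)
  n_tr <- round(trait_fraction * L)
  tr_idx <- sample.int(L, n_tr)
  trait[tr_idx] <- sample(c("HDL", "LDL", "height", "blood_trait", "BMI",
                            "serum_metabolite"), n_tr, replace = TRUE)
  ann <- data.frame(id = variants$id, consequence = cons, score = score,
                    curated = curated, trait = trait, stringsAsFactors = FALSE)
  class(ann) <- c("annotation_table", "data.frame")
  ann
}

#' Shape LOF allele frequencies by deleteriousness and selection efficiency
#'
#' Applies per-population purifying-selection pressure to the ancestral
#' frequencies of LOF variants: `P[k, l]` is multiplied by
#' `exp(-efficiency[k] * score[l] / 50)`, so high-deleteriousness variants are
#' suppressed most where selection is most efficient (large `efficiency`,
#' i.e. large effective population size). This creates the monotone
#' deleteriousness/frequency link the deleteriousness-ratio statistic is
#' designed to detect.
#'
#' @param freqs an `ancestral_freqs` object.
#' @param annotations an annotation table from [simulate_annotations()].
#' @param efficiency length-K non-negative selection-efficiency surrogates.
#' @return the modified `ancestral_freqs`, with `selection_s` (the per-variant
#'   suppression exponent) attached.
#' @export
shape_lof_freqs <- function(freqs, annotations, efficiency) {
  K <- nrow(freqs$P)
  efficiency <- rep_len(efficiency, K)
  if (any(efficiency < 0)) stop("efficiency must be non-negative")
  is_lof <- annotations$curated | annotations$consequence == "stop_gained"
  s <- ifelse(is_lof, annotations$score / 50, 0)
  for (k in seq_len(K))
    freqs$P[k, ] <- pmax(freqs$P[k, ] * exp(-efficiency[k] * s), 1e-4)
  freqs$selection_s <- s
  freqs
}
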