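# Independent oracles and small fixture builders shared across tests.

# Brute-force nSL oracle: per focal SNP and haplotype pair, expand the
# identity run by cumulative products left and right of the focal SNP.
# Independent of the scan's mismatch-interval algorithm.
nsl_oracle <- function(H) {
  n <- nrow(H); L <- ncol(H)
  out <- list()
  for (x in seq_len(L)) {
    der <- which(H[, x] == 1)
    anc <- which(H[, x] == 0)
    if (length(der) < 2 || length(anc) < 2) next
    tract <- function(i, j) {
      a <- H[i, ] == H[j, ]
      r <- if (x < L) sum(cumprod(a[(x + 1):L])) else 0
      l <- if (x > 1) sum(cumprod(rev(a[1:(x - 1)]))) else 0
      1 + r + l
    }
    pair_mean <- function(set) {
      cb <- utils::combn(set, 2)
      mean(apply(cb, 2, function(p) tract(p[1], p[2])))
    }
    out[[length(out) + 1]] <- data.frame(x = x, sl_a = pair_mean(anc),
                                         sl_d = pair_mean(der))
  }
  do.call(rbind, out)
}

# Closed-form HWE exact oracle: direct multinomial evaluation
# P(nAa | n, nA) = n! nA! na! 2^nAa / (nAA! nAa! naa! (2n)!), summed over
# heterozygote counts at most as probable as the observed one.
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  lp <- sapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    lfactorial(n) + lfactorial(nA) + lfactorial(na) + h * log(2) -
      lfactorial(aa) - lfactorial(h) - lfactorial(bb) - lfactorial(2 * n)
  })
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(nAa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# haplotype_set from a bare 0/1 matrix (pads to an even haplotype count)
hapset_from_matrix <- function(H, chrom = "chr1", spacing = 1000L) {
  if (nrow(H) %% 2) H <- H[-nrow(H), , drop = FALSE]
  vt <- variant_table(rep(chrom, ncol(H)), seq_len(ncol(H)) * spacing)
  haplotype_set(H, paste0("S", seq_len(nrow(H) / 2)), vt)
}

# small admixed test cohort used by several files
make_test_cohort <- function(K = 3, L = 600, N = 60, F = 0.2, pulse_g = 10,
                             alpha = 0.3, seed = 1, n_chrom = 2) {
  vt <- simulate_variant_table(L, n_chrom = n_chrom, seed = seed)
  fr <- simulate_ancestral_freqs(K, L, F = F, seed = seed + 1)
  Q <- simulate_Q(N, alpha = rep(alpha, K), seed = seed + 2)
  co <- simulate_admixed_cohort(fr, Q, vt, pulse_g = pulse_g, seed = seed + 3)
  co$freqs <- fr
  co
}
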