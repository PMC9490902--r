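# background fixture: HWE genotypes with MAF in [0.2, 0.5] (het rate >= 0.25)
het_rich_genotypes <- function(N, L, seed, chrom_length_bp = 2e7) {
  set.seed(seed)
  vt <- simulate_variant_table(L, n_chrom = 1, chrom_length_bp = chrom_length_bp,
                               seed = seed)
  calls <- sapply(runif(L, 0.2, 0.5), function(p) rbinom(N, 2, p))
  genotype_matrix(calls, vt)
}

# overwrite a sample's genotypes with homozygotes inside [start, end]
force_homozygous <- function(G, sample, start, end, seed = 1) {
  set.seed(seed)
  idx <- which(G$variants$pos >= start & G$variants$pos <= end)
  g <- G$calls[sample, idx]
  g[g == 1] <- sample(c(0L, 2L), sum(g == 1), replace = TRUE)
  G$calls[sample, idx] <- g
  G
}

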