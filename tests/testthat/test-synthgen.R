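test_that("Balding-Nichols frequencies have the stated moments and limits", {
  # zero-variance limit: P collapses onto the shared ancestral frequencies
  fr0 <- simulate_ancestral_freqs(2, 50, F = 0, seed = 1)
  expect_equal(fr0$P[1, ], fr0$p0)
  expect_equal(fr0$P[2, ], fr0$p0)

  # moment check at K = 3, L = 10000, F = 0.1: mean deviation from p0 ~ 0,
  # per-site variance ~ F * p0 * (1 - p0)
  fr <- simulate_ancestral_freqs(3, 10000, F = 0.1, seed = 2)
  expect_true(all(fr$P >= 0 & fr$P <= 1))
  expect_true(all(fr$p0 >= 0.05 & fr$p0 <= 0.95))
  for (k in 1:3) {
    expect_lt(abs(mean(fr$P[k, ] - fr$p0)), 0.005)
    expect_lt(abs(mean((fr$P[k, ] - fr$p0)^2) / mean(0.1 * fr$p0 * (1 - fr$p0)) - 1), 0.05)
  }

  expect_error(simulate_ancestral_freqs(2, 10, F = 1.2), "F must be")
  expect_error(simulate_ancestral_freqs(2, 10, F = NaN), "F must be")
})

test_that("identical seed and configuration reproduce the cohort bit for bit", {
  a <- make_test_cohort(seed = 7)
  b <- make_test_cohort(seed = 7)
  expect_identical(a$haplotypes$H, b$haplotypes$H)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  c <- make_test_cohort(seed = 8)
  expect_false(identical(a$haplotypes$H, c$haplotypes$H))
})

test_that("haplotype painting follows the individual ancestry proportions", {
  vt <- simulate_variant_table(200, seed = 3)
  fr <- simulate_ancestral_freqs(3, 200, F = 0.2, seed = 4)
  # degenerate mixture: Q = e1 paints every tract with ancestry 1
  Q <- matrix(rep(c(1, 0, 0), each = 5), 5, 3)
  co <- simulate_admixed_cohort(fr, Q, vt, pulse_g = 10, seed = 5)
  expect_true(all(co$truth$local_ancestry == 1L))
  # genotypes are exactly the haplotype pair sums and lie in {0,1,2}
  expect_true(all(co$genotypes$calls %in% 0:2))
  expect_identical(co$genotypes$calls,
                   haplotypes_to_genotypes(co$haplotypes)$calls)
  expect_error(simulate_admixed_cohort(fr, matrix(0.4, 5, 3), vt, 10),
               "sum to 1")
})

test_that("ancestry tract lengths are exponential with rate pulse_g per Morgan", {
  set.seed(11)
  g <- 10
  # 10-Morgan map so that boundary censoring of long tracts is negligible
  cM <- seq(0, 1000, length.out = 10000)
  lens <- unlist(lapply(1:50, function(i) {
    tr <- sample_ancestry_tracts(c(0.5, 0.5), cM, g)
    if (length(tr$breaks_cM) >= 2) diff(tr$breaks_cM)
  }))
  # interior tracts are Exp(g per Morgan), i.e. mean 1/g Morgans = 10 cM
  expect_lt(abs(mean(lens) / 100 - 1 / g) / (1 / g), 0.1)
  # a stray floating-point tie among ~5000 draws is harmless for the KS level
  ks <- suppressWarnings(ks.test(lens / 100, "pexp", rate = g))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort allele frequencies mix the ancestral ones through Q", {
  vt <- simulate_variant_table(800, seed = 21)
  fr <- simulate_ancestral_freqs(3, 800, F = 0.15, seed = 22)
  Q <- simulate_Q(500, alpha = c(1, 1, 1), seed = 23)
  co <- simulate_admixed_cohort(fr, Q, vt, pulse_g = 8, seed = 24)
  expected <- as.numeric(colMeans(Q) %*% fr$P)
  observed <- allele_freq(co$genotypes)
  # binomial sampling error at 2N = 1000 draws
  expect_lt(mean(abs(observed - expected)), 3 * mean(sqrt(expected * (1 - expected) / 1000)))
  expect_lt(max(abs(observed - expected)), 0.12)
})

test_that("ROH injection zeroes heterozygosity, is idempotent and bounded", {
  co <- make_test_cohort(L = 500, N = 10, seed = 31)
  vt <- co$genotypes$variants
  co2 <- inject_roh(co, "S003", "chr1", c(5e6, 4e7))
  idx <- vt$chrom == "chr1" & vt$pos >= 5e6 & vt$pos <= 4e7
  expect_equal(sum(co2$genotypes$calls["S003", idx] == 1), 0)
  co3 <- inject_roh(co2, "S003", "chr1", c(5e6, 4e7))
  expect_identical(co3$haplotypes$H, co2$haplotypes$H)
  expect_length(co3$truth$roh_regions, 2)
  expect_error(inject_roh(co, "nope", "chr1", c(1, 2)), "unknown sample")
  expect_error(inject_roh(co, "S001", "chrX", c(1, 2)), "unknown chromosome")
  expect_error(inject_roh(co, "S001", "chr1", c(1, 9e9)), "bounds")
})

test_that("annotation simulation honours its fractions and the score bins", {
  vt <- simulate_variant_table(1000, seed = 41)
  ann <- simulate_annotations(vt, lof_fraction = 0.1, trait_fraction = 0.2,
                              seed = 42)
  lof <- ann$curated | ann$consequence == "stop_gained"
  expect_equal(sum(lof), 100)
  expect_equal(sum(ann$trait != ""), 200)
  # LOF scores span both deleteriousness bins
  expect_gt(sum(ann$score[lof] >= 25), 0)
  expect_gt(sum(ann$score[lof] <= 5), 0)
  expect_true(all(ann$score >= 0 & ann$score <= 50))
  # lof_fraction = 0: no stop-gains, empty curated list
  ann0 <- simulate_annotations(vt, lof_fraction = 0, seed = 43)
  expect_equal(sum(ann0$consequence == "stop_gained"), 0)
  expect_equal(sum(ann0$curated), 0)
})

test_that("deleteriousness-shaped frequencies fall with the score", {
  vt <- simulate_variant_table(600, seed = 51)
  ann <- simulate_annotations(vt, lof_fraction = 0.3, seed = 52)
  fr <- simulate_ancestral_freqs(2, 600, F = 0.1, seed = 53)
  fr <- shape_lof_freqs(fr, ann, efficiency = c(2, 2))
  Q <- simulate_Q(300, alpha = c(1, 1), seed = 54)
  co <- simulate_admixed_cohort(fr, Q, vt, pulse_g = 5, seed = 55)
  lof <- which(ann$curated | ann$consequence == "stop_gained")
  af <- allele_freq(co$genotypes)[lof]
  # monotone link: frequency rank-decreases with deleteriousness score
  expect_lt(cor(ann$score[lof], af, method = "spearman"), -0.5)
})
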