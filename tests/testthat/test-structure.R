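test_that("LD pruning removes duplicated columns and spares independent ones", {
  set.seed(101)
  calls <- sapply(runif(80, 0.2, 0.8), function(p) rbinom(60, 2, p))
  calls[, 40] <- calls[, 39]                      # exact duplicate, r2 = 1
  vt <- variant_table(rep("chr1", 80), seq_len(80) * 1000)
  G <- genotype_matrix(calls, vt)
  kept <- ld_prune(G, window_snps = 50, step_snps = 20, r2_max = 0.4)
  expect_false(all(c(vt$id[39], vt$id[40]) %in% kept))
  expect_true(any(c(vt$id[39], vt$id[40]) %in% kept))
  # independent simulated variants: false-removal rate below 1%-ish
  calls2 <- sapply(runif(300, 0.2, 0.8), function(p) rbinom(400, 2, p))
  G2 <- genotype_matrix(calls2, variant_table(rep("chr1", 300), seq_len(300) * 1000))
  kept2 <- ld_prune(G2)
  expect_gte(length(kept2), 297)
  # r2_max = 1 removes nothing (no degenerate duplicates present)
  expect_length(ld_prune(G2, r2_max = 1), 300)
})

test_that("Patterson PCA separates populations and projection is consistent", {
  vt <- simulate_variant_table(800, seed = 111)
  fr <- simulate_ancestral_freqs(2, 800, F = 0.2, seed = 112)
  Q <- matrix(c(rep(c(1, 0), each = 40), rep(c(0, 1), each = 40)), 80, 2)
  co <- simulate_admixed_cohort(fr, Q, vt, pulse_g = 5, seed = 113)
  pc <- pca_patterson(co$genotypes, m = 10)
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))
  expect_lte(sum(pc$varfrac), 1)
  # scores are orthogonal
  cp <- crossprod(pc$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
  # PC1 separates the two populations cleanly (silhouette > 0.9)
  lab <- rep(1:2, each = 40)
  sil <- cluster::silhouette(lab, dist(pc$scores[, 1, drop = FALSE]))
  expect_gt(mean(sil[, "sil_width"]), 0.9)
  # projecting the training samples reproduces their scores
  proj <- pca_project(pc, co$genotypes)
  expect_lt(max(abs(proj - pc$scores)), 1e-8)
})

test_that("an unstructured cohort shows no outlying PCA component", {
  vt <- simulate_variant_table(800, seed = 121)
  fr1 <- simulate_ancestral_freqs(1, 800, F = 0.2, seed = 122)
  co1 <- simulate_admixed_cohort(fr1, matrix(1, 80, 1), vt, pulse_g = 5, seed = 123)
  pc1 <- pca_patterson(co1$genotypes, m = 10)
  fr2 <- simulate_ancestral_freqs(2, 800, F = 0.2, seed = 122)
  Q2 <- matrix(c(rep(c(1, 0), each = 40), rep(c(0, 1), each = 40)), 80, 2)
  co2 <- simulate_admixed_cohort(fr2, Q2, vt, pulse_g = 5, seed = 123)
  pc2 <- pca_patterson(co2$genotypes, m = 10)
  # structured cohort: dominant eigenvalue stands far out; unstructured: no gap
  gap1 <- pc1$eigenvalues[1] / pc1$eigenvalues[2]
  gap2 <- pc2$eigenvalues[1] / pc2$eigenvalues[2]
  expect_lt(gap1, 2)
  expect_gt(gap2, 5 * gap1)
})

test_that("Gaussian-mixture clustering recovers K on separated components", {
  set.seed(131)
  mu <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))   # 10-SD separation
  X <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(40, mu[k, 1]), rnorm(40, mu[k, 2]))))
  X <- cbind(X, matrix(rnorm(160 * 4), 160, 4))
  cl <- gmm_cluster(X, n_pc = 6, K_range = 1:9)
  expect_equal(cl$K, 4)
  expect_gt(mclust::adjustedRandIndex(cl$labels, rep(1:4, each = 40)), 0.95)
  expect_equal(rowSums(cl$posterior), rep(1, 160))
  expect_true(all(tabulate(cl$labels, cl$K) > 0))   # no empty component
  # single Gaussian chooses K = 1; constrained range forces K
  X1 <- matrix(rnorm(120 * 6), 120, 6)
  expect_equal(gmm_cluster(X1, K_range = 1:5)$K, 1)
  expect_equal(gmm_cluster(X1, K_range = 3)$K, 3)
})

test_that("admixture EM: closed form at K=1 and monotone likelihood ascent", {
  co <- make_test_cohort(L = 300, N = 40, seed = 141)
  f1 <- admixture_em(co$genotypes, K = 1)
  phat <- colSums(co$genotypes$calls) / (2 * nrow(co$genotypes$calls))
  expect_equal(as.numeric(f1$P),
               unname(pmin(pmax(phat, 1e-6), 1 - 1e-6)),   # MLE, clamped
               tolerance = 1e-9)
  expect_true(all(f1$Q == 1))
  f3 <- admixture_em(co$genotypes, K = 3, seed = 5, max_iter = 150)
  expect_true(all(diff(f3$loglik) > -1e-8))
  expect_equal(unname(rowSums(f3$Q)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(f3$P >= 1e-6 & f3$P <= 1 - 1e-6))
  expect_error(admixture_em(co$genotypes, K = 100), "exceed")
})

test_that("admixture EM recovers ancestry proportions at modest scale", {
  vt <- simulate_variant_table(1200, n_chrom = 2, seed = 151)
  fr <- simulate_ancestral_freqs(3, 1200, F = 0.25, seed = 152)
  Q <- simulate_Q(120, alpha = rep(0.3, 3), seed = 153)
  co <- simulate_admixed_cohort(fr, Q, vt, pulse_g = 10, seed = 154)
  fit <- admixture_em(co$genotypes, K = 3, seed = 1, tol = 1e-7)
  al <- align_Q(fit$Q, Q)
  expect_lt(al$mae, 0.05)
})

test_that("admixture cross-validation guards and determinism", {
  co <- make_test_cohort(L = 200, N = 30, seed = 161)
  expect_error(admixture_cv(co$genotypes, 1:2, mask_fraction = 0), "> 0")
  cv1 <- admixture_cv(co$genotypes, 1:2, folds = 2, seed = 9,
                      tol = 1e-4, max_iter = 200)
  cv2 <- admixture_cv(co$genotypes, 1:2, folds = 2, seed = 9,
                      tol = 1e-4, max_iter = 200)
  expect_identical(cv1$cv_error, cv2$cv_error)
})

test_that("Q dendrogram topology and invariances", {
  Q <- rbind(c(1, 0), c(1, 0), c(0, 1))
  rownames(Q) <- c("s1", "s2", "s3")
  dd <- q_dendrogram(Q)
  # identical rows merge at height 0; unit vectors force ((s1,s2),s3)
  expect_equal(min(dd$hclust$height), 0)
  expect_setequal(dd$hclust$merge[1, ], c(-1, -2))   # s1,s2 merge first
  expect_true(grepl("s1", dd$newick) && grepl("s3", dd$newick))
  # permutation invariance of merge heights
  perm <- c(3, 1, 2)
  dd2 <- q_dendrogram(Q[perm, ])
  expect_equal(sort(dd2$hclust$height), sort(dd$hclust$height))
  # leaf annotation with cluster and ROH overlay
  dd3 <- q_dendrogram(Q, labels = c(1, 1, 2), roh_mb = c(10, 20, 0))
  expect_true(any(grepl("s1\\|c1\\|10Mb", dd3$tree$tip.label)))
  expect_error(q_dendrogram(Q[1, , drop = FALSE]), "at least 2")
  expect_error(q_dendrogram(matrix(c(0.5, 0.2), 1, 2)), "at least 2")
})
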