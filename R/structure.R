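# Ancestry inference: LD pruning, Patterson-scaled PCA with projection,
# Gaussian-mixture clustering of leading PCs, binomial-likelihood admixture
# EM with cross-validation, and the ancestry-Q dendrogram.

#' Sliding-window LD pruning
#'
#' Within each window of `window_snps` variants advanced by `step_snps`,
#' pairs with genotype-correlation r-squared above `r2_max` are resolved by
#' removing the lower-MAF member (ties: the later position); passes repeat
#' until no window contains an offending pair.
#'
#' @param G a [genotype_matrix()] with variants sorted by position.
#' @param window_snps,step_snps window size and step in SNPs.
#' @param r2_max maximum tolerated pairwise r-squared.
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(G, window_snps = 200, step_snps = 50, r2_max = 0.4) {
  L <- ncol(G$calls)
  keep <- rep(TRUE, L)
  p <- allele_freq(G)
  maf <- pmin(p, 1 - p)
  repeat {
    changed <- FALSE
    starts <- seq(1L, max(1L, L - 1L), by = step_snps)
    for (s in starts) {
      idx <- which(keep)[which(keep) >= s & which(keep) < s + window_snps]
      if (length(idx) < 2) next
      cc <- suppressWarnings(cor(G$calls[, idx, drop = FALSE],
                                 use = "pairwise.complete.obs"))
      cc[!is.finite(cc)] <- 0
      r2 <- cc^2
      r2[lower.tri(r2, diag = TRUE)] <- 0
      while (TRUE) {
        w <- which(r2 > r2_max, arr.ind = TRUE)
        if (nrow(w) == 0) break
        top <- w[which.max(r2[w]), ]
        a <- idx[top[1]]; b <- idx[top[2]]
        drop <- if (maf[a] < maf[b]) a
                else if (maf[b] < maf[a]) b
                else max(a, b)              # tie -> later position
        keep[drop] <- FALSE
        changed <- TRUE
        di <- which(idx == drop)
        r2[di, ] <- 0; r2[, di] <- 0
      }
      if (s + window_snps > L) break
    }
    if (!changed) break
  }
  G$variants$id[keep]
}

#' Principal component analysis with Patterson scaling
#'
#' Genotypes are centred by `2 * p_hat` and scaled by
#' `sqrt(2 * p_hat * (1 - p_hat))` per site (the drift-variance scaling),
#' monomorphic sites are excluded, and the scores are the left singular
#' vectors scaled by the singular values. The stored frequencies and loadings
#' allow projection of new samples onto the same axes.
#'
#' @param G a [genotype_matrix()] (pruned; missing calls mean-imputed per site
#'   for the decomposition).
#' @param m number of components to retain.
#' @return object of class `pca_result`: `scores` (N x m), `eigenvalues`,
#'   `varfrac` (variance-explained fractions), `loadings`, `p_hat`, `used`
#'   (ids of sites entering the decomposition).
#' @export
pca_patterson <- function(G, m = 10) {
  N <- nrow(G$calls)
  if (N < 2) stop("need at least 2 samples")
  if (m > N) {
    warning("m reduced to the number of samples")
    m <- N
  }
  p <- allele_freq(G)
  use <- is.finite(p) & p > 0 & p < 1
  X <- G$calls[, use, drop = FALSE]
  p <- p[use]
  X <- sweep(X, 2, 2 * p)
  X[is.na(X)] <- 0                       # mean imputation after centring
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(X, nu = m, nv = m)
  scores <- sv$u %*% diag(sv$d[seq_len(m)], m, m)
  rownames(scores) <- G$samples
  colnames(scores) <- paste0("PC", seq_len(m))
  structure(list(scores = scores,
                 eigenvalues = sv$d[seq_len(m)]^2 / (N - 1),
                 varfrac = sv$d[seq_len(m)]^2 / sum(sv$d^2),
                 loadings = sv$v, p_hat = p,
                 used = G$variants$id[use]),
            class = "pca_result")
}

#' Project new samples onto stored principal axes
#'
#' @param pca a `pca_result` from [pca_patterson()].
#' @param G_new a [genotype_matrix()] containing the sites used in the fit.
#' @return matrix of projected scores (rows = new samples).
#' @export
pca_project <- function(pca, G_new) {
  idx <- match(pca$used, G_new$variants$id)
  if (anyNA(idx)) stop("G_new lacks ", sum(is.na(idx)), " sites used in the PCA fit")
  X <- G_new$calls[, idx, drop = FALSE]
  X <- sweep(X, 2, 2 * pca$p_hat)
  X[is.na(X)] <- 0
  X <- sweep(X, 2, sqrt(2 * pca$p_hat * (1 - pca$p_hat)), "/")
  sc <- X %*% pca$loadings
  colnames(sc) <- colnames(pca$scores)
  sc
}

#' Gaussian-mixture clustering of leading principal components
#'
#' EM-fitted Gaussian mixtures over four covariance families spanning the
#' spherical-to-full spectrum (spherical-equal EII, diagonal-varying VVI,
#' full-shared EEE, full-varying VVV); the (K, family) pair with the best BIC
#' is selected. Delegates the fits to `mclust`, whose hierarchical
#' initialization makes the result deterministic for fixed data.
#'
#' @param scores numeric matrix of PC scores.
#' @param n_pc number of leading columns used (default 6).
#' @param K_range candidate component counts.
#' @param seed integer seed (kept for interface stability; the fit itself is
#'   deterministic).
#' @importFrom mclust Mclust mclustBIC
#' @return object of class `cluster_assignment`: `labels` (per sample, 1..K),
#'   `posterior` (rows sum to 1), `K`, `family`, `bic` (full BIC table).
#' @export
gmm_cluster <- function(scores, n_pc = 6, K_range = 1:9, seed = 1) {
  n_pc <- min(n_pc, ncol(scores))
  X <- scores[, seq_len(n_pc), drop = FALSE]
  set.seed(seed)
  fit <- Mclust(X, G = K_range,
                modelNames = c("EII", "VVI", "EEE", "VVV"),
                verbose = FALSE)
  if (is.null(fit)) stop("all mixture fits failed")
  post <- fit$z
  if (is.null(post)) post <- matrix(1, nrow(X), 1)
  structure(list(labels = as.integer(fit$classification),
                 posterior = post, K = fit$G, family = fit$modelName,
                 bic = fit$BIC),
            class = "cluster_assignment")
}

#' Binomial-likelihood admixture model (unsupervised)
#'
#' Maximizes the admixture log-likelihood
#' `sum_{i,l} g_il * log(sum_k q_ik p_kl) + (2 - g_il) * log(sum_k q_ik (1 - p_kl))`
#' by EM; the log-likelihood is non-decreasing at every iteration. Missing
#' genotype entries are skipped per entry. P entries are clamped to
#' `[1e-6, 1 - 1e-6]`; Q rows sum to 1.
#'
#' @param G a [genotype_matrix()].
#' @param K number of ancestral components.
#' @param seed integer seed for the random initialization.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `admixture_model`: `Q` (N x K), `P` (K x L),
#'   `loglik` (trace), `K`, `converged`.
#' @export
admixture_em <- function(G, K, seed = 1, tol = 1e-6, max_iter = 2000) {
  N <- nrow(G$calls); L <- ncol(G$calls)
  if (K < 1) stop("K must be >= 1")
  if (K > N) stop("K cannot exceed the number of samples")
  g <- G$calls
  obs <- !is.na(g)
  gm <- ifelse(obs, g, 0)          # derived-allele counts, missing -> 0 weight
  wm <- ifelse(obs, 2 - g, 0)
  set.seed(seed)
  q <- matrix(rgamma(N * K, 1), N, K); q <- q / rowSums(q)
  phat <- colSums(gm) / pmax(2 * colSums(obs), 1)
  P <- pmin(pmax(matrix(rep(phat, each = K), K, L) +
                 matrix(runif(K * L, -0.05, 0.05), K, L), 1e-6), 1 - 1e-6)
  if (K == 1) {
    P[1, ] <- pmin(pmax(phat, 1e-6), 1 - 1e-6)
    ll <- sum(gm * log(matrix(P, N, L, byrow = TRUE)) +
              wm * log(1 - matrix(P, N, L, byrow = TRUE)))
    return(structure(list(Q = matrix(1, N, 1), P = P, loglik = ll, K = 1L,
                          converged = TRUE), class = "admixture_model"))
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M1 <- q %*% P                          # E[derived freq] per (i, l)
    M0 <- q %*% (1 - P)
    ll <- sum(gm * log(M1) + wm * log(M0))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) / (abs(ll) + 1) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    R1 <- gm / M1
    R0 <- wm / M0
    A <- (R1 %*% t(P)) * q                 # expected derived counts by (i, k)
    B <- (R0 %*% t(1 - P)) * q
    q <- (A + B)
    q <- q / rowSums(q)
    pn <- P * (t(q) %*% R1)                # expected derived counts by (k, l)
    pd <- (1 - P) * (t(q) %*% R0)
    P <- pmin(pmax(pn / (pn + pd), 1e-6), 1 - 1e-6)
  }
  structure(list(Q = q, P = P, loglik = trace, K = as.integer(K),
                 converged = converged), class = "admixture_model")
}

#' @export
print.admixture_model <- function(x, ...) {
  cat("admixture_model: K =", x$K, ",", nrow(x$Q), "samples,",
      ncol(x$P), "sites; loglik =", format(tail(x$loglik, 1)),
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}

#' Cross-validated choice of the number of ancestral components
#'
#' Per fold, a random fraction of genotype entries is masked, the admixture
#' model is fitted on the remainder, and the masked entries are scored by the
#' mean binomial deviance between the observed allele count and its fitted
#' expectation `2 * sum_k q_ik p_kl`. The reported error per K is the mean
#' over folds; the K with the lowest error is the cross-validated choice.
#'
#' @param G a [genotype_matrix()].
#' @param K_range candidate K values.
#' @param folds number of masking folds.
#' @param mask_fraction fraction of observed entries masked per fold (> 0).
#' @param seed integer seed.
#' @param ... passed to [admixture_em()] (`tol`, `max_iter`).
#' @return data.frame with `K` and `cv_error`, plus attribute `best_K`.
#' @export
admixture_cv <- function(G, K_range, folds = 5, mask_fraction = 0.1,
                         seed = 1, ...) {
  if (mask_fraction <= 0) stop("mask_fraction must be > 0")
  set.seed(seed)
  obs_idx <- which(!is.na(G$calls))
  err <- matrix(NA_real_, length(K_range), folds)
  fold_masks <- lapply(seq_len(folds), function(f)
    sample(obs_idx, round(mask_fraction * length(obs_idx))))
  for (f in seq_len(folds)) {
    mask <- fold_masks[[f]]
    Gm <- G
    Gm$calls[mask] <- NA
    truth <- G$calls[mask]
    for (ki in seq_along(K_range)) {
      fit <- admixture_em(Gm, K_range[ki], seed = seed + f, ...)
      mu <- pmin(pmax(fit$Q %*% fit$P, 1e-9), 1 - 1e-9)[mask]
      # binomial deviance per masked entry (2 trials)
      dev <- -2 * (truth * log(mu) + (2 - truth) * log(1 - mu) -
                   ifelse(truth %in% c(0, 2), 0, truth * log(truth / 2) +
                          (2 - truth) * log(1 - truth / 2)))
      err[ki, f] <- mean(dev)
    }
  }
  out <- data.frame(K = K_range, cv_error = rowMeans(err))
  attr(out, "best_K") <- K_range[which.min(out$cv_error)]
  out
}

#' Ancestry-proportion dendrogram
#'
#' Builds the pairwise Euclidean distance matrix between individual ancestry
#' vectors (rows of Q) and agglomerates by average linkage (UPGMA). Leaves
#' can be annotated with a cluster label and a per-sample total-ROH overlay.
#'
#' @param Q `N x K` ancestry matrix, rows summing to 1; row names are sample
#'   ids.
#' @param labels optional per-sample cluster labels for leaf annotation.
#' @param roh_mb optional per-sample total ROH (Mb) for leaf annotation.
#' @param method distance method for [stats::dist()] (default "euclidean").
#' @param linkage linkage for [stats::hclust()] (default "average").
#' @return list with `tree` (an `ape::phylo`), `newick` (string), `hclust`,
#'   and `order` (leaf ordering of sample ids).
#' @export
q_dendrogram <- function(Q, labels = NULL, roh_mb = NULL,
                         method = "euclidean", linkage = "average") {
  Q <- as.matrix(Q)
  if (nrow(Q) < 2) stop("need at least 2 samples")
  if (any(abs(rowSums(Q) - 1) > 1e-6)) stop("rows of Q must sum to 1")
  ids <- rownames(Q)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(Q)))
  leaf <- ids
  if (!is.null(labels)) leaf <- paste0(leaf, "|c", labels)
  if (!is.null(roh_mb)) leaf <- paste0(leaf, "|", round(roh_mb, 1), "Mb")
  d <- dist(Q, method = method)
  hc <- hclust(d, method = linkage)
  hc$labels <- leaf
  tree <- ape::as.phylo(hc)
  list(tree = tree, newick = ape::write.tree(tree), hclust = hc,
       order = ids[hc$order])
}

#' Align the columns of an estimated Q to a reference by best permutation
#'
#' Utility for parameter-recovery checks: component labels of mixture and
#' admixture fits are arbitrary; this searches all column permutations and
#' returns the one minimizing mean absolute error against `Q_ref`.
#'
#' @param Q_est,Q_ref `N x K` matrices.
#' @return list with `Q` (permuted estimate), `perm`, `mae`.
#' @export
align_Q <- function(Q_est, Q_ref) {
  K <- ncol(Q_ref)
  perms <- permutations_of(K)
  best <- NULL; best_mae <- Inf
  for (i in seq_len(nrow(perms))) {
    pm <- perms[i, ]
    mae <- mean(abs(Q_est[, pm, drop = FALSE] - Q_ref))
    if (mae < best_mae) { best_mae <- mae; best <- pm }
  }
  list(Q = Q_est[, best, drop = FALSE], perm = best, mae = best_mae)
}

# all permutations of 1..n (n small)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}
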