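# Two-reference weighted-LD admixture dating: the LD of an admixed target,
# weighted by reference allele-frequency differences, decays with genetic
# distance as exp(-g * d) for a pulse g generations ago.

#' Weighted-LD decay curve for an admixed target
#'
#' Per variant pair (l, m) on the same chromosome with genetic distance in
#' `[dmin_cM, dmax_cM]`, the haplotype-based LD estimate
#' `D_lm = freq(1,1) - p_l * p_m` in the target is weighted by
#' `w_l * w_m` where `w = ref1_freq - ref2_freq`, and averaged within
#' distance bins of `bin_width_cM`. Swapping the two references flips every
#' weight's sign and leaves the products, hence the curve, unchanged.
#'
#' @param H a [haplotype_set()] for the target cluster, whose variant table
#'   carries cM positions.
#' @param ref1_freqs,ref2_freqs reference allele-frequency vectors aligned to
#'   the target's variants.
#' @param bin_width_cM distance-bin width.
#' @param dmin_cM minimum pair distance (excludes background LD).
#' @param dmax_cM maximum pair distance.
#' @return object of class `weighted_ld_curve`: data.frame `curve`
#'   (`bin_cM` midpoints, `value`, `n_pairs`), plus per-chromosome sums for
#'   jackknifing (`chrom_sums`, `chrom_counts`) and the parameters used.
#' @export
weighted_ld_curve <- function(H, ref1_freqs, ref2_freqs, bin_width_cM = 0.1,
                              dmin_cM = 0.5, dmax_cM = 30) {
  vt <- H$variants
  if (anyNA(vt$cM)) stop("variants must carry cM positions")
  L <- nrow(vt)
  if (length(ref1_freqs) != L || length(ref2_freqs) != L)
    stop("reference frequency vectors must align with the target variants")
  w <- ref1_freqs - ref2_freqs
  breaks <- seq(dmin_cM, dmax_cM + bin_width_cM, by = bin_width_cM)
  nb <- length(breaks) - 1L
  chroms <- unique(vt$chrom)
  S <- matrix(0, length(chroms), nb, dimnames = list(chroms, NULL))
  C <- matrix(0, length(chroms), nb, dimnames = list(chroms, NULL))
  for (ci in seq_along(chroms)) {
    idx <- which(vt$chrom == chroms[ci])
    if (length(idx) < 2) stop("fewer than 2 mapped variants on ", chroms[ci])
    hap <- H$H[, idx, drop = FALSE]
    n <- nrow(hap)
    p <- colMeans(hap)
    D <- crossprod(hap) / n - tcrossprod(p)
    WW <- tcrossprod(w[idx])
    dd <- abs(outer(vt$cM[idx], vt$cM[idx], "-"))
    sel <- upper.tri(dd) & dd >= dmin_cM & dd <= dmax_cM
    bin <- findInterval(dd[sel], breaks, rightmost.closed = TRUE)
    v <- (D * WW)[sel]
    sums <- tapply(v, factor(bin, levels = seq_len(nb)), sum)
    sums[is.na(sums)] <- 0
    S[ci, ] <- S[ci, ] + as.numeric(sums)
    C[ci, ] <- C[ci, ] + as.numeric(table(factor(bin, levels = seq_len(nb))))
  }
  tot_n <- colSums(C)
  keep <- tot_n > 0
  curve <- data.frame(bin_cM = (breaks[-length(breaks)] + bin_width_cM / 2)[keep],
                      value = colSums(S)[keep] / tot_n[keep],
                      n_pairs = tot_n[keep])
  structure(list(curve = curve, chrom_sums = S[, keep, drop = FALSE],
                 chrom_counts = C[, keep, drop = FALSE],
                 bin_width_cM = bin_width_cM, dmin_cM = dmin_cM,
                 dmax_cM = dmax_cM),
            class = "weighted_ld_curve")
}

# single- or double-exponential least squares with log-spaced multistart
fit_exp_decay <- function(d, y, n_pulses, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(d))
  df <- data.frame(d = d, y = y)
  g_grid <- exp(seq(log(1), log(200), length.out = 8))
  best <- NULL
  for (g0 in g_grid) {
    st <- if (n_pulses == 1)
      list(a = max(y[1], 1e-6), g = g0, c = 0)
    else
      list(a1 = max(y[1] / 2, 1e-6), g1 = max(g0 * 3, g0 + 1),
           a2 = max(y[1] / 2, 1e-6), g2 = g0, c = 0)
    form <- if (n_pulses == 1) y ~ a * exp(-g * d) + c
            else y ~ a1 * exp(-g1 * d) + a2 * exp(-g2 * d) + c
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = st, weights = weights,
                        lower = if (n_pulses == 1) c(-Inf, 1e-3, -Inf)
                                else c(-Inf, 1e-3, -Inf, 1e-3, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(weights * resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(NULL)
  cf <- coef(best$fit)
  if (n_pulses == 2 && cf["g1"] < cf["g2"]) {  # enforce g1 > g2 by relabel
    cf <- cf[c("a2", "g2", "a1", "g1", "c")]
    names(cf) <- c("a1", "g1", "a2", "g2", "c")
  }
  list(coef = cf, rss = best$rss, n = length(d),
       n_par = if (n_pulses == 1) 3L else 5L)
}

#' Fit admixture-pulse models to a weighted-LD curve
#'
#' Nonlinear least squares of `a * exp(-g * d) + c` (distances in Morgans, so
#' `g` is directly the number of generations since the pulse) with a
#' log-spaced multistart over decay rates; optionally a two-pulse model
#' `a1 * exp(-g1 * d) + a2 * exp(-g2 * d) + c` with `g1 > g2`, accepted over
#' the one-pulse fit only when an F-test on the residual variance passes at
#' `alpha`. With at least 2 chromosomes, a leave-one-chromosome-out jackknife
#' SE of `g` is computed.
#'
#' @param wld a `weighted_ld_curve` (or a plain data.frame with `bin_cM`,
#'   `value` columns for a single-block fit).
#' @param n_pulses 1 or 2.
#' @param alpha F-test level for accepting the two-pulse model.
#' @return object of class `pulse_fit`: `coef` (a, g, c or a1, g1, a2, g2,
#'   c), `n_pulses` (selected), `g` (decay rates, generations), `se_g`
#'   (jackknife SE, NA without >= 2 chromosomes), `rss`, `f_test` (when a
#'   two-pulse fit was attempted), `converged`.
#' @export
fit_pulses <- function(wld, n_pulses = 1, alpha = 0.05) {
  stopifnot(n_pulses %in% 1:2)
  curve <- if (inherits(wld, "weighted_ld_curve")) wld$curve else wld
  if (nrow(curve) < 5) stop("need at least 5 usable bins")
  d <- curve$bin_cM / 100
  y <- curve$value
  wts <- if ("n_pairs" %in% names(curve)) curve$n_pairs else NULL
  f1 <- fit_exp_decay(d, y, 1, weights = wts)
  if (is.null(f1))
    return(structure(list(converged = FALSE,
                          diagnostics = "one-pulse fit failed at every start"),
                     class = "pulse_fit"))
  sel <- f1; chosen <- 1L; ftest <- NULL
  if (n_pulses == 2) {
    f2 <- fit_exp_decay(d, y, 2, weights = wts)
    if (!is.null(f2)) {
      df2 <- f2$n - f2$n_par
      Fst <- ((f1$rss - f2$rss) / 2) / (f2$rss / df2)
      pF <- pf(Fst, 2, df2, lower.tail = FALSE)
      ftest <- list(F = Fst, df = c(2, df2), p = pF)
      if (is.finite(pF) && pF < alpha) { sel <- f2; chosen <- 2L }
    }
  }
  g_hat <- if (chosen == 1) unname(sel$coef["g"])
           else unname(sel$coef[c("g1", "g2")])
  se_g <- rep(NA_real_, length(g_hat))
  if (inherits(wld, "weighted_ld_curve") && nrow(wld$chrom_sums) >= 2) {
    m <- nrow(wld$chrom_sums)
    jg <- matrix(NA_real_, m, length(g_hat))
    for (ci in seq_len(m)) {
      s <- colSums(wld$chrom_sums[-ci, , drop = FALSE])
      n <- colSums(wld$chrom_counts[-ci, , drop = FALSE])
      ok <- n > 0
      fj <- fit_exp_decay(curve$bin_cM[ok] / 100, s[ok] / n[ok], chosen,
                           weights = n[ok])
      if (!is.null(fj))
        jg[ci, ] <- if (chosen == 1) fj$coef["g"] else fj$coef[c("g1", "g2")]
    }
    ok <- stats::complete.cases(jg)
    if (sum(ok) >= 2) {
      m_ok <- sum(ok)
      se_g <- sqrt((m_ok - 1) / m_ok *
                   colSums(sweep(jg[ok, , drop = FALSE], 2,
                                 colMeans(jg[ok, , drop = FALSE]))^2))
    }
  }
  structure(list(coef = sel$coef, n_pulses = chosen, g = g_hat, se_g = se_g,
                 rss = sel$rss, f_test = ftest, converged = TRUE),
            class = "pulse_fit")
}

#' @export
print.pulse_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("pulse_fit: FAILED -", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat("pulse_fit:", x$n_pulses, "pulse(s); g =",
      paste(round(x$g, 2), collapse = ", "),
      "generations (SE", paste(round(x$se_g, 2), collapse = ", "), ")\n")
  invisible(x)
}

#' Convert generations before present to a calendar year
#'
#' `year = ref_year - g * gen_time_years`, rounded to the nearest integer.
#'
#' @param g generations before the reference year (>= 0).
#' @param gen_time_years generation time in years (default 30).
#' @param ref_year reference calendar year (default 2000).
#' @return integer calendar year (CE).
#' @export
generations_to_year <- function(g, gen_time_years = 30, ref_year = 2000) {
  if (any(g < 0)) stop("g must be >= 0")
  round(ref_year - g * gen_time_years)
}
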