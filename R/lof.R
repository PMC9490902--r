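# Putative loss-of-function variation: curation, per-cluster frequency
# differentiation with Bonferroni control, CADD-binned deleteriousness ratio,
# genotype-by-cluster contingency tests.

#' Curate the putative loss-of-function variant set
#'
#' Union of the curated-list members and the stop-gain-consequence variants,
#' restricted to variants present in the genotype data when `present_ids` is
#' supplied; duplicates collapsed.
#'
#' @param annotations an annotation table (`id`, `consequence`, `curated`).
#' @param present_ids optional character vector of genotyped variant ids.
#' @return character vector of LOF variant ids.
#' @export
curate_lof <- function(annotations, present_ids = NULL) {
  ids <- annotations$id[annotations$curated |
                        annotations$consequence == "stop_gained"]
  ids <- unique(ids)
  if (!is.null(present_ids)) ids <- ids[ids %in% present_ids]
  ids
}

# allelic chi-square (1 df, no continuity correction) for a 2x2 allele table
allelic_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  x2 <- ifelse(den > 0, num / den, 0)
  list(chisq = x2, p = pchisq(x2, 1, lower.tail = FALSE))
}

#' Per-cluster allele-frequency differentiation of LOF variants
#'
#' For each LOF variant and each cluster, a 2x2 allele-count table (cluster
#' vs all other clusters; two alleles per homozygote, one per heterozygote,
#' missing skipped) is tested by the 1-df allelic chi-square without
#' continuity correction. The Bonferroni family is `n_variants * n_clusters`
#' tests by default (configurable to variants only).
#'
#' @param G a [genotype_matrix()].
#' @param clusters per-sample cluster labels (in `G$samples` order).
#' @param lof_set character vector of LOF variant ids (see [curate_lof()]).
#' @param alpha family-wise error target.
#' @param annotations optional annotation table to attach consequence/score
#'   columns.
#' @param family Bonferroni family: `"variants_by_clusters"` (default) or
#'   `"variants"`.
#' @return data.frame of class `lof_records`, one row per variant x cluster:
#'   `id`, `cluster`, `af_cluster`, `af_rest`, `chisq`, `p`, `significant`,
#'   `monomorphic`, plus `consequence`/`score`/`curated` when annotations are
#'   given. Attribute `bonferroni` records the threshold used.
#' @export
cluster_differentiation <- function(G, clusters, lof_set, alpha = 0.05,
                                    annotations = NULL,
                                    family = c("variants_by_clusters",
                                               "variants")) {
  family <- match.arg(family)
  cls <- sort(unique(clusters))
  if (length(cls) < 2) stop("need at least 2 clusters")
  idx <- match(lof_set, G$variants$id)
  if (anyNA(idx)) stop("LOF set contains ungenotyped variants")
  g <- G$calls[, idx, drop = FALSE]
  # per-cluster alt and total allele counts (missing skipped)
  alt <- rowsum(ifelse(is.na(g), 0, g), clusters)
  tot <- rowsum(2 * (!is.na(g)) + 0, clusters)
  alt <- alt[cls, , drop = FALSE]; tot <- tot[cls, , drop = FALSE]
  n_tests <- length(lof_set) *
    if (family == "variants_by_clusters") length(cls) else 1L
  thr <- alpha / n_tests
  rows <- list()
  mono <- colSums(alt) == 0 | colSums(alt) == colSums(tot)
  for (ci in seq_along(cls)) {
    a <- alt[ci, ]; ta <- tot[ci, ]
    c_ <- colSums(alt) - a; tc <- colSums(tot) - ta
    ts <- allelic_chisq(a, ta - a, c_, tc - c_)
    p <- ifelse(mono, 1, ts$p)
    rows[[ci]] <- data.frame(id = lof_set, cluster = cls[ci],
                             af_cluster = ifelse(ta > 0, a / ta, NA_real_),
                             af_rest = ifelse(tc > 0, c_ / tc, NA_real_),
                             chisq = ifelse(mono, 0, ts$chisq), p = p,
                             significant = p < thr, monomorphic = mono,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(annotations)) {
    m <- match(out$id, annotations$id)
    out$consequence <- annotations$consequence[m]
    out$score <- annotations$score[m]
    out$curated <- annotations$curated[m]
  }
  attr(out, "bonferroni") <- thr
  attr(out, "n_tests") <- n_tests
  class(out) <- c("lof_records", "data.frame")
  out
}

#' Top differentiated LOF variants per cluster
#'
#' @param records `lof_records` from [cluster_differentiation()].
#' @param n_top number of lowest p-values reported per cluster.
#' @return the subset of records, ordered by cluster then p.
#' @export
top_differentiated <- function(records, n_top = 5) {
  parts <- lapply(split(seq_len(nrow(records)), records$cluster), function(i) {
    i[order(records$p[i])][seq_len(min(n_top, length(i)))]
  })
  out <- records[unlist(parts), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deleteriousness ratio per cluster
#'
#' Within each cluster, the median allele frequency of high-deleteriousness
#' LOF variants (score >= `high_min`) divided by the median allele frequency
#' of low-deleteriousness ones (score <= `low_max`); variants with scores in
#' between are excluded, so the ratio is invariant to them. A low ratio
#' indicates purifying selection outpacing drift (large effective population
#' size); a high ratio the reverse.
#'
#' @param records `lof_records` carrying a `score` column (pass `annotations`
#'   to [cluster_differentiation()], or merge manually).
#' @param high_min,low_max score-bin edges (CADD-like scale).
#' @return data.frame per cluster: `cluster`, `median_af_high`,
#'   `median_af_low`, `ratio`, `n_high`, `n_low`, `flag` ("" when well
#'   defined; "empty_bin" or "zero_low_median" otherwise; an empty bin gives
#'   `NA`, a zero low median gives `Inf` - neither is silently dropped).
#' @export
deleteriousness_ratio <- function(records, high_min = 25, low_max = 5) {
  if (!"score" %in% names(records)) stop("records lack a deleteriousness score")
  cls <- sort(unique(records$cluster))
  out <- lapply(cls, function(cl) {
    r <- records[records$cluster == cl, ]
    hi <- r$af_cluster[r$score >= high_min]
    lo <- r$af_cluster[r$score <= low_max]
    mh <- if (length(hi)) median(hi, na.rm = TRUE) else NA_real_
    ml <- if (length(lo)) median(lo, na.rm = TRUE) else NA_real_
    flag <- if (!length(hi) || !length(lo)) "empty_bin"
            else if (isTRUE(ml == 0)) "zero_low_median" else ""
    ratio <- if (flag == "empty_bin") NA_real_
             else if (flag == "zero_low_median") Inf else mh / ml
    data.frame(cluster = cl, median_af_high = mh, median_af_low = ml,
               ratio = ratio, n_high = length(hi), n_low = length(lo),
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genotype-by-cluster contingency table and chi-square test
#'
#' 3 x m table of genotype counts (0/1/2) by cluster, tested by chi-square
#' with `(rows - 1)(cols - 1)` degrees of freedom; a warning notes expected
#' cells below 5.
#'
#' @param variant variant id.
#' @param G a [genotype_matrix()].
#' @param clusters per-sample cluster labels.
#' @return list with `table`, `chisq`, `df`, `p`, `expected_warning`.
#' @export
genotype_by_cluster <- function(variant, G, clusters) {
  j <- match(variant, G$variants$id)
  if (is.na(j)) stop("variant not genotyped: ", variant)
  g <- G$calls[, j]
  ok <- !is.na(g)
  tab <- table(factor(g[ok], levels = 0:2), clusters[ok])
  if (ncol(tab) < 2) stop("variant genotyped in fewer than 2 clusters")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  exp_tab <- outer(rs, cs) / n
  keep <- rs > 0
  x2 <- sum((tab[keep, ] - exp_tab[keep, ])^2 / exp_tab[keep, ])
  df <- (sum(keep) - 1) * (ncol(tab) - 1)
  warn <- any(exp_tab[keep, ] < 5)
  if (warn) warning("some expected cell counts are below 5")
  list(table = tab, chisq = x2, df = df,
       p = if (df > 0) pchisq(x2, df, lower.tail = FALSE) else 1,
       expected_warning = warn)
}
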