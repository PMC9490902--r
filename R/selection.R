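# nSL selection scan: pairwise haplotype identity-tract lengths in SNP
# units, frequency-bin standardization, candidate calling and shared/private
# partitioning across ancestry clusters.

#' nSL selection scan over a phased haplotype set
#'
#' At each focal SNP `x`, for every haplotype pair (i, j) in the
#' derived-carrier class, `L_ij(x)` counts the SNPs of the maximal contiguous
#' interval containing `x` over which i and j carry identical alleles at
#' every SNP (so `L >= 1`; intervals truncate at chromosome ends without
#' penalty). `SL_D(x)` is the mean of `L_ij(x)` over derived pairs, `SL_A(x)`
#' the mean over ancestral pairs, and `nsl_raw = ln(SL_A / SL_D)` (negative
#' values mark unusually long derived haplotypes). Scores are undefined and
#' skipped where either carrier class has fewer than 2 haplotypes or where
#' the minor-allele frequency is below `maf_min`.
#'
#' @param H a [haplotype_set()] (phased, derived orientation).
#' @param maf_min minor-allele-frequency floor.
#' @return data.frame of class `nsl_scores`: `id`, `chrom`, `daf`, `sl_a`,
#'   `sl_d`, `nsl_raw` (only defined scores are returned).
#' @export
nsl_scan <- function(H, maf_min = 0.05) {
  if (!inherits(H, "haplotype_set")) stop("nsl_scan needs phased haplotypes")
  vt <- H$variants
  out <- list()
  for (ch in unique(vt$chrom)) {
    idx <- which(vt$chrom == ch)
    hap <- H$H[, idx, drop = FALSE] > 0
    n <- nrow(hap)
    L <- length(idx)
    sumD <- sumA <- cntD <- cntA <- numeric(L)
    xs <- seq_len(L)
    for (i in seq_len(n - 1)) {
      hi <- hap[i, ]
      for (j in (i + 1):n) {
        hj <- hap[j, ]
        mm <- which(hi != hj)
        if (length(mm)) {
          k <- findInterval(xs, mm)
          left <- c(0L, mm)[k + 1L]
          right <- c(mm, L + 1L)[k + 1L]
          # at a mismatch position findInterval lands on the mismatch itself;
          # such positions belong to mixed pairs and are never accumulated
          tl <- right - left - 1
        } else tl <- rep(L, L)
        bd <- hi & hj
        ba <- !hi & !hj
        sumD[bd] <- sumD[bd] + tl[bd]
        cntD[bd] <- cntD[bd] + 1
        sumA[ba] <- sumA[ba] + tl[ba]
        cntA[ba] <- cntA[ba] + 1
      }
    }
    daf <- colMeans(hap)
    ok <- cntD > 0 & cntA > 0 & pmin(daf, 1 - daf) >= maf_min
    if (any(ok))
      out[[ch]] <- data.frame(id = vt$id[idx][ok], chrom = ch, daf = daf[ok],
                              sl_a = (sumA / cntA)[ok],
                              sl_d = (sumD / cntD)[ok],
                              nsl_raw = log((sumA / cntA)[ok] /
                                            (sumD / cntD)[ok]),
                              stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(0), chrom = character(0), daf = numeric(0),
               sl_a = numeric(0), sl_d = numeric(0), nsl_raw = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("nsl_scores", "data.frame")
  res
}

#' Standardize nSL scores within derived-allele-frequency bins
#'
#' Variants are binned by derived-allele frequency into `n_bins` equal-width
#' bins over \[0, 1\]; bins holding fewer than 2 variants are merged with
#' their nearest lower non-empty neighbour (or the next one up at the
#' bottom). Within each merged bin `nsl_std = (nsl_raw - bin mean)/bin SD`.
#' Zero-variance bins are flagged (`flagged = TRUE`, `nsl_std = NA`) rather
#' than dropped.
#'
#' @param scores an `nsl_scores` data.frame from [nsl_scan()].
#' @param n_bins number of frequency bins.
#' @return the scores with `bin`, `nsl_std` and `flagged` columns added.
#' @export
normalize_nsl <- function(scores, n_bins = 50) {
  if (nrow(scores) < n_bins)
    stop("need at least n_bins scored variants")
  b <- pmin(pmax(ceiling(scores$daf * n_bins), 1L), n_bins)
  # merge sparse bins downward into the nearest occupied neighbour
  repeat {
    tab <- table(factor(b, levels = seq_len(n_bins)))
    small <- which(tab > 0 & tab < 2)
    if (!length(small)) break
    s <- small[1]
    occupied <- setdiff(which(tab > 0), s)
    target <- if (any(occupied < s)) max(occupied[occupied < s])
              else min(occupied[occupied > s])
    b[b == s] <- target
  }
  mu <- tapply(scores$nsl_raw, b, mean)
  sg <- tapply(scores$nsl_raw, b, sd)
  key <- as.character(b)
  scores$bin <- b
  scores$nsl_std <- as.numeric((scores$nsl_raw - mu[key]) / sg[key])
  scores$flagged <- !is.finite(scores$nsl_std)
  scores$nsl_std[scores$flagged] <- NA_real_
  scores
}

#' Call selection candidates in one cluster
#'
#' Candidates must satisfy all of: `|nsl_std| >= abs_min`, `|nsl_std|` at or
#' above the given percentile of the cluster's own |score| distribution, and
#' presence of a trait annotation (the conservative already-associated
#' filter).
#'
#' @param scores normalized scores ([normalize_nsl()]).
#' @param annotations an annotation table with `id` and `trait` columns.
#' @param abs_min absolute standardized-score floor.
#' @param percentile genomic-distribution percentile (99 by default; 99.9 is
#'   the stricter alternative).
#' @param cluster label recorded on the result.
#' @return object of class `candidate_set`: list with `cluster`, `ids`,
#'   `traits` (named by id), `threshold`.
#' @export
call_candidates <- function(scores, annotations, abs_min = 2,
                            percentile = 99, cluster = "cluster") {
  a <- abs(scores$nsl_std)
  thr <- quantile(a, percentile / 100, na.rm = TRUE, names = FALSE, type = 7)
  trait_map <- annotations$trait[annotations$trait != ""]
  names(trait_map) <- annotations$id[annotations$trait != ""]
  if (!length(trait_map)) {
    warning("empty annotation table; no candidates can be called")
    return(structure(list(cluster = cluster, ids = character(0),
                          traits = character(0), threshold = thr),
                     class = "candidate_set"))
  }
  pass <- !is.na(a) & a >= abs_min & a >= thr & scores$id %in% names(trait_map)
  ids <- scores$id[pass]
  structure(list(cluster = cluster, ids = ids,
                 traits = trait_map[ids], threshold = thr),
            class = "candidate_set")
}

#' Partition candidate sets into shared and private signals
#'
#' Assigns every candidate variant to exactly one cell of the
#' inclusion/exclusion lattice over clusters, tabulates the cells (Venn
#' counts), extracts the shared-by-all table (optionally with per-cluster
#' standardized scores), and groups private candidates by trait label.
#'
#' @param sets list of `candidate_set`s (length >= 2), one per cluster.
#' @param score_tables optional named list of normalized score tables (one
#'   per cluster) to fill per-cluster `nsl_std` columns in the shared table.
#' @return list with `venn` (data.frame: cell, count), `shared_all`
#'   (data.frame: id, trait, one nsl_std column per cluster), `private`
#'   (per-cluster list of trait-grouped id lists), `n_union`.
#' @export
shared_private_partition <- function(sets, score_tables = NULL) {
  if (length(sets) < 2) stop("need candidate sets for at least 2 clusters")
  cl <- vapply(sets, function(s) s$cluster, "")
  ids <- sort(unique(unlist(lapply(sets, function(s) s$ids))))
  memb <- vapply(sets, function(s) ids %in% s$ids, logical(length(ids)))
  memb <- matrix(memb, nrow = length(ids), dimnames = list(ids, cl))
  cell <- apply(memb, 1, function(r) paste(cl[r], collapse = "&"))
  venn <- as.data.frame(table(cell), stringsAsFactors = FALSE)
  names(venn) <- c("cell", "count")
  shared_ids <- ids[rowSums(memb) == length(sets)]
  traits <- unlist(lapply(sets, function(s) s$traits))
  traits <- traits[!duplicated(names(traits))]
  shared_all <- data.frame(id = shared_ids,
                           trait = unname(traits[shared_ids]),
                           stringsAsFactors = FALSE)
  if (!is.null(score_tables)) for (k in seq_along(sets)) {
    st <- score_tables[[k]]
    shared_all[[paste0("nsl_std_", cl[k])]] <-
      st$nsl_std[match(shared_ids, st$id)]
  }
  private <- lapply(seq_along(sets), function(k) {
    pids <- ids[memb[, k] & rowSums(memb) == 1]
    split(pids, unname(traits[pids]))
  })
  names(private) <- cl
  list(venn = venn, shared_all = shared_all, private = private,
       n_union = length(ids))
}
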