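#' admixkit: structure, homozygosity and functional variation in admixed cohorts
#'
#' End-to-end, fully simulatable analysis of admixed, partly consanguineous
#' cohorts: ground-truth cohort simulation, genotype QC, ancestry inference
#' (PCA, Gaussian-mixture clustering, admixture EM), run-of-homozygosity
#' detection, nSL selection scans, loss-of-function frequency differentiation
#' and weighted-LD admixture dating.
#'
#' @importFrom stats approx cor dist hclust quantile rbinom runif rnorm rbeta
#'   rgamma rpois rexp sd var median pchisq setNames optim nls coef resid
#'   pf cutree ks.test rmultinom
#' @importFrom utils read.delim write.table packageVersion head tail
#' @keywords internal
"_PACKAGE"

#' Construct a variant table
#'
#' A variant table is the marker-coordinate backbone shared by every container
#' in the package: one row per biallelic variant with chromosome, 1-based bp
#' position, identifier, ref/alt alleles and (optionally) a genetic-map
#' position in cM. Positions must be strictly increasing within chromosome and
#' cM non-decreasing.
#'
#' @param chrom chromosome labels (coerced to character).
#' @param pos 1-based bp positions, strictly increasing within chromosome.
#' @param id variant identifiers; defaults to `chrom:pos`.
#' @param ref,alt alleles; allele "alt" is treated as derived throughout.
#' @param cM genetic positions in centimorgans, or `NA` to be interpolated
#'   later from a genetic map (see [interpolate_cM()]).
#' @return a `data.frame` of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, id = NULL, ref = "A", alt = "G", cM = NA_real_) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  n <- length(pos)
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  vt <- data.frame(chrom = chrom, pos = pos, id = as.character(id),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   cM = rep_len(as.numeric(cM), n),
                   stringsAsFactors = FALSE)
  for (ch in unique(vt$chrom)) {
    p <- vt$pos[vt$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
    g <- vt$cM[vt$chrom == ch]
    if (!anyNA(g) && any(diff(g) < 0)) stop("cM must be non-decreasing within chromosome ", ch)
  }
  class(vt) <- c("variant_table", "data.frame")
  vt
}

#' Construct a genotype matrix
#'
#' @param calls integer matrix, samples in rows and variants in columns,
#'   values in `{0, 1, 2}` (count of the alt/derived allele) with `NA` for
#'   missing calls. Row names are sample ids.
#' @param variants a [variant_table()] with one row per column of `calls`.
#' @param phased logical; `TRUE` when the calls derive from phased haplotypes.
#' @return an object of class `genotype_matrix` with fields `calls`,
#'   `variants`, `samples`, `phased`.
#' @export
genotype_matrix <- function(calls, variants, phased = FALSE) {
  calls <- as.matrix(calls)
  if (ncol(calls) != nrow(variants))
    stop("calls has ", ncol(calls), " columns but variants has ", nrow(variants), " rows")
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  if (is.null(rownames(calls))) rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  colnames(calls) <- variants$id
  structure(list(calls = calls, variants = variants,
                 samples = rownames(calls), phased = isTRUE(phased)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "variants",
      if (x$phased) "(phased)" else "(unphased)", "\n")
  cat("  missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Construct a phased haplotype set
#'
#' Haplotypes are stored as a `2N x L` binary matrix in derived-allele
#' orientation (1 = derived); rows `2i-1` and `2i` are the two haplotypes of
#' sample `i`.
#'
#' @param H binary matrix (`2N x L`), values 0/1.
#' @param samples character vector of N sample ids.
#' @param variants a [variant_table()].
#' @return an object of class `haplotype_set`.
#' @export
haplotype_set <- function(H, samples, variants) {
  H <- as.matrix(H)
  if (nrow(H) != 2L * length(samples)) stop("H must have 2 rows per sample")
  if (ncol(H) != nrow(variants)) stop("H/variants dimension mismatch")
  if (!all(H %in% 0:1)) stop("haplotype alleles must be 0/1")
  rownames(H) <- paste0(rep(samples, each = 2L), "_", c(1L, 2L))
  colnames(H) <- variants$id
  structure(list(H = H, samples = samples, variants = variants),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$H), "haplotypes (", length(x$samples),
      "samples ) x", ncol(x$H), "variants\n")
  invisible(x)
}

#' Collapse a haplotype set to diploid genotypes
#'
#' @param hs a [haplotype_set()].
#' @return a phased [genotype_matrix()]; each genotype is the sum of the two
#'   haplotype alleles.
#' @export
haplotypes_to_genotypes <- function(hs) {
  n <- length(hs$samples)
  odd <- seq(1L, 2L * n, by = 2L)
  calls <- hs$H[odd, , drop = FALSE] + hs$H[odd + 1L, , drop = FALSE]
  rownames(calls) <- hs$samples
  genotype_matrix(calls, hs$variants, phased = TRUE)
}

#' Subset a genotype matrix by samples and/or variants
#'
#' @param G a [genotype_matrix()].
#' @param samples sample ids or logical/integer index; `NULL` keeps all.
#' @param variants variant ids or logical/integer index; `NULL` keeps all.
#' @return the subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(G, samples = NULL, variants = NULL) {
  calls <- G$calls
  vt <- G$variants
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(calls))
    calls <- calls[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, vt$id)
    calls <- calls[, variants, drop = FALSE]
    vt <- vt[variants, , drop = FALSE]
    class(vt) <- c("variant_table", "data.frame")
  }
  genotype_matrix(calls, vt, phased = G$phased)
}

#' Alt-allele frequencies of a genotype matrix
#'
#' @param G a [genotype_matrix()].
#' @return numeric vector of per-variant alt-allele frequencies over
#'   non-missing calls (`NaN` where every call is missing).
#' @export
allele_freq <- function(G) {
  colSums(G$calls, na.rm = TRUE) / (2 * colSums(!is.na(G$calls)))
}
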