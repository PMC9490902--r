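# On-disk formats: VCF v4.2 genotypes, 4-column genetic maps, annotation and
# result TSVs, JSON run reports. Coordinates on disk are 1-based inclusive bp.

#' Read a VCF into a genotype matrix (and haplotypes when fully phased)
#'
#' Only biallelic SNP records are kept; multiallelic or indel records are
#' skipped with a reported count. Missing GT (`./.` or `.|.`) becomes `NA`.
#' Phased haplotypes are returned iff every non-missing GT separator is `|`.
#'
#' @param path path to a VCF (plain text or gzip).
#' @return list with `genotypes` ([genotype_matrix()]), `haplotypes`
#'   ([haplotype_set()] or `NULL`), and `n_skipped` (non-biallelic-SNP
#'   records dropped).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!"GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !grepl("GT", v@gt[1, "FORMAT"]))
    stop("VCF has no GT FORMAT field")
  keep <- vcfR::is.biallelic(v) &
    nchar(v@fix[, "REF"]) == 1 & nchar(v@fix[, "ALT"]) == 1
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped, " non-biallelic-SNP record(s)")
  v <- v[keep, ]
  fix <- v@fix
  vt <- variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                      id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                  paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                  fix[, "ID"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  if (any(!is.na(gt) & !sep %in% c("|", "/")))
    stop("inconsistent ploidy or malformed GT at variant ",
         which(!is.na(gt) & !sep %in% c("|", "/"))[1])
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  calls <- matrix(as.integer(a1) + as.integer(a2), nrow = nrow(gt),
                  dimnames = dimnames(gt))
  phased <- all(sep[!is.na(gt)] == "|") && !anyNA(calls)
  G <- genotype_matrix(t(calls), vt, phased = phased)
  hs <- NULL
  if (phased) {
    n <- ncol(gt)
    H <- matrix(0L, 2L * n, nrow(gt))
    H[seq(1, 2 * n, 2), ] <- t(matrix(as.integer(a1), nrow(gt)))
    H[seq(2, 2 * n, 2), ] <- t(matrix(as.integer(a2), nrow(gt)))
    hs <- haplotype_set(H, colnames(gt), vt)
  }
  list(genotypes = G, haplotypes = hs, n_skipped = n_skipped)
}

#' Write genotypes (or phased haplotypes) as VCF v4.2
#'
#' @param x a [genotype_matrix()] or [haplotype_set()]. Haplotype sets are
#'   written phased (`|` separator); unphased genotype matrices use `/`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "haplotype_set")) {
    vt <- x$variants
    n <- length(x$samples)
    odd <- seq(1L, 2L * n, by = 2L)
    gt <- matrix(paste0(t(x$H[odd, , drop = FALSE]), "|",
                        t(x$H[odd + 1L, , drop = FALSE])),
                 nrow = ncol(x$H))
    samples <- x$samples
  } else {
    vt <- x$variants
    map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", ncol(x$calls), nrow(x$calls))
    ok <- !is.na(t(x$calls))
    gt[ok] <- map[as.character(t(x$calls)[ok])]
    samples <- x$samples
  }
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=admixkit_", as.character(packageVersion("admixkit"))),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- cbind(vt$chrom, vt$pos, vt$id, vt$ref, vt$alt, ".", ".", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(body, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column genetic map
#'
#' Tab-separated columns `chrom, id, cM, bp`, sorted by bp within chromosome
#' with non-decreasing cM (a PLINK .map layout with cM filled in).
#'
#' @param path path to the map file.
#' @return `data.frame` of class `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  m <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(m) != 4) stop("genetic map must have 4 columns (chrom, id, cM, bp)")
  names(m) <- c("chrom", "id", "cM", "bp")
  m$chrom <- as.character(m$chrom)
  for (ch in unique(m$chrom)) {
    s <- m[m$chrom == ch, ]
    if (is.unsorted(s$bp)) stop("map not sorted by position on ", ch)
    if (any(diff(s$cM) < 0)) stop("decreasing cM on ", ch)
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Write a genetic map in the 4-column layout
#' @param map a `genetic_map` (or equivalent data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  write.table(map[, c("chrom", "id", "cM", "bp")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interpolate variant cM positions from a genetic map
#'
#' Linear interpolation between flanking map points; positions outside the
#' map are clamped to the end values. With `map = NULL` a constant
#' 1 cM/Mb rate is used and a warning is raised.
#'
#' @param variants a [variant_table()].
#' @param map a `genetic_map` from [read_genetic_map()], or `NULL`.
#' @return the variant table with `cM` filled in.
#' @export
interpolate_cM <- function(variants, map) {
  if (is.null(map)) {
    warning("no genetic map supplied; assuming a constant 1 cM/Mb")
    variants$cM <- variants$pos * 1e-6
    return(variants)
  }
  for (ch in unique(variants$chrom)) {
    i <- variants$chrom == ch
    s <- map[map$chrom == ch, ]
    if (nrow(s) == 0) stop("chromosome ", ch, " absent from genetic map")
    if (nrow(s) == 1) {
      variants$cM[i] <- s$cM
    } else {
      variants$cM[i] <- approx(s$bp, s$cM, xout = variants$pos[i],
                               rule = 2, ties = "ordered")$y
    }
  }
  variants
}

#' Read a variant annotation table
#'
#' Tab-separated with a header; mandatory columns `id`, `consequence`,
#' `score`; a `curated` logical and a `trait` column are normalized when
#' present (missing -> `FALSE` / `""`). Unknown extra columns are preserved.
#'
#' @param path path to the annotation TSV.
#' @return `data.frame` of class `annotation_table`.
#' @export
read_annotations <- function(path) {
  a <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("id", "consequence", "score"))
    if (!col %in% names(a)) stop("annotation table lacks mandatory column: ", col)
  if (!"curated" %in% names(a)) a$curated <- FALSE
  a$curated <- as.logical(a$curated)
  if (!"trait" %in% names(a)) a$trait <- ""
  a$trait[is.na(a$trait)] <- ""
  class(a) <- c("annotation_table", "data.frame")
  a
}

#' Write an annotation table
#' @param ann annotation table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables plus a JSON run report
#'
#' Each element of `tables` is written as `<name>.tsv` under `dir`; the run
#' report `run_report.json` records the configuration of every stage, seeds,
#' and the package version, so a run is reconstructible from its output
#' directory alone.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @param config named list of per-stage parameter sets (arbitrary nesting).
#' @param seeds named list or vector of seeds used.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(tables, dir, config = list(), seeds = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  report <- list(package = "admixkit",
                 version = as.character(packageVersion("admixkit")),
                 date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 config = config, seeds = seeds,
                 tables = names(tables))
  f <- file.path(dir, "run_report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, f))
}
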