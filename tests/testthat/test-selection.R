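test_that("nSL on a hand-built panel matches the hand computation", {
  # 4 haplotypes x 5 SNPs; focal SNP 3: haplotypes 3,4 carry the derived
  # allele and agree on SNPs 1-4 (L = 4); haplotypes 1,2 are ancestral and
  # agree on SNPs 3-5 only (L = 3) -> nsl_raw = ln(3/4)
  H <- rbind(c(0, 1, 0, 1, 0),
             c(1, 0, 0, 1, 0),
             c(0, 0, 1, 1, 1),
             c(0, 0, 1, 1, 0))
  hs <- hapset_from_matrix(H)
  sc <- nsl_scan(hs, maf_min = 0)
  r3 <- sc[sc$id == hs$variants$id[3], ]
  expect_equal(r3$sl_a, 3)
  expect_equal(r3$sl_d, 4)
  expect_equal(r3$nsl_raw, log(3 / 4))
  # identical haplotypes outside a lone focal difference: SL_A = SL_D = L
  H2 <- rbind(c(0, 0, 1, 0, 1), c(0, 0, 1, 0, 1),
              c(0, 0, 0, 0, 1), c(0, 0, 0, 0, 1))
  sc2 <- nsl_scan(hapset_from_matrix(H2), maf_min = 0)
  r <- sc2[sc2$id == "chr1:3000", ]
  expect_equal(r$nsl_raw, 0)
  expect_equal(r$sl_a, 5)
  expect_error(nsl_scan(matrix(0, 2, 2)), "phased")
})

test_that("nSL equals the brute-force pairwise oracle on random panels", {
  for (s in 1:12) {
    set.seed(300 + s)
    n <- sample(seq(8, 20, 2), 1)
    L <- sample(30:60, 1)
    H <- matrix(rbinom(n * L, 1, runif(1, 0.3, 0.7)), n, L)
    hs <- hapset_from_matrix(H)
    sc <- nsl_scan(hs, maf_min = 0)
    or <- nsl_oracle(H)
    m <- match(hs$variants$id[or$x], sc$id)
    expect_false(anyNA(m))
    expect_equal(sc$sl_a[m], or$sl_a)
    expect_equal(sc$sl_d[m], or$sl_d)
  }
})

test_that("nSL is invariant to haplotype order and negates under allele flip", {
  set.seed(311)
  H <- matrix(rbinom(16 * 50, 1, 0.5), 16, 50)
  sc <- nsl_scan(hapset_from_matrix(H), maf_min = 0)
  scp <- nsl_scan(hapset_from_matrix(H[sample(16), ]), maf_min = 0)
  expect_equal(sc$nsl_raw, scp$nsl_raw)
  # flipping derived/ancestral at one focal SNP swaps SL_A and SL_D there
  x <- 25
  Hf <- H; Hf[, x] <- 1 - Hf[, x]
  scf <- nsl_scan(hapset_from_matrix(Hf), maf_min = 0)
  id <- paste0("chr1:", x * 1000)
  expect_equal(scf$nsl_raw[scf$id == id], -sc$nsl_raw[sc$id == id])
})

test_that("frequency-bin standardization has unit moments per bin", {
  set.seed(321)
  L <- 600
  p <- runif(L, 0.05, 0.95)
  H <- sapply(p, function(pp) rbinom(40, 1, pp))
  sc <- nsl_scan(hapset_from_matrix(H))
  scn <- normalize_nsl(sc, n_bins = 20)
  for (b in unique(scn$bin)) {
    z <- scn$nsl_std[scn$bin == b & !scn$flagged]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
  # one bin equals global z-scoring
  g1 <- normalize_nsl(sc, n_bins = 1)
  expect_equal(g1$nsl_std, (sc$nsl_raw - mean(sc$nsl_raw)) / sd(sc$nsl_raw))
  expect_error(normalize_nsl(sc[1:10, ], n_bins = 50), "at least")
})

test_that("candidate calling enforces all three criteria", {
  sc <- data.frame(id = paste0("v", 1:200), nsl_std = rnorm(200, 0, 0.5))
  sc$nsl_std[7] <- 5          # extreme and annotated
  sc$nsl_std[8] <- 4.5        # extreme but unannotated
  ann <- data.frame(id = c("v7", "v100"), consequence = "intron_variant",
                    score = 1, curated = FALSE, trait = c("LDL", "height"))
  cs <- call_candidates(sc, ann, cluster = "c1")
  expect_equal(cs$ids, "v7")
  expect_equal(unname(cs$traits["v7"]), "LDL")
  # percentile 100 keeps at most the single top variant
  cs100 <- call_candidates(sc, ann, percentile = 100)
  expect_lte(length(cs100$ids), 1)
  # empty annotations yield an empty set with a warning
  expect_warning(cs0 <- call_candidates(sc, ann[0, ]), "empty")
  expect_length(cs0$ids, 0)
})

test_that("shared/private partition forms an exact lattice", {
  mk <- function(cl, ids) structure(list(cluster = cl, ids = ids,
    traits = setNames(rep("t", length(ids)), ids)), class = "candidate_set")
  a <- mk("c1", c("v1", "v2", "v3"))
  b <- mk("c2", c("v2", "v3", "v4"))
  c_ <- mk("c3", c("v3", "v5"))
  pt <- shared_private_partition(list(a, b, c_))
  expect_equal(sum(pt$venn$count), pt$n_union)
  expect_equal(pt$n_union, 5)
  expect_equal(pt$shared_all$id, "v3")
  expect_equal(unlist(pt$private$c1, use.names = FALSE), "v1")
  expect_equal(unlist(pt$private$c3, use.names = FALSE), "v5")
  # identical sets: everything shared; disjoint sets: everything private
  pt2 <- shared_private_partition(list(a, mk("c2", a$ids)))
  expect_equal(pt2$shared_all$id, a$ids)
  pt3 <- shared_private_partition(list(mk("c1", "x"), mk("c2", "y")))
  expect_equal(nrow(pt3$shared_all), 0)
  expect_error(shared_private_partition(list(a)), "at least 2")
})

test_that("an engineered sweep is flagged as a candidate", {
  called <- above_neutral <- 0
  for (s in 1:20) {
    set.seed(330 + s)
    L <- 1000; n <- 60
    H <- sapply(runif(L, 0.05, 0.95), function(p) rbinom(n, 1, p))
    x <- 500
    carriers <- 1:20
    win <- (x - 25):(x + 25)
    H[carriers, win] <- rep(H[carriers[1], win], each = length(carriers))
    H[carriers, x] <- 1          # long shared derived haplotype
    H[-carriers, x] <- 0
    hs <- hapset_from_matrix(H)
    scn <- normalize_nsl(nsl_scan(hs), n_bins = 20)
    ann <- data.frame(id = hs$variants$id[x],
                      consequence = "intron_variant", score = 1,
                      curated = FALSE, trait = "HDL")
    cs <- call_candidates(scn, ann, abs_min = 2, percentile = 99)
    called <- called + (ann$id %in% cs$ids)
    focal <- abs(scn$nsl_std[scn$id == ann$id])
    above_neutral <- above_neutral +
      (length(focal) == 1 && !is.na(focal) && focal >= qnorm(0.995))
  }
  expect_gte(called, 18)
  expect_gte(above_neutral, 18)
})
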