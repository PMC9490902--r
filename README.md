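# admixkit

Population-structure-aware analysis of genotyped cohorts with complex
admixture and consanguinity — the analytical situation typical of Gulf-region,
Middle Eastern and other strongly substructured populations, where ancestry
clusters differ in homozygosity burden, admixture history, selection signals
and the drift of deleterious variation.

`admixkit` is aimed at population and medical geneticists who want to run
this whole chain of analyses on diploid SNP data **and** to validate every
stage against simulated cohorts with known ground truth. The package ships a
first-class generator of admixed cohorts, so each claim the pipeline makes
(cluster count, ROH calls, selection candidates, admixture dates) can be
checked against the truth that generated the data.

## What it computes

* **Synthetic cohorts** — ancestral allele frequencies under the
  Balding–Nichols model (`p_kl ~ Beta` with mean `p0_l` and variance
  `F_k p0_l (1 − p0_l)`), individuals with Dirichlet ancestry proportions
  `q_i`, haplotypes painted as ancestry mosaics by a Poisson breakpoint
  process at rate `g` per Morgan (tract lengths `~ Exp(g)`), injected
  autozygous tracts, and annotation tables with a deleteriousness–frequency
  link.
* **QC** — call-rate filters (sites before samples), one-sided site
  heterozygosity outliers, the conditional exact Hardy–Weinberg test, and
  method-of-moments relatedness (`PI_HAT = P(IBD=2) + P(IBD=1)/2`).
* **Structure** — sliding-window LD pruning, PCA with Patterson scaling and
  projection of new samples, Gaussian-mixture clustering of the leading
  components (BIC over four covariance families), the binomial-likelihood
  admixture model
  `ℓ = Σ_il [g_il ln Σ_k q_ik p_kl + (2−g_il) ln Σ_k q_ik (1−p_kl)]`
  fitted by EM with masked-entry cross-validation over K, and UPGMA
  dendrograms of ancestry vectors.
* **ROH** — the PLINK-style scanning-window detector (50-SNP windows, ≤1
  heterozygote, per-SNP hit fraction ≥ 0.05, length/count/density gates) plus
  per-sample totals, `F_ROH` and excess-homozygosity inbreeding.
* **Selection** — the nSL statistic: at each focal SNP,
  `nsl_raw = ln(SL_A / SL_D)` where `SL_D`/`SL_A` are mean pairwise
  identity-tract lengths (in SNPs) among derived/ancestral carriers;
  standardized within derived-allele-frequency bins; candidates require
  `|nsl_std| ≥ 2`, the top percentile, and a trait annotation; candidate sets
  are partitioned into shared and private signals across clusters.
* **LOF** — curated-list ∪ stop-gain loss-of-function sets, per-cluster
  one-vs-rest allelic chi-square with Bonferroni control, genotype-by-cluster
  contingency tests, and the deleteriousness ratio
  `median AF(score ≥ 25) / median AF(score ≤ 5)` per cluster (low ratio =
  purifying selection outpacing drift).
* **Dating** — two-reference weighted LD (`D̂_lm w_l w_m` with
  `w = f_ref1 − f_ref2`, binned by genetic distance), exponential pulse fits
  `a e^{−g d} + c` (one or two pulses, F-test selection, chromosome
  jackknife SE), and generation→calendar conversion.

## Worked example

Simulate a two-ancestry cohort (100 individuals, 2 000 SNPs on four
chromosomes) admixed 12 generations ago, plant a 4-Mb autozygous tract in
one sample, and run the pipeline:

```r
library(admixkit)

vt     <- simulate_variant_table(2000, n_chrom = 4, chrom_length_bp = 2e7, seed = 1)
freqs  <- simulate_ancestral_freqs(K = 2, L = 2000, F = 0.3, seed = 2)
Q      <- simulate_Q(N = 100, alpha = c(0.3, 0.3), seed = 3)
cohort <- simulate_admixed_cohort(freqs, Q, vt, pulse_g = 12, seed = 4)
cohort <- inject_roh(cohort, "S001", "chr1", c(5e6, 9e6))

qc <- qc_pipeline(cohort$genotypes, pi_hat = 0.45)  # structured cohort: see vignette
print(qc$report)
#> QC report: 0 samples and 13 sites removed
#> hwe
#>  13

pc <- pca_patterson(qc$genotypes, m = 10)
round(pc$varfrac[1], 3)
#> [1] 0.159
cl <- gmm_cluster(pc$scores, n_pc = 6, K_range = 1:6)
cl$K
#> [1] 3

segs <- detect_roh(cohort$genotypes)
segs[segs$sample == "S001", ]
#>  sample chrom start_bp  end_bp n_snps length_kb
#>    S001  chr1  5063230 9201917    103  4138.688

fit <- fit_pulses(weighted_ld_curve(cohort$haplotypes,
                                    freqs$P[1, ], freqs$P[2, ]), n_pulses = 1)
print(fit)
#> pulse_fit: 1 pulse(s); g = 12.1 generations (SE 1.93 )
generations_to_year(fit$g)
#> [1] 1637
```

Reading the output: the 13 sites removed by the exact Hardy–Weinberg filter
are a Wahlund effect of pooling two ancestries; PC1 carries 16% of the
variance (the ancestry axis); the mixture clustering splits the admixture
cline into three groups; the injected 5–9 Mb tract is recovered as a single
4 139-kb segment of 103 SNPs; and the weighted-LD decay dates the pulse at
12.1 ± 1.9 generations (truth: 12), i.e. around 1637 CE at 30 years per
generation.

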