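---
title: "Models and methods behind admixkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind admixkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`admixkit` analyses cohorts whose defining features are strong ancestry
substructure, historical admixture pulses, and consanguinity. This vignette
is the package's own account of the models it fits, the parameters that
matter, the choices made where the design was genuinely open, and what the
simulation-based tests do and do not establish.

## The synthetic cohort generator

Everything downstream is validated against cohorts from `synthgen`, so its
assumptions are the contract.

**Ancestral frequencies.** `simulate_ancestral_freqs()` draws, for each of
`K` ancestral populations and `L` variants, a frequency from
`Beta` with mean `p0_l` and variance `F_k p0_l (1 - p0_l)` — the
Balding–Nichols model, i.e. exactly the family the admixture likelihood
assumes. The shared frequencies `p0` are Uniform(0.05, 0.95): bounded away
from 0 and 1 so sites are rarely monomorphic at birth (they may still become
monomorphic by sampling, and downstream code excludes such sites rather than
assuming they cannot occur). `F` per population is the familiar
differentiation parameter; 0.1–0.3 spans within-continental to
between-continental differentiation.

**Haplotype painting.** Each haplotype is a mosaic of ancestry tracts:
breakpoints follow a Poisson process at rate `pulse_g` per Morgan along the
genetic map, each tract's ancestry is drawn independently from the
individual's proportions `q_i`, and each allele is Bernoulli of the tract
ancestry's frequency. This is the standard single-pulse admixture model:
interior tract lengths are `Exp(pulse_g)` in Morgans and admixture LD decays
as `exp(-g d)`. Two-pulse cohorts (`simulate_two_pulse_cohort()`) mix two
painted layers with the same ancestry-proportion distribution, so the
expected allele frequencies agree across layers and the pooled weighted-LD
curve is the mixture of the two exponentials without a Wahlund term.

**What is deliberately not simulated**: background LD within ancestral
populations (sites are independent within a tract), mutation and genealogical
noise, genotyping error, and realistic site-frequency spectra. Consequences:
passing tests demonstrate correctness of the algorithms under the admixture
model, not robustness to array artefacts or to background LD. In particular
the nSL neutral calibration (below) is a statement about unlinked neutral
sites.

**Ancestry proportions.** Cohorts are given Dirichlet `q_i`. Recovery
fixtures use Dirichlet(0.3), which produces clusters with predominant single
ancestries plus a minority of strongly admixed individuals — the
configuration real structured cohorts show, and one in which the admixture
decomposition is well identified. A uniform Dirichlet(1) cohort (everyone
heavily admixed) is markedly harder: the same likelihood is flatter and
individual proportions are recovered with roughly twice the error.

**Deleteriousness link.** `simulate_annotations()` assigns a 0–50
CADD-like score; `shape_lof_freqs()` multiplies ancestral frequencies of
loss-of-function variants by `exp(-efficiency_k * score/50)`. `efficiency`
is a per-population surrogate for how effectively purifying selection beats
drift (large effective population size = large efficiency). It induces the
monotone frequency/deleteriousness link that the deleteriousness-ratio
statistic is designed to read out.

## QC

Filters run in the order relatedness → site-heterozygosity outliers → site
call rate → sample call rate → Hardy–Weinberg, with sites filtered before
samples (the PLINK convention). Defaults: ≤1% missing per site, ≤5% per
sample (strict inequalities at the threshold), heterozygosity flagged only
above mean + 3 SD (one-sided, since excess heterozygosity is the artefact
signature), HWE removal at p < 1e-6, PI_HAT > 0.185 (midpoint between 2nd-
and 3rd-degree relatives).

The exact HWE test conditions on allele counts and sums the probabilities of
heterozygote counts no more probable than the observed one; probabilities are
built by the standard ratio recurrence (numerically stable, no factorials).
The test suite checks it against a direct log-gamma evaluation of the
multinomial form for every table with up to 50 individuals.

Relatedness uses method-of-moments IBD: observed IBS 0/1/2 counts per pair
against their Hardy–Weinberg expectations computed from *unbiased
count-based estimators* of the allele-frequency powers (the finite-sample
correction matters: plugging in `p̂^2 q̂^2` directly inflates PI_HAT
noticeably at small N). Two caveats are inherent to the method and
documented rather than hidden: estimates are noisy below a few thousand
sites, and **population structure inflates PI_HAT between individuals who
merely share ancestry** — in a structured cohort, prune relatedness within
clusters or raise the threshold, as the README example does.

## Structure

*LD pruning* follows the sliding-window greedy rule (window 200 SNPs, step
50, r² > 0.4; the lower-MAF member of an offending pair is removed, ties to
the later position) repeated to a fixed point.

*PCA* uses Patterson scaling — centre by `2 p̂`, scale by
`sqrt(2 p̂ (1 - p̂))` — which puts drift on a common scale across
frequencies; monomorphic sites are excluded and missing calls are
mean-imputed after centring. Scores are `U D` from the SVD; stored loadings
and frequencies make projection of new samples exactly reproduce training
scores. Scores are sign-ambiguous, as in any PCA.

*Gaussian-mixture clustering* of the first 6 components spans four
covariance families (spherical-equal, diagonal-varying, full-shared,
full-varying) and selects (K, family) by BIC via `mclust`, whose
hierarchical initialization is deterministic given the data. Six components
and K up to 9 are defaults, not dogma. A caution the worked example shows:
an admixture *cline* is not a Gaussian blob, so BIC may split a continuum
into more clusters than there are ancestral populations — the admixture
model, not the clustering, is the arbiter of K for ancestry.

*Admixture model.* The binomial likelihood is maximized by plain EM with
multiplicative count updates; the log-likelihood is non-decreasing every
iteration (a property the tests assert), `P` is clamped to
`[1e-6, 1 - 1e-6]`, missing genotypes contribute nothing to any sum, and
convergence is declared at relative log-likelihood change `< 1e-6` (cap
2 000 iterations). Initialization is seeded: Dirichlet rows for `Q`, observed
frequencies plus uniform jitter for `P`. Cross-validation masks a fraction
(default 10%) of observed entries per fold, refits, and scores masked
entries by mean binomial deviance against `2 Σ_k q̂_ik p̂_kl`.

At the recovery design size used in the tests (K = 3, F = 0.2, N = 200,
L = 5 000, Dirichlet(0.3)), mean absolute error of `Q̂` is below 0.05. A
note on `P̂`: with N = 200 spread over three ancestries, each ancestral
frequency is informed by roughly 130 allele draws, so even an oracle given
the true `Q` cannot beat an RMSE of about 0.036; the suite therefore asserts
RMSE < 0.05 — the estimator sits at the sampling floor, and tightening the
bound would require a larger cohort, not a better algorithm.

*Ancestry dendrogram.* Pairwise Euclidean distances between rows of `Q`,
average linkage (UPGMA). Both are configurable; Euclidean/average is the
default because ancestry vectors live on the simplex where Euclidean
distance is adequate and UPGMA keeps merge heights interpretable as mean
distances. Leaves can carry cluster labels and per-sample total ROH for the
classic dendrogram-plus-homozygosity overlay.

## Runs of homozygosity

The detector is the PLINK scanning-window heuristic with the PLINK 1.9
defaults exposed in `roh_params()`: 50-SNP windows tolerating ≤1
heterozygote and ≤5 missing calls; a SNP is in-run when ≥5% of the windows
fully inside the chromosome that overlap it are homozygous; runs are split
at gaps > 1 000 kb and reported at ≥100 SNPs, ≥1 000 kb, and ≥1 SNP per
50 kb. Edge behaviour: only windows fully inside the chromosome count, so
the first and last few SNPs are supported by fewer windows. Homozygosity is
label-free, so calls are invariant to allele flips (asserted). The recovery
tests use a 1 SNP / 5 kb map; on sparser maps the SNP-count and density
gates dominate, which is the main practical failure mode of ROH detection
on thin arrays.

`het_inbreeding()` is the excess-homozygosity moment estimator
`F = (O_hom − E_hom)/(L − E_hom)` with the `n/(n−1)` small-sample factor in
`E_hom`; `roh_summary()` reports per-sample totals, segment counts and
`F_ROH` = total ROH length over the genotyped span.

## Selection: nSL

At focal SNP `x`, for haplotypes i, j the tract `L_ij(x)` counts the SNPs of
the maximal contiguous interval containing `x` on which i and j are
identical at every SNP. The convention here — the interval *includes* the
focal SNP, so `L ≥ 1` always, and intervals truncate at chromosome ends
without penalty — is stated explicitly because endpoint conventions differ
between implementations; scan, brute-force test oracle and documentation all
share it. `SL_D` and `SL_A` are the means over derived-carrier and
ancestral-carrier pairs and `nsl_raw = ln(SL_A/SL_D)`; unusually long
derived haplotypes (a sweep on the derived allele) push the score negative.
Scores are undefined, and skipped, when either carrier class has fewer than
two haplotypes or the MAF is below 0.05.

Standardization bins scored variants by derived-allele frequency into 50
equal-width bins, merging bins with fewer than two variants into their
nearest occupied lower neighbour, and z-scores within bins; zero-variance
bins are flagged rather than silently dropped. On neutral unlinked cohorts
the `|nsl_std| ≥ 2` rate lands near the two-sided normal tail (4.6%), which
the calibration test asserts within a pre-set band of 3.0–6.5% that covers
Monte-Carlo noise plus the approximation of binned z-scores by a standard
normal.

Candidate calling is deliberately conservative, requiring all three of
`|nsl_std| ≥ 2`, `|nsl_std|` at or above the cluster's 99th percentile, and
a prior trait association. The percentile default is 99, with 99.9 available
(`percentile = 99.9`) for a stricter genome-wide screen; the absolute value
is used so that strong negative scores (derived sweeps) and positive scores
(ancestral haplotype excess) are treated symmetrically. The shared/private
partition assigns each candidate to exactly one cell of the
inclusion/exclusion lattice over clusters — the counts are what a Venn
diagram of cluster candidate sets displays.

## Loss-of-function variation

The LOF set is the union of a curated list and stop-gain consequences,
restricted to genotyped variants. Differentiation is tested one cluster vs
all others on 2×2 allele-count tables with the 1-df chi-square *without*
continuity correction (the PLINK `--assoc` convention), and the Bonferroni
family defaults to variants × clusters — the conservative reading, since the
procedure tests every cluster; `family = "variants"` is available. Under a
null with no differentiation (97 variants × 4 clusters) the family-wise
error rate stays at or below the nominal 0.05, which the calibration test
checks over 2 000 replicates.

The deleteriousness ratio divides the median within-cluster allele frequency
of high-score LOFs (≥ 25) by that of low-score LOFs (≤ 5). Scores in (5, 25)
are excluded by construction, making the ratio invariant to them (asserted).
Degenerate cases are flagged, never dropped: an empty bin yields `NA` with
flag `"empty_bin"`, a zero low-bin median yields `Inf` with flag
`"zero_low_median"`. Interpretation: drift moves both bins alike, selection
suppresses the high bin specifically, so the cluster with the most effective
selection (largest Ne) shows the smallest ratio — the ordering the seeded
simulation test reproduces 20/20 times.

Genotype-by-cluster tables (3 × m chi-square) replace tree-based displays of
ancestry-genotype association; a warning marks expected cells below 5.

## Admixture dating

The weighted-LD curve accumulates, for each same-chromosome pair within
0.5–30 cM, the haplotype-based `D̂_lm = freq(11) − p̂_l p̂_m` of the target
weighted by `(f1_l − f2_l)(f1_m − f2_m)` from two reference frequency
vectors, averaged in 0.1-cM bins. The lower cutoff (0.5 cM) excludes
background LD; swapping the references flips every weight's sign and leaves
the curve unchanged (asserted).

Fitting minimizes weighted least squares of `a e^{−g d} + c` (distances in
Morgans, so `g` is directly the generation depth) with bins weighted by
their pair counts and a log-spaced multistart over `g` from 1 to 200; the
two-pulse model `a1 e^{−g1 d} + a2 e^{−g2 d} + c` (g1 > g2 enforced by
relabelling) is accepted only when an F-test on residual variance passes at
0.05. With ≥2 chromosomes, a leave-one-chromosome-out jackknife gives the SE
of `g`. Failure across all starts returns a structured failure object, never
a silent fallback. Two numerical notes from the recovery experiments: the
pair-count weighting matters for separating a slow pulse from the affine
term, and a recent pulse (small g) is intrinsically harder to pin down on
short chromosomes because `e^{−g d}` barely decays over the available
distance range — the two-pulse fixture therefore uses eight 1-Morgan
chromosomes (400 diploids), where median recovery over seeds is within ±25%
for both pulses and the one-pulse suite ({5, 10, 32}, four chromosomes,
200 diploids) is within ±20%.

`generations_to_year()` is `ref_year − g × gen_time_years` rounded; the
generation time (30 y) and baseline (2000 CE) are explicit arguments because
published conversions are not always mutually consistent and the user should
own that choice.

## Uniparental diversity

Nei's haplotype diversity `H = n/(n−1)(1 − Σ p_i²)`. The Y/mtDNA ratio is
reported both at full precision and truncated (not rounded) to two decimals:
for diversities 0.574/0.873 the quotient is 0.6575…, printed as 0.65 under
truncation — the convention such ratios are customarily quoted with, and the
reason both forms are returned.

## Problem sizes and runtime

The test suite is sized for a desktop single core: oracle equivalences use
100 random panels of ≤24 haplotypes × ≤80 SNPs plus exhaustive HWE tables to
n = 50; parameter recovery uses N = 200 × L = 5 000 (admixture),
N = 100 × L = 800 (cross-validation over K = 1..5), 20 ROH fixtures of
10 × 4 000, and the dating sizes above; calibration uses a 100 × 4 000
neutral panel and 2 000 null replicates of 200 × 97. The full suite runs in
under two minutes.

## Known limitations

* Sites are unlinked within ancestry tracts, so any method whose null
  depends on background LD (e.g. nSL on dense real data) is calibrated here
  only for the unlinked case; on real data, use the empirical within-bin
  distribution, as the standardization already does.
* The relatedness estimator assumes a homogeneous population; in structured
  cohorts PI_HAT mixes kinship with shared ancestry.
* The admixture EM is plain (no quasi-Newton acceleration); at much larger
  N × L than the tested sizes, convergence time grows accordingly.
* Weighted-LD dating is implemented for one pair of references (the
  two-reference simplification); multi-reference scans and Z-score ranking
  of reference pairs are out of scope.
* Haplotype-based `D̂` requires phased input; an unphased covariance
  estimator is not provided.
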