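Package: admixkit
Title: Population Structure, Homozygosity and Functional Variation in Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-structure-aware analysis of genotyped
    cohorts with complex admixture and consanguinity: simulation of admixed
    diploid cohorts with known ground truth (Balding-Nichols ancestral
    frequencies, dated admixture pulses, injected runs of homozygosity),
    genotype quality control (call rate, heterozygosity outliers, exact
    Hardy-Weinberg test, relatedness pruning), ancestry inference (LD pruning,
    Patterson-scaled PCA with projection, Gaussian-mixture clustering of
    leading components, binomial-likelihood admixture EM with cross-validation,
    ancestry dendrograms), PLINK-style run-of-homozygosity detection and
    inbreeding summaries, haplotype diversity for uniparental markers, the nSL
    haplotype selection statistic with frequency-bin standardization and
    shared/private candidate partitioning, loss-of-function frequency
    differentiation with a deleteriousness-ratio statistic, and weighted-LD
    admixture dating with exponential pulse fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    ape,
    vcfR,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
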