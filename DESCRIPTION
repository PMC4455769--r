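Package: geodiff
Title: Geographic Differentiation and Environmental Association for Haploid SNP Panels
Version: 1.0.0
Authors@R:
    person("Geodiff", "Developers", email = "geodiff@example.org", role = c("aut", "cre"))
Description: Tools for analysing geographic population structure in inbred
    (effectively haploid) SNP genotype panels, modelled on diversity-panel
    studies of crop wild relatives. Includes genotype quality control and
    allele polarisation, Weir-Cockerham and hierarchical F-statistics with
    permutation tests, linkage-disequilibrium and haplotype-window scans for
    high-differentiation chromosomal regions, a no-admixture Gibbs sampler for
    Bayesian genetic assignment with replicate-run label alignment,
    informativeness for assignment, rarefaction of allelic richness, Mantel and
    Procrustes comparisons of genetic and geographic structure, Bayenv-style
    environmental-association Bayes factors with a population allele-frequency
    covariance null, spatial allele-frequency gradient (SPA-style) scores,
    empirical-percentile outlier calling with enrichment resampling, and a
    seeded synthetic-data generator that emulates the statistical structure all
    of these stages assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
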