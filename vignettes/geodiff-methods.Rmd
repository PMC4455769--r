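---
title: "Methods: geographic differentiation and environmental association in haploid SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geographic differentiation and environmental association in haploid SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geodiff)
```

## Scope and data model

`geodiff` analyses geographic population structure in panels of inbred,
georeferenced accessions genotyped on a fixed SNP array — the setting typical
of diversity collections of selfing crop wild relatives. Because such lines
are near-completely homozygous (observed heterozygosity of a fraction of a
percent), all statistics treat a sample as a single gene copy: the genotype
matrix holds haploid calls 0 (ancestral/reference), 1 (derived/alternate),
a pre-QC heterozygote flag `H` (an error proxy in inbred material) and `N`
(missing).

The package covers the full analysis arc: quality control and allele
polarisation; within-group diversity (segregating sites, private SNPs,
percent pairwise difference, joint unfolded SFS, rarefaction); Weir–Cockerham
and hierarchical F-statistics; linkage-disequilibrium and haplotype-window
scans that localise high-differentiation chromosomal regions; Bayesian
genetic assignment; geography (Mantel, PCA, Procrustes); and environmental
association (covariance-corrected Bayes factors and spatial gradient
scores), with percentile outlier calling and annotation-enrichment
resampling. A synthetic-data generator produces datasets with all of the
structure these stages assume, so every stage is testable against ground
truth without any proprietary accession data.

## Quality control

`qc_filter()` applies three rules in a fixed order: (1) drop markers
monomorphic among non-missing calls; (2) drop markers with ≥ 15% missing
data (the boundary is inclusive); (3) drop markers with > 10% observed
heterozygosity; finally any residual `H` calls are converted to missing.
The order is part of the contract (each rule sees the survivors of the
previous one). One consequence worth knowing: converting residual `H` to
missing can leave a marker's final missing fraction slightly above 15%; we
do not re-apply rule 2, because the rule order is fixed.

Polarisation (`polarize()`) recodes calls so 0 is the ancestral allele
wherever an outgroup-derived ancestral state is available. Markers whose
ancestral state matches neither allele are flagged `unpolarizable` and are
excluded from frequency-spectrum analyses only; markers with no outgroup
call stay unpolarized but remain usable for F-statistics and LD.

## F-statistics

`wc_fst()` implements the Weir–Cockerham variance-components estimator for
one gene copy per individual. Per marker, with `r` groups of sizes `n_i` and
frequencies `p_i`:

- `n_c = (N − Σ n_i² / N) / (r − 1)`
- `MSA = Σ n_i (p_i − p̄)² / (r − 1)`, `MSW = Σ n_i p_i (1 − p_i) / (N − r)`
- `a = (MSA − MSW) / n_c`, `θ = a / (a + MSW)`

Multi-locus and region estimates always combine by ratio of sums
(`Σa / Σt`), never by averaging per-marker ratios. Negative per-marker
estimates are reported as computed; they are truncated at zero only when an
empirical percentile threshold is displayed, matching the usual figure
convention. Both choices follow standard practice for this estimator.

`hierarchical_f()` fits the three-level nested ANOVA (populations,
subpopulations within populations, individuals within subpopulations) with
the unbalanced-design coefficients, and reports every level pair as a ratio
of summed components. Degenerate nestings collapse to the two-level model,
so a one-level call agrees with `wc_fst()` to machine precision. Two
permutation tests use a multinomial likelihood-ratio (G) statistic:
subpopulation labels permuted within populations (individuals-within-
subpopulations), and whole subpopulations permuted among populations
(subpopulations-within-populations), with `p = (1 + #{G* ≥ G}) / (1 + n_perm)`.

## Assignment model

`gibbs_assign()` is a deliberate re-implementation of only the model the
source analyses selected: no admixture, uncorrelated allele frequencies,
Dirichlet(1) priors per locus per cluster. It is not a full STRUCTURE
replacement (no admixture proportions, no correlated-frequencies prior, no
ΔK heuristics). Replicate chains routinely settle in different modes on
real-scale data; `align_runs()` resolves label switching by exhaustive
permutation search (K ≤ 8) and averages the aligned membership matrices,
which is the CLUMPP-style consensus the field uses. Function defaults are
desk-scale (2,000 + 2,000 sweeps); the pipeline's `scale = "full"` setting
restores the publication-scale 100,000 + 100,000.

Informativeness for assignment (`informativeness()`) uses cluster allele
frequencies from hard labels by default; a membership-weighted variant is
available (`weighted = TRUE`), since the original tooling does not document
which it uses.

## Environmental association

The Bayenv-style null model treats each SNP's transformed population
frequencies — logit of the boundary-shrunken frequency `(c + 0.5)/(n + 1)` —
as multivariate normal around a per-SNP mean with a shared population
covariance Ω. Three numerical choices matter:

- **Anchored mean prior.** The per-SNP mean enters the likelihood only
  through the latent frequencies, so with a flat prior the common mode of Ω
  and the mean level are confounded and independent chains wander along that
  ridge (we observed mirror-image Ω estimates between runs). We give the
  mean a proper normal prior centred on the SNP's pooled transformed
  frequency (SD 1.5 on the logit scale), which anchors the level and makes Ω
  identifiable.
- **Rao-Blackwellised Ω.** The reported Ω accumulates the conditional
  posterior mean of the inverse-Wishart update rather than raw draws,
  removing a large Monte-Carlo noise term. The estimate is the mean over two
  independent runs and the element-wise between-run correlation is reported
  as the convergence diagnostic, mirroring the original two-run protocol. A
  low correlation is itself diagnostic — with strongly block-structured data
  and short runs it flags multimodality rather than a software fault.
- **Bayes factors by grid integration.** `bayes_factor()` integrates a
  linear environmental effect β over a Uniform(−0.3, 0.3) grid. For each β
  the latent-frequency integral is importance-sampled with a Gaussian
  posterior-approximation proposal (prior × normal approximation of the
  binomial likelihood), with the exact binomial likelihood in the weights.
  Sampling from the MVN prior instead — the naive scheme — has a vanishing
  effective sample size beyond a handful of populations. Because the β prior
  is bounded and our approximation differs from the original software's MCMC,
  Bayes factors are comparable in rank but not magnitude to published values.

`spa_score()` fits, per SNP, a logistic allele-frequency surface over
standardised (longitude, latitude) by ridge-damped Newton iterations
(ridge 1e-4); the score is the gradient norm ‖a‖, invariant to rotations of
the coordinate frame. Complete spatial separation is flagged and returns the
ridge-regularised fit.

Outliers are flagged at empirical genome-wide percentiles (95th/99th), with
ties at the threshold included. Enrichment of candidate sets by annotation
uses equal-size resampling without replacement from a caller-scoped SNP
universe; a resample with an empty denominator counts as +∞, i.e. above
every finite observed ratio.

## The synthetic-data generator

`simulate_dataset()` states the world the analyses assume:

- **Nested Balding–Nichols frequencies**, not a coalescent: populations draw
  Beta frequencies around an ancestral value with dispersion `F_pop`
  (default 0.042), subpopulations around their population with `F_subpop`
  (default 0.155) — the two-level differentiation reported for the
  wild-barley panel this package is modelled on. The statistics under test
  are frequency-based, so a frequency-level simulator is the matched (and
  fast) choice.
- **Ascertainment** is emulated by bounding the ancestral frequency away
  from 0/1 (`Uniform(maf_min, 1 − maf_min)`, default floor 0.1), the
  signature of array SNPs discovered in a small panel; it produces the
  expected deficit of rare variants in the spectrum.
- **Two backbone regions** (defaults: 2H 67–74 cM, 5H 47–52 cM) emulate
  putative chromosomal rearrangements: inside a region every sample carries
  one of its population's few backbone haplotypes (default 6 in the diverse
  "Western-like" population 1, 2 in population 2), which simultaneously
  creates high LD, high F_ST, low haplotype counts, and the East/West
  haplotype-diversity asymmetry.
- **Geography on a km plane** with an impassable meridian between the two
  populations, mapped to lat/lon near 35°N 48°E; analysis operations on real
  coordinates always use great-circle (haversine) distances because ranges
  of thousands of km make planar approximations poor.
- **Environment** variables are linear in the standardised coordinates plus
  Gaussian noise (`env_noise_sd`, default 1 — noise comparable to signal),
  giving a temperature-like latitude axis and a precipitation/altitude-like
  longitude axis, so environmental PCA has two recoverable gradients.
- **Environmental effects are per-sample clines**: selected SNPs get a logit
  shift of `env_effect_size` (default 4) per SD of the sample's longitude
  gradient. Two deliberate choices: effects act on each sample's local
  environment (a subpopulation-level shift is nearly binary East/West in
  this geography and hence perfectly confounded with the structure the
  covariance null removes — power against it is ~0 by construction, which we
  verified with a closed-form bound); and the default slope is strong, in
  the range of the steepest spatial gradients reported for such panels,
  because the power contract concerns clearly adaptive variants.
- **Error injection**: missing calls (default 5%, the fraction of
  low-confidence calls set to missing upstream in the motivating study) and
  heterozygote flags (default 0.2%, the observed heterozygosity of inbred
  lines) give the QC filter real work.

What the generator does *not* emulate: recombination-map realism, selection
beyond backbone construction, sequence-level mutation processes, spatial
autocorrelation of environment beyond linear gradients. A green test
therefore establishes that an estimator recovers the stated
frequency/geography structure — not that it is robust to every feature of
real array data.

## Numerical conventions

- Marker sort order is (linkage group, cM, marker id); equal-cM ties break
  lexicographically for reproducibility.
- 5-SNP haplotype windows are consecutive and non-overlapping; trailing
  windows with fewer than five markers are dropped; windows never span
  linkage groups. Missing calls give a missing window code unless
  within-cluster modal-allele imputation is requested (the EM-phasing
  imputation used upstream in the motivating study is out of scope, and the
  data are haploid).
- PCA mean-imputes missing calls per marker and fixes score signs by making
  each component's largest-magnitude loading positive.
- Procrustes uses the symmetric (unit-norm) formulation; reflection is
  disallowed by default so a single counterclockwise rotation angle in
  [0, 360) is reported, with `t0 = sqrt(1 − D)`.
- All permutation p-values use `(1 + #{extreme}) / (1 + n_perm)`; enrichment
  p-values are plain resample proportions to match the exhaustive-enumeration
  definition.
- Every stochastic routine takes an explicit seed and restores the RNG state
  (`withr::with_seed`); replicate chains derive per-run seeds by fixed
  offsets.

Two practical caveats for the permutation machinery. First, the
subpopulations-within-populations test permutes whole subpopulations, so on a
balanced 2 × 3 design roughly 10% of permutations reproduce the observed
partition exactly and the attainable p-value floor is about 0.1 regardless of
how strong the structure is; unbalanced subpopulation sizes (the usual case in
real collections) break those ties. Second, with only a handful of analysis
populations the per-SNP mean centring in the covariance model forces
off-diagonal entries toward −1/(P − 1) of the diagonal; the independence
diagnostics are therefore meaningful in the many-population regime the method
is designed for (~17 clusters), not for toy P.

## Known limitations

- Bayes-factor magnitudes depend on the bounded β prior; only ranks should
  be compared across implementations.
- The covariance sampler's between-run correlation degrades on short runs
  when structure forms two balanced blocks; run longer chains or read the
  diagnostic as intended.
- `R_ST` uses the simple pooled-vs-within variance form; microsatellite
  mutation-rate heterogeneity is not modelled.
- The assignment sampler reports per-run likelihood traces for convergence
  assessment but applies no automatic convergence control.
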