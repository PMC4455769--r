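# geodiff

Geographic differentiation and environmental association for haploid SNP
panels.

## The problem

Diversity collections of selfing crop wild relatives — inbred, georeferenced
accessions genotyped on a fixed SNP array — pose a recurring analysis
problem: how is genetic variation structured across a species' range, which
chromosomal regions carry a disproportionate share of that differentiation,
and which variants track environmental gradients rather than demography
alone? `geodiff` implements that full analysis arc for effectively haploid
genotype data:

- **QC and polarisation** — the standard inbred-panel filters (monomorphic,
  ≥ 15% missing, > 10% observed heterozygosity, in that order), and
  recoding against an outgroup-derived ancestral state.
- **Diversity** — segregating sites, private SNPs, percent pairwise
  difference, joint unfolded site frequency spectrum with hypergeometric
  projection, rarefaction of allelic richness and private alleles,
  microsatellite expected heterozygosity.
- **Differentiation** — per-SNP and ratio-of-sums Weir–Cockerham
  F<sub>ST</sub> (haploid variance components), hierarchical F-statistics
  with G-statistic permutation tests, region summaries, R<sub>ST</sub> for
  microsatellites.
- **LD and haplotypes** — pairwise r² within linkage groups (MAF > 5%),
  region-vs-flank LD contrasts, 5-SNP haplotype windows, region
  haplotype-frequency tables by population.
- **Assignment** — a no-admixture, uncorrelated-frequencies Gibbs sampler
  with CLUMPP-style replicate alignment, and informativeness for assignment
  (I<sub>n</sub>).
- **Geography** — haversine distances, Mantel tests, genotype PCA, Velicer
  MAP component selection, Ward clustering, Procrustes rotation of PC space
  onto the map.
- **Environmental association** — Bayenv-style Bayes factors against a
  population allele-frequency covariance null, SPA-style logistic spatial
  gradient scores, empirical-percentile outlier calling, and
  annotation-enrichment resampling.
- **simdata** — a seeded generator producing genotypes, geography,
  environment and annotations with all of the structure above (nested
  populations, isolation by distance, backbone-haplotype "rearrangement"
  regions, ascertainment bias, environmental clines), plus the ground truth
  to verify every stage.

The central statistic is the haploid Weir–Cockerham estimator: per marker,
with groups of size $n_i$ and allele frequencies $p_i$,

$$\theta = \frac{a}{a + \mathrm{MSW}},\qquad
a = \frac{\mathrm{MSA} - \mathrm{MSW}}{n_c},$$

with MSA/MSW the among- and within-group mean squares and $n_c$ the usual
unequal-size coefficient; multi-locus values are always $\sum a / \sum t$.
The environmental-association null is $x_\ell \sim
\mathcal{N}(\mu_\ell \mathbf{1}, \Omega)$ on logit-transformed population
frequencies, with Bayes factors integrating a linear effect
$\beta\,\mathrm{env}$ over a bounded grid.

## Worked example

```r
library(geodiff)

# a 282-sample, 2331-SNP synthetic panel: 2 populations x 3 subpopulations,
# two backbone regions on 2H and 5H
b <- simulate_dataset(sim_config(seed = 1))
g <- qc_filter(b$genotypes)$genotypes
dim(g)
#> [1]  282 2329

scan <- wc_fst(g, b$truth$pop)
attr(scan, "theta_global")
#> [1] 0.1022675

region_fst(scan, b$markers, list(linkage_group = "2H", cM_lo = 67, cM_hi = 74))
#> $theta
#> [1] 0.7050107
#>
#> $n_markers
#> [1] 15

ld <- pairwise_r2(g, b$markers)
unlist(region_ld_contrast(ld, list(linkage_group = "2H", cM_lo = 67,
                                   cM_hi = 74))[1:2])
#>     inside    outside
#> 0.29327660 0.00824624

mantel(allele_sharing_dist(g),
       great_circle_km(b$samples$latitude, b$samples$longitude),
       n_perm = 999, seed = 1)[c("statistic", "p")]
#> $statistic
#> [1] 0.5958661
#>
#> $p
#> [1] 0.001
```

Read: genome-wide differentiation between the two primary populations is
θ ≈ 0.10, dominated by the drift targets of the generator, while the 15
markers of the 2H backbone region are far more differentiated (θ ≈ 0.71)
and carry ~35-fold elevated LD — the signature the package is built to
localise. The Mantel test shows strong isolation by distance.

The full pipeline (simulate/read → QC → assignment → scans → report CSVs and
a JSON manifest) runs from a single seeded config:

```r
cfg <- pipeline_config(seed = 1)          # scale = "full" for long samplers
run_pipeline(cfg, "out/")
```

or from the command line via `inst/exec/geodiff`:

```sh
geodiff run config.json out/ --seed 1
```

## Documentation

The methods vignette (`vignettes/geodiff-methods.Rmd`) documents the models,
the generator's stated world and its limits, and every numerical convention
(estimator forms, priors, tie-breaking, seeds).
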