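test_that("sim_config validates its invariants", {
  expect_error(sim_config(samples_per_subpop = 1), "samples_per_subpop")
  expect_error(sim_config(missing_rate = 1.2), "rates")
  expect_error(sim_config(region_specs = list(
    list(linkage_group = "9H", cM_lo = 1, cM_hi = 5))), "unknown linkage group")
  expect_error(sim_config(region_specs = list(
    list(linkage_group = "2H", cM_lo = 10, cM_hi = 200))), "within")
  expect_error(sim_config(region_specs = list(
    list(linkage_group = "2H", cM_lo = 10, cM_hi = 30),
    list(linkage_group = "2H", cM_lo = 20, cM_hi = 40))), "overlapping")
})

test_that("seed fully determines the simulated output", {
  cfg <- sim_config(samples_per_subpop = 4, snps_per_group = 20, seed = 9)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$markers, b$markers)
  expect_identical(a$env, b$env)
  c <- simulate_dataset(sim_config(samples_per_subpop = 4, snps_per_group = 20,
                                   seed = 10))
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("no drift yields panmixia (F_ST ~ 0, mean frequency difference ~ 0)", {
  b <- simulate_dataset(sim_config(
    n_subpops_per_pop = 1, samples_per_subpop = 100, snps_per_group = 286,
    F_pop = 0, F_subpop = 0, region_specs = list(), missing_rate = 0,
    het_error_rate = 0, seed = 5))
  g <- b$genotypes
  pop <- b$truth$pop
  p1 <- colMeans(g[pop == "P1", ]); p2 <- colMeans(g[pop == "P2", ])
  expect_lt(abs(mean(p1 - p2)), 0.01)
  theta <- attr(wc_fst(g, pop), "theta_global")
  expect_lt(abs(theta), 0.01)
})

test_that("increasing F_pop increases realized genome-wide F_ST monotonically", {
  grid <- c(0.02, 0.05, 0.1, 0.2, 0.3)
  realized <- sapply(seq_along(grid), function(i) {
    mean(sapply(1:3, function(s) {
      b <- simulate_dataset(sim_config(
        n_subpops_per_pop = 1, samples_per_subpop = 40, n_linkage_groups = 3,
        snps_per_group = 120, F_pop = grid[i], F_subpop = 0,
        region_specs = list(), missing_rate = 0, het_error_rate = 0,
        seed = 100 * i + s))
      attr(wc_fst(b$genotypes, b$truth$pop), "theta_global")
    }))
  })
  expect_gt(stats::cor(grid, realized, method = "spearman"), 0.9)
})

test_that("backbone regions bound the haplotype count and inflate LD", {
  cfg <- sim_config(samples_per_subpop = 10, snps_per_group = 120,
                    n_linkage_groups = 2,
                    region_specs = list(list(linkage_group = "2H", cM_lo = 60,
                                             cM_hi = 80, n_backbone = 2L,
                                             divergence = 0.5)),
                    missing_rate = 0, het_error_rate = 0, seed = 21)
  b <- simulate_dataset(cfg)
  ids <- b$truth$region_markers[[1]]
  expect_gt(length(ids), 4)
  # pre-error-injection bound: distinct region haplotypes <= backbones x pops
  strs <- apply(b$genotypes[, ids], 1, paste, collapse = "")
  expect_lte(length(unique(strs)), 2 * 2)
  g <- qc_filter(b$genotypes)$genotypes
  ld <- pairwise_r2(g, b$markers)
  ct <- region_ld_contrast(ld, list(linkage_group = "2H", cM_lo = 60, cM_hi = 80))
  expect_gte(ct$inside / ct$outside, 3)
})

test_that("geography respects the mountain line and env follows gradients", {
  b <- sim_medium()
  lon <- b$samples$longitude
  pop <- b$truth$pop
  expect_true(all(lon[pop == "P1"] < 48))
  expect_true(all(lon[pop == "P2"] > 48))
  expect_true(all(abs(b$samples$latitude) <= 90))
  # temperature variables track latitude, precipitation tracks longitude
  expect_gt(abs(stats::cor(b$env$temp_mean, b$samples$latitude)), 0.3)
  expect_gt(abs(stats::cor(b$env$precip_annual, lon)), 0.3)
})

test_that("missing and heterozygote codes are injected near stated rates", {
  b <- simulate_dataset(sim_config(samples_per_subpop = 20, snps_per_group = 150,
                                   n_linkage_groups = 3, region_specs = list(),
                                   missing_rate = 0.05, het_error_rate = 0.01,
                                   seed = 33))
  g <- b$genotypes
  expect_lt(abs(mean(is.na(g)) - 0.05), 0.01)
  expect_lt(abs(mean(g == 2L, na.rm = TRUE) - 0.01), 0.005)
})

test_that("write_fixture is deterministic and round-trips", {
  b <- simulate_dataset(sim_config(samples_per_subpop = 2, snps_per_group = 10,
                                   n_linkage_groups = 2, region_specs = list(),
                                   seed = 4))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_fixture(b, d1)
  m2 <- write_fixture(b, d2)
  expect_identical(m1$md5, m2$md5)

  # VCF shape: one record per marker, one genotype column per sample
  vcf <- readLines(file.path(d1, "genotypes.vcf"))
  body <- vcf[!startsWith(vcf, "#")]
  expect_length(body, ncol(b$genotypes))
  expect_length(strsplit(body[1], "\t")[[1]], 9 + nrow(b$genotypes))

  # round trips reproduce the in-memory matrix exactly
  gv <- read_genotypes(file.path(d1, "genotypes.vcf"), "vcf")
  gt <- read_genotypes(file.path(d1, "genotypes.tsv"), "tsv")
  expect_equal(unname(`attributes<-`(gv, NULL)),
               unname(as.vector(b$genotypes)), ignore_attr = TRUE)
  expect_identical(dimnames(gv), dimnames(b$genotypes))
  expect_equal(as.vector(gt), as.vector(b$genotypes))
})
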