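test_that("wc_fst trivial identities", {
  # equal frequencies at equal n: theta ~ 0 (may be slightly negative)
  x <- geno_from_counts(c(5, 5), c(10, 10))
  s <- wc_fst(x$g, x$partition)
  expect_lt(abs(s$theta), 0.12)
  expect_lte(s$a, 0)
  # fixed difference: theta = 1
  x <- geno_from_counts(c(10, 0), c(10, 10))
  expect_equal(wc_fst(x$g, x$partition)$theta, 1)
  # worked example: n1 = n2 = 4, derived 3 vs 1 -> theta = 0.2
  x <- geno_from_counts(c(3, 1), c(4, 4))
  expect_equal(wc_fst(x$g, x$partition)$theta, 0.2)
  # monomorphic marker excluded
  x <- geno_from_counts(c(4, 4), c(4, 4))
  expect_true(is.na(wc_fst(x$g, x$partition)$theta))
  expect_error(wc_fst(x$g, factor(rep("A", 8))), "2 groups")
})

test_that("wc_fst equals the exhaustive scalar oracle on all small instances", {
  for (r in 2:3) {
    sizes_list <- if (r == 2) list(c(2, 2), c(3, 5), c(6, 4), c(2, 6))
                  else list(c(2, 2, 2), c(3, 4, 5), c(6, 2, 3))
    for (sizes in sizes_list) {
      counts_grid <- expand.grid(lapply(sizes, function(n) 0:n))
      for (i in seq_len(nrow(counts_grid))) {
        counts <- as.numeric(counts_grid[i, ])
        x <- geno_from_counts(counts, sizes)
        got <- wc_fst(x$g, x$partition)
        want <- oracle_wc(counts, sizes)
        if (is.na(want[["theta"]])) {
          expect_true(is.na(got$theta))
        } else {
          expect_equal(got$theta, want[["theta"]], tolerance = 1e-12)
          expect_equal(got$a, want[["a"]], tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("multi-locus theta is ratio-of-sums and marker-order invariant", {
  b <- sim_small()
  g <- qc_geno(b)
  s <- wc_fst(g, b$truth$pop)
  expect_equal(attr(s, "theta_global"),
               sum(s$a, na.rm = TRUE) / sum(s$t, na.rm = TRUE))
  perm <- sample(ncol(g))
  s2 <- wc_fst(g[, perm], b$truth$pop)
  expect_equal(attr(s2, "theta_global"), attr(s, "theta_global"))
  # genome-wide region equals the global estimate
  mk <- b$markers
  whole <- region_fst(s, mk, list(linkage_group = "1H", cM_lo = 0, cM_hi = 150))
  only1h <- mk$marker_id[mk$linkage_group == "1H" &
                         mk$marker_id %in% s$marker_id[!is.na(s$theta)]]
  expect_identical(whole$n_markers, length(only1h))
})

test_that("region_fst errors on empty regions", {
  b <- sim_small()
  s <- wc_fst(qc_geno(b), b$truth$pop)
  expect_error(region_fst(s, b$markers,
                          list(linkage_group = "1H", cM_lo = 900, cM_hi = 901)),
               "no scanned markers")
})

test_that("hierarchical_f with one level reduces to wc_fst", {
  b <- simulate_dataset(sim_config(samples_per_subpop = 6, snps_per_group = 40,
                                   n_linkage_groups = 2, region_specs = list(),
                                   missing_rate = 0, het_error_rate = 0,
                                   seed = 7))
  g <- qc_geno(b)                             # complete data: rule parity
  s <- wc_fst(g, b$truth$subpop)
  h <- hierarchical_f(g, factor(rep("P", nrow(g))), b$truth$subpop,
                      n_perm = 5, seed = 1)
  expect_equal(h$F["Population", "Subpopulation"],
               attr(s, "theta_global"), tolerance = 1e-12)
  h2 <- hierarchical_f(g, b$truth$pop, b$truth$pop, n_perm = 5, seed = 1)
  s2 <- wc_fst(g, b$truth$pop)
  expect_equal(h2$F["Total", "Population"], attr(s2, "theta_global"),
               tolerance = 1e-12)
})

test_that("hierarchical_f null: random labels give F ~ 0 and p > 0.05", {
  b <- simulate_dataset(sim_config(
    n_subpops_per_pop = 1, samples_per_subpop = 60, n_linkage_groups = 3,
    snps_per_group = 150, F_pop = 0, F_subpop = 0, region_specs = list(),
    missing_rate = 0, het_error_rate = 0, seed = 17))
  g <- qc_filter(b$genotypes)$genotypes
  labels <- withr::with_seed(3, {
    pop <- factor(sample(rep(c("X", "Y"), each = 60)))
    sub <- factor(paste0(pop, sample(rep(1:3, 40))))
    list(pop = pop, sub = sub)
  })
  h <- hierarchical_f(g, labels$pop, labels$sub, n_perm = 60, seed = 2)
  expect_lt(abs(h$F["Total", "Population"]), 0.01)
  expect_lt(abs(h$F["Population", "Subpopulation"]), 0.01)
  expect_gt(min(h$tests$p), 0.05)
})

test_that("hierarchical_f detects structure and orders levels correctly", {
  b <- sim_medium()
  g <- qc_geno(b)
  h <- hierarchical_f(g, b$truth$pop, b$truth$subpop, n_perm = 30, seed = 4)
  expect_gt(h$F["Total", "Subpopulation"], h$F["Total", "Population"])
  expect_lt(h$tests$p[1], 0.05)
  # test (ii) permutes whole subpopulations: with 2 x 3 equal-sized
  # subpopulations 10% of permutations reproduce the observed partition
  # exactly, so the attainable p floor is ~0.1 even under perfect structure
  expect_lte(h$tests$p[2], 0.15)
  expect_equal(h$F["Population", "Population"], 0)
})

test_that("R_ST identities and stepwise-model contrast", {
  # identical size distributions in both groups: R_ST ~ 0 over loci
  big <- withr::with_seed(5, matrix(sample(8:20, 60 * 10, replace = TRUE),
                                    60, 10))
  part_big <- factor(rep(c("A", "B"), each = 30))
  expect_lt(abs(rst(big, part_big)$mean), 0.1)
  part <- factor(rep(c("A", "B"), each = 2))
  # fixed difference, zero within-group variance: R_ST = 1
  m1 <- cbind(l1 = c(10L, 10L, 14L, 14L))
  expect_equal(rst(m1, part)$mean, 1)
  # monomorphic locus skipped
  m2 <- cbind(l1 = c(10L, 10L, 14L, 14L), l2 = c(9L, 9L, 9L, 9L))
  expect_equal(rst(m2, part)$mean, 1)
})

test_that("partition correlation: self, attenuation, independence", {
  b <- sim_medium()
  g <- qc_geno(b)
  s <- wc_fst(g, b$truth$pop)
  expect_equal(partition_correlation(s, s), 1)
  # relabeling an increasing fraction of samples attenuates r monotonically
  rs <- sapply(c(0.1, 0.3, 0.5), function(fr) {
    withr::with_seed(11, {
      lab <- as.character(b$truth$pop)
      idx <- sample(length(lab), round(fr * length(lab)))
      lab[idx] <- sample(c("P1", "P2"), length(idx), replace = TRUE)
      partition_correlation(s, wc_fst(g, factor(lab)))
    })
  })
  expect_true(all(diff(rs) < 0))
  expect_error(partition_correlation(s[1:2, ], s[1:2, ]), "3 shared")
})
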