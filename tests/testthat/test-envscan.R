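test_that("env_pca: scaling invariants, degenerate inputs, loadings", {
  b <- sim_medium()
  ep <- env_pca(b$env)
  expect_true(all(abs(colMeans(ep$scaled)) < 1e-9))
  expect_true(all(abs(apply(ep$scaled, 2, stats::sd) - 1) < 1e-9))
  expect_equal(crossprod(ep$loadings), diag(ncol(ep$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # env built from 2 latent gradients: first two PCs carry most variance
  expect_gt(sum(ep$var_explained[1:2]), 0.5)
  expect_error(env_pca(cbind(b$env[, 1:3], const = 1)), "constant")
  # two perfectly correlated variables: a single nonzero eigenvalue
  x <- data.frame(a = rnorm(30)); x$b <- 2 * x$a
  ep2 <- env_pca(x)
  expect_lt(ep2$var_explained[2], 1e-9)
})

test_that("make_population_clusters sizes and count conservation", {
  b <- sim_medium()
  g <- qc_geno(b)
  p <- genotype_pca(g)
  ep <- env_pca(b$env)
  cl <- make_population_clusters(g, p$scores[, 1:2], ep$scores,
                                 target_mean_size = 17)
  expect_identical(cl$n_clusters, max(2L, as.integer(round(nrow(g) / 17))))
  expect_equal(sum(cl$sizes[, 1]), sum(!is.na(g[, 1])))
  expect_true(all(cl$counts <= cl$sizes))
  expect_identical(length(cl$labels), nrow(g))
  # 34 samples at target 17 -> 2 clusters
  cl2 <- make_population_clusters(g[1:34, ], p$scores[1:34, 1:2],
                                  ep$scores[1:34, , drop = FALSE], 17)
  expect_identical(cl2$n_clusters, 2L)
})

test_that("covariance model: independence null and convergence/recovery", {
  # (a) independent drift: off-diagonals ~ 0 relative to the diagonal
  # many-population regime (the analysis uses ~17 clusters); with few
  # populations the per-SNP mean centring alone forces off-diagonals toward
  # -1/(P-1) of the diagonal
  b1 <- simulate_dataset(sim_config(
    n_subpops_per_pop = 8, samples_per_subpop = 15, snps_per_group = 90,
    n_linkage_groups = 3, F_pop = 0, F_subpop = 0.1, region_specs = list(),
    missing_rate = 0, het_error_rate = 0, seed = 41))
  cl1 <- make_cluster_table(b1)
  cv1 <- estimate_covariance(cl1, n_iter = 3000, n_runs = 2, seed = 2)
  o <- cv1$omega; ut <- upper.tri(o)
  expect_lt(abs(mean(o[ut])), 0.1 * mean(diag(o)))

  # (b) nested structure: two-run element-wise correlation > 0.95 and
  # recovery of the generator kinship (winsorised-logit scale) > 0.8
  b2 <- simulate_dataset(sim_config(
    samples_per_subpop = 30, snps_per_group = 150, n_linkage_groups = 3,
    F_pop = 0.2, F_subpop = 0.1, region_specs = list(), missing_rate = 0,
    het_error_rate = 0, seed = 31))
  g2 <- qc_filter(b2$genotypes)$genotypes
  cl2 <- make_cluster_table(b2, g2)
  cv2 <- estimate_covariance(cl2, n_iter = 4000, n_runs = 2, seed = 2)
  expect_gt(cv2$run_correlation, 0.95)
  sf <- pmin(pmax(b2$truth$sub_freq[colnames(g2), ], 0.01), 0.99)
  truek <- stats::cov(log(sf / (1 - sf)))
  ut2 <- upper.tri(truek)
  expect_gt(stats::cor(cv2$omega[ut2], truek[ut2]), 0.8)
  expect_true(isSymmetric(cv2$omega))
  expect_true(all(eigen(cv2$omega, symmetric = TRUE)$values > 0))
})

test_that("bayes factors: null calibration and replicate averaging", {
  b <- simulate_dataset(sim_config(
    samples_per_subpop = 30, snps_per_group = 100, n_linkage_groups = 3,
    F_pop = 0.05, F_subpop = 0.05, region_specs = list(), missing_rate = 0,
    het_error_rate = 0, seed = 51))
  cl <- make_cluster_table(b)
  cv <- estimate_covariance(cl, n_iter = 2000, n_runs = 1, seed = 2)
  # orthogonal env vector (no SNP has any true effect)
  env <- withr::with_seed(1, stats::rnorm(cl$n_clusters))
  bf <- bayes_factor(cl, env, cv, n_draws = 300, n_estimates = 2, seed = 3)
  expect_lt(abs(stats::median(bf$log10_bf)), 0.2)
  expect_true(all(is.finite(bf$log10_bf)))
  expect_error(bayes_factor(cl, rep(1, cl$n_clusters), cv), "constant")
  # averaging more replicate estimates shrinks between-replicate variance
  b1a <- bayes_factor(cl, env, cv, n_draws = 150, n_estimates = 1, seed = 11)
  b1b <- bayes_factor(cl, env, cv, n_draws = 150, n_estimates = 1, seed = 12)
  b2a <- bayes_factor(cl, env, cv, n_draws = 150, n_estimates = 3, seed = 13)
  b2b <- bayes_factor(cl, env, cv, n_draws = 150, n_estimates = 3, seed = 14)
  expect_lt(stats::var(b2a$log10_bf - b2b$log10_bf),
            stats::var(b1a$log10_bf - b1b$log10_bf))
})

test_that("spa scores: flat surfaces, cline recovery, rotation invariance", {
  withr::with_seed(7, {
    n <- 500
    lonlat <- cbind(runif(n, 30, 60), runif(n, 30, 40))
    Z <- scale(lonlat)
    # flat: constant frequency in space
    g_flat <- matrix(rbinom(n, 1, 0.4), n, 1,
                     dimnames = list(paste0("s", 1:n), "flat"))
    s <- spa_score(g_flat, lonlat)
    expect_lt(s$score, 0.35)
    # logistic cline with a = (2, 0)
    p <- 1 / (1 + exp(-(2 * Z[, 1] + 0.2)))
    g_cline <- matrix(rbinom(n, 1, p), n, 1,
                      dimnames = list(paste0("s", 1:n), "cline"))
    sc <- spa_score(g_cline, lonlat)
    expect_lt(abs(sc$score - 2), 0.5)
    # rotation invariance of the score (whitened coordinates so the
    # internal standardisation is an exact no-op in both frames)
    Zw <- Z %*% backsolve(chol(cov(Z)), diag(2))
    th <- 0.7
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    s0 <- spa_score(g_cline, Zw)
    sr <- spa_score(g_cline, Zw %*% R)
    expect_lt(abs(sr$score - s0$score), 1e-6)
  })
})

test_that("spa equals a generic-optimizer fit of the same likelihood", {
  withr::with_seed(8, {
    for (i in 1:25) {
      n <- 80
      lonlat <- cbind(stats::rnorm(n), stats::rnorm(n))
      p <- 1 / (1 + exp(-(stats::rnorm(1) * scale(lonlat)[, 1])))
      g <- matrix(rbinom(n, 1, p), n, 1,
                  dimnames = list(paste0("s", 1:n), "m"))
      fit <- spa_score(g, lonlat, ridge = 1e-4)
      Z <- cbind(scale(lonlat), 1)
      nll <- function(b) {
        eta <- Z %*% b
        -sum(g[, 1] * eta - log1p(exp(eta))) + 1e-4 * sum(b^2) / 2
      }
      ob <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                         control = list(reltol = 1e-14, maxit = 1000))
      if (fit$separated) next
      expect_equal(fit$score, sqrt(sum(ob$par[1:2]^2)), tolerance = 1e-4)
    }
  })
})

test_that("outlier calling: percentile definition, ties, truncation", {
  withr::with_seed(9, x <- stats::runif(1000))
  out <- call_outliers(x, 95)
  expect_lt(abs(out$n_flagged - 50), 10)
  expect_true(all(x[out$flag] >= out$threshold))
  # ties at the threshold are all included
  xt <- c(rep(1, 10), seq(0, 0.9, length.out = 190))
  ot <- call_outliers(xt, 95)
  expect_gte(ot$n_flagged, 10)
  # F_ST convention: negatives truncated for thresholding only
  xf <- c(stats::rnorm(200, 0, 0.01), 0.5)
  of <- call_outliers(xf, 95, truncate_at_zero = TRUE)
  expect_true(of$flag[201])
  expect_gte(of$threshold, 0)
})

test_that("enrichment resampling: degenerate and enriched cases", {
  mk <- data.frame(marker_id = paste0("m", 1:40),
                   genic = rep(c(TRUE, FALSE), 20),
                   codon_effect = rep(c("synonymous", "nonsynonymous",
                                        "noncoding", "unknown"), 10),
                   stringsAsFactors = FALSE)
  # candidates = whole universe: observed ratio equals universe ratio, p ~ 1
  er <- enrichment_resample(mk$marker_id, mk, "genic_vs_nongenic",
                            n_resample = 200, seed = 1)
  expect_equal(er$observed, 1)
  expect_equal(er$p, 1)
  # all-genic candidates from a balanced universe: small p
  er2 <- enrichment_resample(mk$marker_id[mk$genic][1:8], mk,
                             "genic_vs_nongenic", n_resample = 500, seed = 2)
  expect_lt(er2$p, 0.05)
  expect_error(enrichment_resample(character(0), mk), "empty")
})
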