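#' Scale an environmental table and summarise it by PCA
#'
#' Variables are scaled to mean 0, SD 1 (a constant column is an error) and
#' decomposed by PCA. Loadings are reported so that thematic axes (e.g. a
#' temperature-dominant and a precipitation/altitude-dominant axis) are
#' identifiable; the sign convention makes each component's largest-magnitude
#' loading positive.
#'
#' @param env data.frame or matrix of environmental variables per sample
#'   (non-numeric columns such as `sample_id` are carried through as rownames).
#' @return list (class `env_pca`): `scores`, `loadings`, `var_explained`,
#'   `scaled` (the scaled matrix).
#' @export
env_pca <- function(env) {
  env <- as.data.frame(env)
  if ("sample_id" %in% names(env)) {
    rn <- env$sample_id
    env <- env[, setdiff(names(env), "sample_id"), drop = FALSE]
  } else rn <- rownames(env)
  x <- as.matrix(env)
  if (!is.numeric(x)) stop("environmental variables must be numeric")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant environmental column: ",
                          paste(colnames(x)[sds == 0], collapse = ", "))
  xs <- scale(x)
  pr <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  load <- pr$rotation
  scores <- pr$x
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(scores) <- rn
  structure(list(scores = scores, loadings = load,
                 var_explained = pr$sdev^2 / sum(pr$sdev^2),
                 scaled = `rownames<-`(unclass(xs), rn)),
            class = "env_pca")
}

#' Group samples into analysis populations for environmental association
#'
#' Ward-clusters the genotype PC scores into
#' `round(n_samples / target_mean_size)` clusters (the analysis populations
#' whose allele frequencies feed the covariance model), merges any cluster
#' with fewer than 2 samples into the nearest cluster by centroid distance,
#' and tabulates per-cluster derived-allele counts, sample sizes, and mean
#' environmental PC values.
#'
#' @param g post-QC genotype matrix.
#' @param pc_scores genotype PC scores (samples x significant components).
#' @param env_scores environmental PC score matrix (samples x PCs).
#' @param target_mean_size desired mean cluster size.
#' @return list (class `pop_freq_table`): `labels`, `counts` (clusters x
#'   markers derived counts), `sizes` (non-missing counts), `env` (clusters x
#'   env PCs means), `n_clusters`.
#' @export
make_population_clusters <- function(g, pc_scores, env_scores,
                                     target_mean_size = 17) {
  n <- nrow(g)
  k <- max(2L, as.integer(round(n / target_mean_size)))
  labels <- ward_clusters(pc_scores, k)$labels
  # merge clusters of size < 2 into the nearest centroid
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < 2]
    if (!length(small)) break
    cent <- rowsum(as.matrix(pc_scores), labels) / as.vector(table(labels))
    s <- small[1]
    others <- setdiff(rownames(cent), s)
    d <- colSums((t(cent[others, , drop = FALSE]) - cent[s, ])^2)
    warning("cluster ", s, " has fewer than 2 samples; merged into nearest")
    labels[labels == as.integer(s)] <- as.integer(names(which.min(d)))
  }
  labels <- as.integer(factor(labels))
  k <- max(labels)
  obs <- !is.na(g)
  y <- g; y[!obs] <- 0L
  counts <- rowsum(y * obs, labels)
  sizes <- rowsum(obs * 1, labels)
  envm <- rowsum(as.matrix(env_scores), labels) / as.vector(table(labels))
  structure(list(labels = labels, counts = counts, sizes = sizes,
                 env = envm, n_clusters = k),
            class = "pop_freq_table")
}

# logit of boundary-shrunken frequency
shrunk_logit <- function(c, n) logit((c + 0.5) / (n + 1))

#' Estimate the population allele-frequency covariance matrix
#'
#' Bayenv-style null model: per SNP l the transformed population frequencies
#' `x_l` (logit of the shrunken frequency `(c + 0.5)/(n + 1)`) are
#' `MVN(mu_l * 1, Omega)`; observed derived counts are
#' `Binomial(n_il, invlogit(x_il))`. A Metropolis-within-Gibbs sampler
#' updates the latent `x` (random-walk Metropolis, vectorised over SNPs), the
#' per-SNP mean `mu_l` (conjugate normal), and `Omega` (conjugate
#' inverse-Wishart). The estimate is the posterior mean of Omega, averaged
#' over `n_runs` independent runs; the element-wise correlation between runs
#' is returned as a convergence diagnostic.
#'
#' @param freqs a [make_population_clusters()] result (or any list with
#'   `counts` and `sizes` matrices, populations x markers).
#' @param n_iter sweeps per run (first half discarded as burn-in).
#' @param n_runs independent runs.
#' @param seed integer seed.
#' @param proposal_sd random-walk SD for latent frequency updates.
#' @param x_reps latent-frequency Metropolis repetitions per sweep (extra
#'   mixing relative to the conjugate mean/covariance updates).
#' @return list (class `cov_model`): `omega` (mean across runs), `run_omegas`,
#'   `run_correlation`, `mu` (posterior-mean per-SNP means from run 1),
#'   `settings`.
#' @export
estimate_covariance <- function(freqs, n_iter = 30000, n_runs = 2, seed = 1L,
                                proposal_sd = 0.3, x_reps = 3L) {
  counts <- freqs$counts; sizes <- freqs$sizes
  P <- nrow(counts); L <- ncol(counts)
  if (P < 2) stop("need at least 2 populations")
  if (L < 50) warning("fewer than 50 SNPs: covariance estimate will be noisy")
  runs <- lapply(seq_len(n_runs), function(r)
    withr::with_seed(as.integer(seed) + 7919L * (r - 1L),
                     covariance_run(counts, sizes, n_iter, proposal_sd,
                                    x_reps)))
  omegas <- lapply(runs, `[[`, "omega")
  omega <- Reduce(`+`, omegas) / n_runs
  run_cor <- if (n_runs >= 2)
    stats::cor(as.vector(omegas[[1]]), as.vector(omegas[[2]])) else NA_real_
  structure(list(omega = omega, run_omegas = omegas,
                 run_correlation = run_cor, mu = runs[[1]]$mu,
                 settings = list(n_iter = n_iter, n_runs = n_runs,
                                 proposal_sd = proposal_sd)),
            class = "cov_model")
}

covariance_run <- function(counts, sizes, n_iter, proposal_sd, x_reps = 3L) {
  P <- nrow(counts); L <- ncol(counts)
  x <- shrunk_logit(counts, sizes)              # P x L latent init
  mu <- colMeans(x)
  # proper prior anchoring the per-SNP ancestral mean: without it the common
  # mode of Omega and the level of mu are confounded (the likelihood never
  # sees mu directly) and the sampler wanders along that ridge
  mu0 <- shrunk_logit(colSums(counts), colSums(sizes))
  tau2 <- 1.5^2
  omega <- stats::cov(t(x)) + diag(1e-3, P)
  nu0 <- P + 2                                  # inverse-Wishart prior df
  psi0 <- diag(0.1, P)
  burn <- n_iter %/% 2
  osum <- matrix(0, P, P); musum <- numeric(L); kept <- 0L
  oinv <- solve(omega)
  loglik_bin <- function(xm) {
    pm <- invlogit(xm)
    counts * log(pm) + (sizes - counts) * log1p(-pm)
  }
  llx <- loglik_bin(x)
  for (sweep in seq_len(n_iter)) {
    ## latent x: random-walk Metropolis, one population at a time, vectorised
    ## over SNPs using the conditional normal given the other populations;
    ## repeated x_reps times per sweep to improve mixing relative to the
    ## conjugate mu/Omega updates
    for (rep in seq_len(x_reps)) for (i in seq_len(P)) {
      prop <- x[i, ] + stats::rnorm(L, 0, proposal_sd)
      dev <- sweep(x, 2, mu)                    # P x L deviations
      cond_mean <- mu - colSums(oinv[i, -i, drop = FALSE] %*%
                                  dev[-i, , drop = FALSE]) / oinv[i, i]
      lp_old <- -0.5 * oinv[i, i] * (x[i, ] - cond_mean)^2
      lp_new <- -0.5 * oinv[i, i] * (prop - cond_mean)^2
      pm_new <- invlogit(prop)
      ll_new <- counts[i, ] * log(pm_new) + (sizes[i, ] - counts[i, ]) * log1p(-pm_new)
      acc <- log(stats::runif(L)) < (lp_new + ll_new - lp_old - llx[i, ])
      x[i, acc] <- prop[acc]
      llx[i, acc] <- ll_new[acc]
    }
    ## mu: conjugate normal with the anchoring prior N(mu0, tau2)
    prec <- sum(oinv) + 1 / tau2
    mu <- (colSums(oinv %*% x) + mu0 / tau2) / prec +
      stats::rnorm(L, 0, sqrt(1 / prec))
    ## omega: conjugate inverse-Wishart
    dev <- sweep(x, 2, mu)
    S <- tcrossprod(dev)
    W <- tryCatch(stats::rWishart(1, nu0 + L, solve(psi0 + S))[, , 1],
                  error = function(e) NULL)
    if (is.null(W)) {
      warning("singular covariance update; jittered")
      W <- stats::rWishart(1, nu0 + L,
                           solve(psi0 + S + diag(1e-6, P)))[, , 1]
    }
    omega <- solve(W)
    oinv <- W
    if (sweep > burn) {
      # Rao-Blackwellised accumulation: conditional posterior mean of Omega
      # given (x, mu) instead of the raw inverse-Wishart draw
      osum <- osum + (psi0 + S) / (nu0 + L - P - 1)
      musum <- musum + mu
      kept <- kept + 1L
    }
  }
  list(omega = osum / kept, mu = musum / kept)
}

#' Environmental-association Bayes factors
#'
#' For each SNP, the Bayes factor compares a model in which the transformed
#' population frequencies follow `MVN(mu 1 + beta * env, Omega)` (beta given a
#' Uniform prior on `beta_range`) against the null `beta = 0`. The marginal
#' likelihood is integrated numerically over a beta grid; for each beta the
#' latent-frequency integral is approximated by importance sampling from the
#' MVN prior (shared noise draws across SNPs and grid points), with mu set to
#' its generalized-least-squares profile value. The per-SNP BF is averaged
#' over `n_estimates` independent estimations (their SD is returned).
#'
#' @param freqs a [make_population_clusters()] result.
#' @param env_pc numeric vector: the environmental PC value per population
#'   (standardised internally).
#' @param cov a [estimate_covariance()] result.
#' @param n_draws importance-sampling draws per estimate.
#' @param n_estimates replicate estimations averaged per SNP.
#' @param beta_range Uniform prior support for beta.
#' @param n_grid beta grid size.
#' @param seed integer seed.
#' @return data.frame (class `bf_scan`): marker, log10 BF mean and SD.
#' @export
bayes_factor <- function(freqs, env_pc, cov, n_draws = 2000, n_estimates = 5,
                         beta_range = c(-0.3, 0.3), n_grid = 11, seed = 1L) {
  counts <- freqs$counts; sizes <- freqs$sizes
  P <- nrow(counts); L <- ncol(counts)
  env <- as.numeric(env_pc)
  if (length(env) != P) stop("env_pc must have one value per population")
  if (stats::sd(env) == 0) stop("environmental vector constant across populations")
  env <- as.numeric(scale(env))
  omega <- cov$omega
  ch <- chol(omega)
  oinv <- chol2inv(ch)
  denom <- sum(oinv)
  grid <- seq(beta_range[1], beta_range[2], length.out = n_grid)
  if (!any(grid == 0)) grid <- sort(c(grid, 0))
  x0 <- shrunk_logit(counts, sizes)             # P x L observed transform
  phat <- (counts + 0.5) / (sizes + 1)
  Vobs <- 1 / (sizes * phat * (1 - phat))       # approx obs variance of x0
  null_i <- which(grid == 0)
  bfs <- matrix(NA_real_, L, n_estimates)
  for (est in seq_len(n_estimates)) {
    z <- withr::with_seed(as.integer(seed) + 6007L * (est - 1L),
                          matrix(stats::rnorm(n_draws * P), n_draws, P))
    logml <- matrix(NA_real_, length(grid), L)
    for (l in seq_len(L)) {
      ## importance proposal: Gaussian posterior approximation combining the
      ## MVN prior with a normal approximation N(x0, Vobs) of the binomial
      ## likelihood; exact binomial likelihood enters through the weights.
      Vinv <- diag(1 / Vobs[, l], P)
      Spost <- chol2inv(chol(oinv + Vinv))
      chp <- chol(Spost)
      eps <- z %*% chp                          # draws x P, N(0, Spost)
      lq <- -0.5 * rowSums((eps %*% chol2inv(chp)) * eps)  # proposal logdens (up to const)
      for (bi in seq_along(grid)) {
        shift <- grid[bi] * env
        mu_hat <- sum(oinv %*% (x0[, l] - shift)) / denom  # GLS profile mu
        m_pr <- mu_hat + shift                             # prior mean
        m_post <- as.numeric(Spost %*% (oinv %*% m_pr + Vinv %*% x0[, l]))
        xs <- sweep(eps, 2, m_post, "+")
        dev <- sweep(xs, 2, m_pr)
        lpri <- -0.5 * rowSums((dev %*% oinv) * dev)
        llik <- xs %*% counts[, l] - log1p(exp(xs)) %*% sizes[, l]
        lw <- lpri + as.numeric(llik) - lq
        mx <- max(lw)
        logml[bi, l] <- mx + log(mean(exp(lw - mx)))
      }
    }
    mx <- apply(logml, 2, max)
    log_alt <- mx + log(colMeans(exp(sweep(logml, 2, mx))))  # uniform over grid
    bfs[, est] <- (log_alt - logml[null_i, ]) / log(10)
  }
  out <- data.frame(marker_id = colnames(counts), log10_bf = rowMeans(bfs),
                    log10_bf_sd = apply(bfs, 1, stats::sd),
                    stringsAsFactors = FALSE)
  class(out) <- c("bf_scan", "data.frame")
  out
}

#' Spatial allele-frequency gradient (SPA-style) scores
#'
#' Fits, per SNP, a logistic allele-frequency surface
#' `f(x) = 1 / (1 + exp(-(a . x + b)))` over standardised (longitude,
#' latitude) by maximising the Bernoulli likelihood of the haploid calls
#' (Newton iterations with a small ridge; complete spatial separation is
#' flagged and returned with the ridge-regularised fit). The SPA score is
#' `||a||`, which is invariant to rotations of the coordinate frame.
#'
#' @param g post-QC genotype matrix.
#' @param lonlat n x 2 matrix of (longitude, latitude).
#' @param ridge ridge penalty added to the Newton Hessian.
#' @param max_iter Newton iterations.
#' @return data.frame (class `spa_scan`): marker, a1, a2, b, score,
#'   separation flag.
#' @export
spa_score <- function(g, lonlat, ridge = 1e-4, max_iter = 50) {
  check_geno(g, allow_het = FALSE)
  lonlat <- as.matrix(lonlat)
  stopifnot(nrow(lonlat) == nrow(g), ncol(lonlat) == 2)
  Z <- scale(lonlat)
  out <- data.frame(marker_id = colnames(g), a1 = NA_real_, a2 = NA_real_,
                    b = NA_real_, score = NA_real_, separated = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(g))) {
    y <- g[, j]
    keep <- !is.na(y)
    fit <- logistic_newton(cbind(Z[keep, , drop = FALSE], 1), y[keep],
                           ridge, max_iter)
    out$a1[j] <- fit$coef[1]; out$a2[j] <- fit$coef[2]; out$b[j] <- fit$coef[3]
    out$score[j] <- sqrt(sum(fit$coef[1:2]^2))
    out$separated[j] <- fit$separated
  }
  class(out) <- c("spa_scan", "data.frame")
  out
}

logistic_newton <- function(X, y, ridge, max_iter) {
  beta <- numeric(ncol(X))
  sep <- FALSE
  step <- rep(Inf, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- invlogit(eta)
    w <- p * (1 - p)
    grad <- crossprod(X, y - p) - ridge * beta
    H <- crossprod(X, X * w) + diag(ridge, ncol(X))
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) { sep <- TRUE; break }
    step <- as.numeric(step)
    # damp huge steps (near-separation)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  if (max(abs(step)) > 1e-4) sep <- TRUE
  if (sqrt(sum(beta[-length(beta)]^2)) > 20) sep <- TRUE
  list(coef = beta, separated = sep)
}

#' Empirical-percentile outlier calling
#'
#' Flags values at or above the genome-wide empirical percentile threshold
#' (ties at the threshold are included). For F_ST tracks, negative estimates
#' are truncated at 0 before thresholding (display convention); the values
#' themselves are not modified.
#'
#' @param x numeric statistic per SNP (>= 100 finite values recommended).
#' @param percentile percentile (e.g. 95 or 99).
#' @param truncate_at_zero truncate negatives before computing the threshold.
#' @return list: `flag` (logical per entry), `threshold`, `n_flagged`.
#' @export
call_outliers <- function(x, percentile = 95, truncate_at_zero = FALSE) {
  v <- x
  if (truncate_at_zero) v <- pmax(v, 0)
  if (sum(is.finite(v)) < 100)
    warning("fewer than 100 finite values: percentile threshold unstable")
  thr <- percentile_threshold(v, percentile)
  flag <- !is.na(v) & v >= thr
  list(flag = flag, threshold = thr, n_flagged = sum(flag))
}

#' Region-level outlier summary
#'
#' @param flag logical outlier flags per marker (in marker-table order of
#'   `marker_ids`).
#' @param marker_ids marker ids matching `flag`.
#' @param markers marker table.
#' @param region `(linkage_group, cM_lo, cM_hi)`.
#' @return list: `n_markers`, `n_flagged`, `fraction`.
#' @export
region_outlier_summary <- function(flag, marker_ids, markers, region) {
  region <- as_region(region)
  mk <- markers[match(marker_ids, markers$marker_id), ]
  inside <- mk$linkage_group == region$linkage_group &
    mk$cM >= region$cM_lo & mk$cM <= region$cM_hi
  list(n_markers = sum(inside), n_flagged = sum(flag & inside),
       fraction = sum(flag & inside) / sum(inside))
}

#' Enrichment of candidate SNPs by annotation, via resampling
#'
#' Observed ratio (genic/nongenic or nonsynonymous/synonymous) among the
#' candidates, compared with ratios in `n_resample` draws of equal size
#' without replacement from the SNP universe.
#' `p = proportion of null ratios >= observed` (one-sided enrichment); a
#' resample with a zero denominator yields `+Inf`, ordered above all finite
#' ratios.
#'
#' @param candidates character vector of candidate marker ids.
#' @param markers marker table with `genic` and `codon_effect` columns.
#' @param contrast `"genic_vs_nongenic"` or `"nonsyn_vs_syn"`.
#' @param n_resample resampling draws.
#' @param seed optional seed.
#' @param universe marker ids to draw from (default: all markers in the
#'   table, so region- or centromere-scoped universes can be passed).
#' @return list: `observed`, `null` (vector), `p`.
#' @export
enrichment_resample <- function(candidates, markers,
                                contrast = c("genic_vs_nongenic", "nonsyn_vs_syn"),
                                n_resample = 1000, seed = NULL,
                                universe = NULL) {
  contrast <- match.arg(contrast)
  if (!length(candidates)) stop("empty candidate list")
  universe <- universe %||% markers$marker_id
  mk <- markers[match(universe, markers$marker_id), ]
  num_den <- function(ids) {
    m <- mk[match(ids, mk$marker_id), ]
    if (contrast == "genic_vs_nongenic") {
      c(sum(m$genic, na.rm = TRUE), sum(!m$genic, na.rm = TRUE))
    } else {
      c(sum(m$codon_effect == "nonsynonymous", na.rm = TRUE),
        sum(m$codon_effect == "synonymous", na.rm = TRUE))
    }
  }
  ratio <- function(nd) if (nd[2] == 0) Inf else nd[1] / nd[2]
  obs <- ratio(num_den(candidates))
  k <- length(candidates)
  null <- with_seed_if(seed, vapply(seq_len(n_resample), function(b)
    ratio(num_den(sample(universe, k))), 0))
  list(observed = obs, null = null, p = mean(null >= obs))
}
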