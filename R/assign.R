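#' Bayesian genetic assignment (no-admixture Gibbs sampler)
#'
#' Simplified re-implementation of the no-admixture, uncorrelated-frequencies
#' assignment model: each sample carries a single cluster label `z_i`; each
#' cluster has independent Dirichlet(1) allele-frequency priors at every locus
#' (Beta(1,1) for biallelic SNPs). The Gibbs sampler alternates sampling
#' cluster frequencies given labels and labels given frequencies; missing
#' calls contribute no likelihood term. The per-run membership matrix Q is the
#' fraction of post-burn-in sweeps each sample spent in each cluster.
#' Replicate runs are label-aligned and averaged by [align_runs()].
#'
#' Input is either a genotype matrix (biallelic, codes 0/1/NA) or a
#' [build_haplotypes()] result (multi-allelic window codes).
#'
#' @param data genotype matrix or `haplo_blocks`.
#' @param K number of clusters.
#' @param n_burn,n_iter burn-in and retained sweeps. Defaults are test-scale;
#'   publication-scale runs use 1e5/1e5.
#' @param n_runs replicate runs (different chains).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed (each run derives its own stream).
#' @param keep_z also store the post-burn-in label draws per run (for
#'   posterior diagnostics; memory grows with `n * n_iter / thin`).
#' @return list (class `assign_result`): `K`, `runs` (list of per-run lists
#'   with `Q`, `loglik` trace, final frequency draws), `Q` (aligned consensus),
#'   `labels` (hard argmax labels), `similarity` (mean pairwise run agreement
#'   after alignment).
#' @export
gibbs_assign <- function(data, K, n_burn = 2000, n_iter = 2000, n_runs = 3,
                         thin = 1L, seed = 1L, keep_z = FALSE) {
  x <- assign_input(data)
  n <- nrow(x)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of samples")
  if (K == 1L) {
    Q <- matrix(1, n, 1, dimnames = list(rownames(x), "C1"))
    return(structure(list(K = 1L, runs = list(), Q = Q,
                          labels = rep(1L, n), similarity = 1),
                     class = "assign_result"))
  }
  runs <- lapply(seq_len(n_runs), function(r)
    withr::with_seed(as.integer(seed) + 104729L * (r - 1L),
                     gibbs_run(x, K, n_burn, n_iter, thin, keep_z)))
  aligned <- align_runs(lapply(runs, `[[`, "Q"))
  structure(list(K = as.integer(K), runs = runs, Q = aligned$Q,
                 labels = max.col(aligned$Q, ties.method = "first"),
                 similarity = aligned$similarity),
            class = "assign_result")
}

# normalize input to an integer matrix of allele codes 1..A_l (NA missing)
assign_input <- function(data) {
  if (inherits(data, "haplo_blocks")) return(data$codes)
  check_geno(data, allow_het = FALSE)
  data + 1L
}

gibbs_run <- function(x, K, n_burn, n_iter, thin = 1L, keep_z = FALSE) {
  n <- nrow(x); L <- ncol(x)
  zkeep <- if (keep_z) matrix(NA_integer_, n, (n_iter %/% thin)) else NULL
  n_alleles <- apply(x, 2, max, na.rm = TRUE)
  biallelic <- all(n_alleles <= 2)
  z <- sample.int(K, n, replace = TRUE)
  qsum <- matrix(0, n, K)
  loglik <- numeric(n_burn + n_iter)
  kept <- 0L
  if (biallelic) {
    x1 <- (x == 2L) * 1; x1[is.na(x)] <- 0
    x0 <- (x == 1L) * 1; x0[is.na(x)] <- 0
    for (sweep in seq_len(n_burn + n_iter)) {
      Z <- matrix(0, K, n); Z[cbind(z, seq_len(n))] <- 1
      d1 <- Z %*% x1                                # K x L derived counts
      d0 <- Z %*% x0
      p <- matrix(stats::rbeta(K * L, 1 + d1, 1 + d0), K, L)
      p <- clamp(p, 1e-12, 1 - 1e-12)
      ll <- x1 %*% t(log(p)) + x0 %*% t(log(1 - p)) # n x K
      mx <- ll[cbind(seq_len(n), max.col(ll, ties.method = "first"))]
      pr <- exp(ll - mx)
      pr <- pr / rowSums(pr)
      u <- stats::runif(n)
      z <- max.col(-(t(apply(pr, 1, cumsum)) < u) * 1,
                   ties.method = "first")           # inverse-cdf draw
      loglik[sweep] <- sum(ll[cbind(seq_len(n), z)])
      if (sweep > n_burn && (sweep - n_burn) %% thin == 0L) {
        qsum[cbind(seq_len(n), z)] <- qsum[cbind(seq_len(n), z)] + 1
        kept <- kept + 1L
        if (keep_z) zkeep[, kept] <- z
      }
    }
  } else {
    for (sweep in seq_len(n_burn + n_iter)) {
      ll <- matrix(0, n, K)
      for (l in seq_len(L)) {
        A <- n_alleles[l]
        cnt <- matrix(0, K, A)
        obs <- !is.na(x[, l])
        if (any(obs))
          cnt <- cnt + unclass(table(factor(z[obs], seq_len(K)),
                                     factor(x[obs, l], seq_len(A))))
        gm <- matrix(stats::rgamma(K * A, 1 + cnt), K, A)
        p <- gm / rowSums(gm)
        lp <- log(clamp(p, 1e-12, 1))
        li <- matrix(0, n, K)
        li[obs, ] <- t(lp)[x[obs, l], , drop = FALSE]
        ll <- ll + li
      }
      mx <- ll[cbind(seq_len(n), max.col(ll, ties.method = "first"))]
      pr <- exp(ll - mx); pr <- pr / rowSums(pr)
      u <- stats::runif(n)
      z <- max.col(-(t(apply(pr, 1, cumsum)) < u) * 1,
                   ties.method = "first")
      loglik[sweep] <- sum(ll[cbind(seq_len(n), z)])
      if (sweep > n_burn && (sweep - n_burn) %% thin == 0L) {
        qsum[cbind(seq_len(n), z)] <- qsum[cbind(seq_len(n), z)] + 1
        kept <- kept + 1L
        if (keep_z) zkeep[, kept] <- z
      }
    }
  }
  Q <- qsum / kept
  dimnames(Q) <- list(rownames(x), paste0("C", seq_len(K)))
  list(Q = Q, loglik = loglik, n_burn = n_burn, n_iter = n_iter, z = zkeep)
}

#' Align replicate assignment runs (label switching)
#'
#' Greedy pairwise alignment in the CLUMPP spirit: run 1 fixes the labels; for
#' every other run the column permutation maximizing the sum of sample-wise
#' dot products with run 1 is chosen (exhaustive over K! permutations for
#' K <= 8, greedy column matching above). The consensus is the mean of the
#' aligned Q matrices; the reported similarity is the mean over runs of
#' `1 - ||Q1 - Qr P|| / sqrt(2 n)` (1 for identical runs).
#'
#' @param qs list of samples x K membership matrices.
#' @return list with `Q` (consensus), `perms` (chosen permutation per run),
#'   `similarity`.
#' @export
align_runs <- function(qs) {
  stopifnot(length(qs) >= 1)
  K <- ncol(qs[[1]])
  n <- nrow(qs[[1]])
  if (!all(vapply(qs, function(q) all(dim(q) == c(n, K)), TRUE)))
    stop("all Q matrices must share dimensions")
  ref <- qs[[1]]
  perm_list <- vector("list", length(qs))
  perm_list[[1]] <- seq_len(K)
  aligned <- list(ref)
  sims <- numeric(length(qs)); sims[1] <- 1
  for (r in seq_along(qs)[-1]) {
    S <- crossprod(ref, qs[[r]])            # K x K dot products
    if (K <= 8) {
      pm <- perms(K)
      scores <- apply(pm, 1, function(p) sum(S[cbind(seq_len(K), p)]))
      best <- pm[which.max(scores), ]
    } else {
      # greedy matching for large K
      best <- integer(K); taken <- logical(K)
      for (k in order(-apply(S, 1, max))) {
        j <- which.max(ifelse(taken, -Inf, S[k, ]))
        best[k] <- j; taken[j] <- TRUE
      }
    }
    qa <- qs[[r]][, best, drop = FALSE]
    colnames(qa) <- colnames(ref)
    aligned[[r]] <- qa
    perm_list[[r]] <- best
    sims[r] <- 1 - norm(ref - qa, "F") / sqrt(2 * n)
  }
  Q <- Reduce(`+`, aligned) / length(aligned)
  list(Q = Q, perms = perm_list, similarity = mean(sims))
}

#' Informativeness for assignment (I_n)
#'
#' For one locus with per-cluster allele frequencies `p_ij` (cluster i,
#' allele j) and `pbar_j = mean_i p_ij`:
#' `I_n = sum_j ( -pbar_j log pbar_j + sum_i p_ij / K * log p_ij )`
#' with `0 log 0 = 0`. `I_n` is 0 for identical cluster frequencies and at
#' most `log K`.
#'
#' @param freqs K x A matrix of allele frequencies (rows sum to 1).
#' @return I_n in nats.
#' @export
informativeness <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (any(abs(rowSums(freqs) - 1) > 1e-6))
    stop("cluster allele frequencies must sum to 1")
  K <- nrow(freqs)
  pbar <- colMeans(freqs)
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  sum(-xlx(pbar)) + sum(xlx(freqs)) / K
}

#' Per-locus informativeness scan
#'
#' Computes [informativeness()] at every locus from cluster allele frequencies
#' estimated either from hard labels (default, matching Infocalc usage) or
#' weighted by membership coefficients.
#'
#' @param data genotype matrix or `haplo_blocks`.
#' @param assignment either a factor/vector of hard labels or an
#'   `assign_result` (whose consensus Q is used when `weighted = TRUE`).
#' @param weighted use Q-weighted frequency estimates.
#' @return data.frame locus, In.
#' @export
informativeness_scan <- function(data, assignment, weighted = FALSE) {
  x <- assign_input(data)
  if (inherits(assignment, "assign_result")) {
    Q <- assignment$Q
    labels <- assignment$labels
  } else {
    labels <- as.integer(as.factor(assignment))
    Q <- NULL
    if (weighted) stop("weighted scan needs an assign_result")
  }
  K <- if (weighted) ncol(Q) else max(labels)
  vals <- vapply(seq_len(ncol(x)), function(l) {
    obs <- !is.na(x[, l])
    A <- max(x[obs, l])
    f <- matrix(0, K, A)
    for (k in seq_len(K)) {
      w <- if (weighted) Q[obs, k] else (labels[obs] == k) * 1
      cnt <- vapply(seq_len(A), function(a) sum(w * (x[obs, l] == a)), 0)
      if (sum(cnt) == 0) return(NA_real_)
      f[k, ] <- cnt / sum(cnt)
    }
    informativeness(f)
  }, 0)
  data.frame(locus = colnames(x) %||% seq_len(ncol(x)), In = vals,
             stringsAsFactors = FALSE)
}

#' Assignment stability under region masking
#'
#' Runs [gibbs_assign()] on the full marker set and on the set excluding the
#' given regions' markers, aligns the two consensus Q matrices, and reports
#' per-sample membership changes.
#'
#' @param g genotype matrix.
#' @param markers marker table.
#' @param regions list of `(linkage_group, cM_lo, cM_hi)` regions to mask.
#' @param K clusters.
#' @param ... passed to [gibbs_assign()].
#' @return list with `full`, `masked` (assign_results), `delta_q` (per-sample
#'   max |Q difference|), `n_label_changes`.
#' @export
masked_assignment_check <- function(g, markers, regions, K = 2, ...) {
  check_markers(markers, g)
  mask <- rep(FALSE, ncol(g))
  mk <- markers[match(colnames(g), markers$marker_id), ]
  for (r in regions) {
    r <- as_region(r)
    mask <- mask | (mk$linkage_group == r$linkage_group &
                    mk$cM >= r$cM_lo & mk$cM <= r$cM_hi)
  }
  if (sum(!mask) < 50)
    warning("fewer than 50 markers remain after masking")
  full <- gibbs_assign(g, K, ...)
  masked <- gibbs_assign(g[, !mask, drop = FALSE], K, ...)
  al <- align_runs(list(full$Q, masked$Q))
  qm <- al$Q * 2 - full$Q                      # recovered aligned masked Q
  delta <- apply(abs(qm - full$Q), 1, max)
  list(full = full, masked = masked, delta_q = delta,
       n_label_changes = sum(max.col(full$Q, ties.method = "first") !=
         max.col(qm, ties.method = "first")),
       n_masked = sum(mask))
}
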