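#' Allele-sharing genetic distance
#'
#' `1 - proportion of shared alleles` over markers co-called in both samples.
#'
#' @param g post-QC genotype matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
allele_sharing_dist <- function(g) {
  check_geno(g, allow_het = FALSE)
  x <- g; x[is.na(x)] <- 0
  obs <- !is.na(g)
  ncc <- tcrossprod(obs * 1)
  same <- tcrossprod(x * obs) + tcrossprod((1 - x) * obs)
  d <- 1 - same / ncc
  diag(d) <- 0
  dimnames(d) <- list(rownames(g), rownames(g))
  d
}

#' Mantel test
#'
#' Pearson correlation of the upper-triangle entries of two distance matrices;
#' significance by jointly permuting the rows and columns of the second
#' matrix. `p = (1 + #\{permuted >= observed\}) / (1 + n_perm)`.
#'
#' @param dA,dB square symmetric matrices over the same samples (n >= 4).
#' @param n_perm number of permutations.
#' @param seed optional seed.
#' @return list with `statistic` and `p`.
#' @export
mantel <- function(dA, dB, n_perm = 999, seed = NULL) {
  stopifnot(all(dim(dA) == dim(dB)), nrow(dA) >= 4)
  ut <- upper.tri(dA)
  a <- dA[ut]
  if (stats::sd(a) == 0 || stats::sd(dB[ut]) == 0)
    stop("constant distance matrix: Mantel statistic undefined")
  obs <- stats::cor(a, dB[ut])
  n <- nrow(dA)
  with_seed_if(seed, {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      i <- sample.int(n)
      if (stats::cor(a, dB[i, i][ut]) >= obs) ge <- ge + 1L
    }
    list(statistic = obs, p = (1 + ge) / (1 + n_perm), n_perm = n_perm)
  })
}

#' Mean-impute missing calls per marker
#'
#' @param g post-QC genotype matrix.
#' @return numeric matrix with missing calls replaced by marker means.
#' @export
geno_impute <- function(g) {
  check_geno(g, allow_het = FALSE)
  p <- colMeans(g, na.rm = TRUE)
  x <- g
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- p[idx[, 2]]
  x
}

#' PCA of a genotype matrix
#'
#' Missing calls are mean-imputed per marker; markers are centered and
#' optionally scaled by `sqrt(p(1-p))`. Scores carry a deterministic sign
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param g post-QC genotype matrix (n >= 2).
#' @param scale_freq divide each marker by its binomial SD.
#' @return list (class `geno_pca`): `scores`, `loadings`, `eigenvalues`
#'   (variances of the components), `var_explained`.
#' @export
genotype_pca <- function(g, scale_freq = FALSE) {
  check_geno(g, allow_het = FALSE)
  if (nrow(g) < 2) stop("need at least 2 samples")
  p <- colMeans(g, na.rm = TRUE)
  x <- sweep(geno_impute(g), 2, p)
  if (scale_freq) {
    s <- sqrt(p * (1 - p))
    s[s == 0] <- 1
    x <- sweep(x, 2, s, "/")
  }
  sv <- svd(x)
  k <- sum(sv$d > max(sv$d) * 1e-10)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  load <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  ev <- sv$d[seq_len(k)]^2 / (nrow(x) - 1)
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(k)))
  dimnames(load) <- list(colnames(g), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = load, eigenvalues = ev,
                 var_explained = ev / sum(sv$d^2 / (nrow(x) - 1))),
            class = "geno_pca")
}

#' Velicer's minimum average partial (MAP) test
#'
#' For k = 0..k_max the first k principal components are partialled out of the
#' correlation matrix and the average squared off-diagonal partial correlation
#' is computed; the returned component count minimizes that average. 0 means
#' no component passes (pure noise).
#'
#' @param x data matrix (columns are variables, >= 3).
#' @param k_max maximum components examined.
#' @return list with `n_components` and `map` (the criterion per k).
#' @export
velicer_map <- function(x, k_max = NULL) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("need at least 3 columns")
  keep <- apply(x, 2, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  R <- stats::cor(x)
  e <- eigen(R, symmetric = TRUE)
  p <- ncol(R)
  if (is.null(k_max)) k_max <- min(p - 2L, nrow(x) - 2L)
  crit <- numeric(k_max + 1)
  off <- function(M) {
    d <- sqrt(diag(M))
    if (any(d <= 1e-12)) return(NA_real_)
    P <- M / tcrossprod(d)
    mean(P[upper.tri(P)]^2)
  }
  crit[1] <- mean(R[upper.tri(R)]^2)
  for (k in seq_len(k_max)) {
    Rk <- R - e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(e$values[seq_len(k)], k) %*% t(e$vectors[, seq_len(k), drop = FALSE])
    crit[k + 1] <- off(Rk)
  }
  crit_ok <- crit
  crit_ok[!is.finite(crit_ok)] <- Inf
  list(n_components = which.min(crit_ok) - 1L, map = crit)
}

#' Ward clustering of PC scores
#'
#' Agglomerative minimum-variance clustering (`hclust` method `ward.D2`) on
#' Euclidean distances.
#'
#' @param scores numeric matrix (samples x components).
#' @param n_clusters desired cluster count (<= n).
#' @return list with `labels` (integer vector) and `tree` (hclust object).
#' @export
ward_clusters <- function(scores, n_clusters) {
  scores <- as.matrix(scores)
  if (n_clusters > nrow(scores)) stop("n_clusters exceeds sample count")
  tree <- stats::hclust(stats::dist(scores), method = "ward.D2")
  list(labels = stats::cutree(tree, k = n_clusters), tree = tree)
}

#' Procrustes superimposition of PC scores onto geography
#'
#' Least-squares similarity transform (rotation + uniform scale +
#' translation; reflection disallowed unless `allow_reflection`) of the 2-D PC
#' configuration onto lon/lat, after centering and unit-norm scaling of both
#' configurations. Reports the counterclockwise rotation angle in degrees in
#' [0, 360), the scale, the minimized normalized residual `D`, and the
#' similarity statistic `t0 = sqrt(1 - D)`.
#'
#' @param pc2 n x 2 score matrix.
#' @param lonlat n x 2 matrix of (longitude, latitude).
#' @param allow_reflection permit an improper rotation.
#' @return list (class `procrustes_fit`): `angle_deg`, `rotation`, `scale`,
#'   `translation`, `D`, `t0`.
#' @export
procrustes_to_geography <- function(pc2, lonlat, allow_reflection = FALSE) {
  X <- as.matrix(pc2); Y <- as.matrix(lonlat)
  stopifnot(ncol(X) == 2, ncol(Y) == 2, nrow(X) == nrow(Y), nrow(X) >= 3)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  nx <- sqrt(sum(Xc^2)); ny <- sqrt(sum(Yc^2))
  if (nx == 0 || ny == 0) stop("degenerate configuration")
  Xs <- Xc / nx; Ys <- Yc / ny
  sv <- svd(crossprod(Xs, Ys))
  s <- diag(2)
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) s[2, 2] <- -1
  R <- sv$u %*% s %*% t(sv$v)          # X %*% R approximates Y
  d <- sum(diag(s) * sv$d)
  D <- 1 - d^2
  scale <- d * ny / nx
  angle <- atan2(R[2, 1], R[1, 1]) * 180 / pi   # counterclockwise for row vecs
  if (angle < 0) angle <- angle + 360
  structure(list(angle_deg = angle, rotation = R, scale = scale,
                 translation = cy - as.numeric(cx %*% R) * scale,
                 D = D, t0 = sqrt(max(0, 1 - D))),
            class = "procrustes_fit")
}

#' Permutation test for Procrustes similarity
#'
#' Permutes the row order of the geographic configuration and recomputes `t0`;
#' `p = (1 + #\{t0_perm >= t0_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams procrustes_to_geography
#' @param n_perm permutations.
#' @param seed optional seed.
#' @return list with `t0`, `p`.
#' @export
procrustes_test <- function(pc2, lonlat, n_perm = 999, seed = NULL,
                            allow_reflection = FALSE) {
  obs <- procrustes_to_geography(pc2, lonlat, allow_reflection)$t0
  n <- nrow(as.matrix(pc2))
  with_seed_if(seed, {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      i <- sample.int(n)
      t0 <- procrustes_to_geography(pc2, as.matrix(lonlat)[i, , drop = FALSE],
                                    allow_reflection)$t0
      if (t0 >= obs) ge <- ge + 1L
    }
    list(t0 = obs, p = (1 + ge) / (1 + n_perm), n_perm = n_perm)
  })
}
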