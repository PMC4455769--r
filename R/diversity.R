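#' Segregating sites within a group
#'
#' Number of markers with at least two alleles among the group's non-missing
#' haploid calls.
#'
#' @param g post-QC genotype matrix.
#' @param group sample ids or row indices defining the group.
#' @return integer count.
#' @export
segregating_sites <- function(g, group) {
  check_geno(g, allow_het = FALSE)
  sub <- g[resolve_rows(g, group), , drop = FALSE]
  n0 <- colSums(sub == 0L, na.rm = TRUE)
  n1 <- colSums(sub == 1L, na.rm = TRUE)
  sum(n0 > 0L & n1 > 0L)
}

resolve_rows <- function(g, group) {
  if (is.character(group)) {
    i <- match(group, rownames(g))
    if (anyNA(i)) stop("unknown sample ids: ",
                       paste(group[is.na(i)], collapse = ", "))
    i
  } else {
    if (length(group) == 0) stop("empty group")
    group
  }
}

#' Private SNP counts per group
#'
#' A marker is private to group G when it is polymorphic within G and the
#' allele segregating in G is absent (the marker is monomorphic, or entirely
#' missing) in every other group — i.e. one of its alleles segregates only
#' in G.
#'
#' @param g post-QC genotype matrix.
#' @param partition factor of group labels per sample (non-overlapping).
#' @return named integer vector of private-SNP counts per group.
#' @export
private_snps <- function(g, partition) {
  check_geno(g, allow_het = FALSE)
  partition <- check_partition(g, partition)
  lev <- levels(partition)
  n0 <- n1 <- matrix(0L, length(lev), ncol(g), dimnames = list(lev, NULL))
  for (l in lev) {
    sub <- g[partition == l, , drop = FALSE]
    n0[l, ] <- colSums(sub == 0L, na.rm = TRUE)
    n1[l, ] <- colSums(sub == 1L, na.rm = TRUE)
  }
  poly <- n0 > 0L & n1 > 0L
  out <- stats::setNames(integer(length(lev)), lev)
  for (l in lev) {
    others <- setdiff(lev, l)
    o0 <- colSums(n0[others, , drop = FALSE]) > 0L
    o1 <- colSums(n1[others, , drop = FALSE]) > 0L
    # allele 0 (or 1) segregates in l but nowhere else
    out[l] <- sum(poly[l, ] & (!o0 | !o1))
  }
  out
}

#' Percent pairwise difference within a group
#'
#' For every pair of samples, the fraction of markers (non-missing in both)
#' with differing calls, expressed in percent; returns the mean and SD over
#' pairs. Pairs with no co-called markers are skipped with a warning.
#'
#' @param g post-QC genotype matrix.
#' @param group sample ids or indices (>= 2 samples).
#' @return named numeric vector `c(mean=, sd=, n_pairs=)`.
#' @export
percent_pairwise_difference <- function(g, group) {
  check_geno(g, allow_het = FALSE)
  sub <- g[resolve_rows(g, group), , drop = FALSE]
  if (nrow(sub) < 2) stop("need at least 2 samples")
  x <- sub; x[is.na(x)] <- 0
  obs <- !is.na(sub)
  # co-called marker counts and mismatch counts via cross-products
  ncc <- tcrossprod(obs * 1)
  same <- tcrossprod(x * obs) + tcrossprod((1 - x) * obs)
  diffp <- 100 * (1 - same / ncc)
  vals <- diffp[upper.tri(diffp)]
  ncc_u <- ncc[upper.tri(ncc)]
  if (any(ncc_u == 0)) {
    warning(sum(ncc_u == 0), " sample pair(s) with no co-called markers skipped")
    vals <- vals[ncc_u > 0]
  }
  c(mean = mean(vals), sd = stats::sd(vals), n_pairs = length(vals))
}

#' Joint unfolded site frequency spectrum for two groups
#'
#' Uses polarized markers only (per the `polarized` attribute set by
#' [polarize()], if present). Returns the raw per-SNP derived counts with
#' per-SNP sample sizes, plus a projected spectrum at fixed sizes
#' (`project_to`) obtained by hypergeometric projection: a SNP with `d`
#' derived of `n` non-missing calls contributes
#' `P(k derived in a subsample of size g)` mass to row/column `k`.
#'
#' @param g polarized post-QC genotype matrix.
#' @param partition factor with exactly 2 levels.
#' @param project_to integer vector of length 2, projection sizes per group;
#'   defaults to the smallest per-SNP non-missing count in each group.
#' @return list with `raw` (data.frame marker, dA, nA, dB, nB) and `projected`
#'   (matrix (gA+1) x (gB+1) of expected SNP counts; entries sum to the
#'   number of SNPs projectable in both groups).
#' @export
joint_sfs <- function(g, partition, project_to = NULL) {
  check_geno(g, allow_het = FALSE)
  partition <- check_partition(g, partition)
  if (nlevels(partition) != 2) stop("joint_sfs needs exactly 2 groups")
  pol <- attr(g, "polarized")
  if (!is.null(pol)) {
    if (!any(pol)) stop("no polarized markers")
    g <- g[, pol, drop = FALSE]
  }
  a <- g[partition == levels(partition)[1], , drop = FALSE]
  b <- g[partition == levels(partition)[2], , drop = FALSE]
  dA <- colSums(a == 1L, na.rm = TRUE); nA <- colSums(!is.na(a))
  dB <- colSums(b == 1L, na.rm = TRUE); nB <- colSums(!is.na(b))
  raw <- data.frame(marker_id = colnames(g), dA = dA, nA = nA, dB = dB,
                    nB = nB, row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(project_to)) project_to <- c(min(nA), min(nB))
  gA <- project_to[1]; gB <- project_to[2]
  proj <- matrix(0, gA + 1, gB + 1,
                 dimnames = list(0:gA, 0:gB))
  ok <- nA >= gA & nB >= gB
  for (j in which(ok)) {
    pa <- stats::dhyper(0:gA, dA[j], nA[j] - dA[j], gA)
    pb <- stats::dhyper(0:gB, dB[j], nB[j] - dB[j], gB)
    proj <- proj + outer(pa, pb)
  }
  list(raw = raw, projected = proj, project_to = c(gA, gB))
}

# per-locus rarefied distinct-allele count: counts is a vector of allele
# counts at one locus (one group), g the subsample size.
alpha_g_locus <- function(counts, g) {
  n <- sum(counts)
  if (g > n) return(NA_real_)
  sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
}

#' Rarefaction of allelic richness and private alleles
#'
#' For each group and each subsample size `g` up to `g_max`, the expected
#' number of distinct alleles per locus
#' `alpha_g = sum_j [1 - C(N - N_j, g) / C(N, g)]` (N = non-missing gene
#' copies at the locus, N_j the count of allele j), averaged over loci, and
#' the expected number of alleles private to the group in subsamples of size
#' `g` drawn from every group (the standard across-group combinatorial
#' extension: allele j is observed in the focal subsample and missed in every
#' other group's subsample). Loci where any group's non-missing count is
#' below `g` are skipped at that `g`.
#'
#' @param x either a post-QC genotype matrix (alleles 0/1) or an integer
#'   allele matrix (samples x loci, e.g. microsatellite sizes, NA missing).
#' @param partition factor of group labels.
#' @param g_max largest subsample size (gene copies).
#' @return data.frame with columns group, g, alpha (mean distinct alleles per
#'   locus), private (mean private alleles per locus), n_loci.
#' @export
rarefaction <- function(x, partition, g_max) {
  partition <- check_partition(x, partition)
  lev <- levels(partition)
  loci <- seq_len(ncol(x))
  # per-locus allele count tables per group
  tabs <- lapply(lev, function(l) {
    sub <- x[partition == l, , drop = FALSE]
    lapply(loci, function(j) table(sub[, j]))
  })
  names(tabs) <- lev
  out <- list()
  for (g in seq_len(g_max)) {
    for (li in seq_along(lev)) {
      l <- lev[li]
      av <- pv <- numeric(0)
      for (j in loci) {
        cj <- tabs[[l]][[j]]
        ns <- vapply(tabs, function(tt) sum(tt[[j]]), 0)
        if (any(ns < g)) next          # locus skipped at this g
        av <- c(av, alpha_g_locus(as.numeric(cj), g))
        # private-allele extension: present in focal subsample, absent in all
        # other groups' subsamples of the same size
        alleles <- names(cj)
        p <- 0
        for (al in alleles) {
          nf <- sum(cj); kf <- as.numeric(cj[al])
          pres <- 1 - exp(lchoose(nf - kf, g) - lchoose(nf, g))
          absent <- 1
          for (lo in setdiff(lev, l)) {
            to <- tabs[[lo]][[j]]
            no <- sum(to)
            ko <- if (al %in% names(to)) as.numeric(to[al]) else 0
            absent <- absent * exp(lchoose(no - ko, g) - lchoose(no, g))
          }
          p <- p + pres * absent
        }
        pv <- c(pv, p)
      }
      out[[length(out) + 1L]] <- data.frame(group = l, g = g,
                                            alpha = mean(av), private = mean(pv),
                                            n_loci = length(av),
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Microsatellite expected heterozygosity per group
#'
#' Per locus `H_e = n/(n-1) * (1 - sum_j p_j^2)` (unbiased small-sample
#' correction), averaged over loci within each group. Monomorphic loci
#' contribute 0.
#'
#' @param msat integer allele-size matrix, samples x loci, NA missing.
#' @param partition factor of group labels.
#' @param correct apply the `n/(n-1)` correction (default TRUE).
#' @return named numeric vector of mean expected heterozygosity per group.
#' @export
microsat_expected_het <- function(msat, partition, correct = TRUE) {
  partition <- check_partition(msat, partition)
  out <- stats::setNames(numeric(nlevels(partition)), levels(partition))
  for (l in levels(partition)) {
    sub <- msat[partition == l, , drop = FALSE]
    he <- apply(sub, 2, function(col) {
      col <- col[!is.na(col)]
      n <- length(col)
      if (n < 2) return(NA_real_)
      p <- table(col) / n
      h <- 1 - sum(p^2)
      if (correct) h * n / (n - 1) else h
    })
    out[l] <- mean(he, na.rm = TRUE)
  }
  out
}
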