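#' Per-SNP Weir-Cockerham F_ST (haploid)
#'
#' Variance-components estimator for haploid calls. With r groups of sizes
#' `n_i` and allele frequencies `p_i` at a marker:
#' `n_c = (N - sum n_i^2 / N) / (r - 1)`, `MSA = sum n_i (p_i - pbar)^2 / (r-1)`,
#' `MSW = sum n_i p_i (1 - p_i) / (N - r)`, `a = (MSA - MSW) / n_c`,
#' `t = a + MSW`, `theta = a / t`. Markers where fewer than two groups have
#' at least two non-missing calls, or that are monomorphic overall, get NA.
#' The multi-locus estimate is the ratio of sums `sum(a) / sum(t)`, never the
#' mean of per-marker ratios. Negative per-marker estimates are reported as
#' computed.
#'
#' @param g post-QC genotype matrix.
#' @param partition factor of group labels (>= 2 groups).
#' @return data.frame (class `fst_scan`) with columns marker_id, a, t, theta;
#'   attribute `theta_global` holds the ratio-of-sums estimate.
#' @export
wc_fst <- function(g, partition) {
  check_geno(g, allow_het = FALSE)
  partition <- check_partition(g, partition)
  if (nlevels(partition) < 2) stop("need at least 2 groups")
  lev <- levels(partition)
  r <- length(lev)
  ni <- matrix(0, r, ncol(g)); di <- matrix(0, r, ncol(g))
  for (i in seq_len(r)) {
    sub <- g[partition == lev[i], , drop = FALSE]
    ni[i, ] <- colSums(!is.na(sub))
    di[i, ] <- colSums(sub == 1L, na.rm = TRUE)
  }
  use <- colSums(ni >= 2) >= 2
  N <- colSums(ni)
  ruse <- colSums(ni > 0)                  # groups actually represented
  pbar <- colSums(di) / N
  mono <- pbar <= 0 | pbar >= 1
  pi <- di / ni                            # NaN where ni = 0
  nc <- (N - colSums(ni^2) / N) / (ruse - 1)
  dev <- (pi - matrix(pbar, r, ncol(g), byrow = TRUE))^2
  msa <- colSums(ni * dev, na.rm = TRUE) / (ruse - 1)
  msw <- colSums(ni * pi * (1 - pi), na.rm = TRUE) / (N - ruse)
  a <- (msa - msw) / nc
  t <- a + msw
  theta <- a / t
  bad <- !use | mono | !is.finite(theta)
  a[bad] <- t[bad] <- theta[bad] <- NA_real_
  scan <- data.frame(marker_id = colnames(g), a = a, t = t, theta = theta,
                     row.names = NULL, stringsAsFactors = FALSE)
  class(scan) <- c("fst_scan", "data.frame")
  attr(scan, "theta_global") <- sum(a, na.rm = TRUE) / sum(t, na.rm = TRUE)
  attr(scan, "groups") <- lev
  scan
}

#' Ratio-of-sums F_ST over a map region
#'
#' @param scan result of [wc_fst()].
#' @param markers marker table with `marker_id`, `linkage_group`, `cM`.
#' @param region list or vector `(linkage_group, cM_lo, cM_hi)`.
#' @return list with `theta` (ratio-of-sums mean over the region's markers)
#'   and `n_markers`.
#' @export
region_fst <- function(scan, markers, region) {
  region <- as_region(region)
  check_markers(markers)
  mk <- markers[match(scan$marker_id, markers$marker_id), ]
  inside <- !is.na(mk$cM) & mk$linkage_group == region$linkage_group &
    mk$cM >= region$cM_lo & mk$cM <= region$cM_hi
  inside <- inside & !is.na(scan$theta)
  if (!any(inside)) stop("region contains no scanned markers")
  list(theta = sum(scan$a[inside]) / sum(scan$t[inside]),
       n_markers = sum(inside))
}

as_region <- function(region) {
  if (is.list(region)) {
    stopifnot(all(c("linkage_group", "cM_lo", "cM_hi") %in% names(region)))
    region
  } else {
    list(linkage_group = as.character(region[1]),
         cM_lo = as.numeric(region[2]), cM_hi = as.numeric(region[3]))
  }
}

# nested haploid ANOVA sums of squares / variance components for one marker
# set, vectorised over markers. pop/sub are integer codes per sample.
# Degenerate nestings (a single population, or subpopulations identical to
# populations) collapse to the corresponding two-level model with the missing
# component fixed at 0, so a one-level call reduces exactly to wc_fst.
nested_components <- function(g, pop, sub) {
  pops <- sort(unique(pop)); subs <- sort(unique(sub))
  r <- length(pops); B <- length(subs)
  m <- ncol(g)
  obs <- !is.na(g)
  y <- g; y[!obs] <- 0
  n_sj <- rowsum(obs * 1, sub)               # B x m non-missing per subpop
  d_sj <- rowsum(y * obs, sub)               # derived counts per subpop
  pop_of_sub <- vapply(subs, function(s) pop[match(s, sub)], 0L)
  n_pj <- rowsum(n_sj, pop_of_sub)           # r x m
  d_pj <- rowsum(d_sj, pop_of_sub)
  N <- colSums(n_sj)
  D <- colSums(d_sj)
  pbar <- D / N
  p_s <- d_sj / n_sj
  p_p <- d_pj / n_pj
  # sums of squares
  ss_total <- D * (1 - pbar)                               # sum (y - pbar)^2
  ss_within_sub <- colSums(n_sj * p_s * (1 - p_s), na.rm = TRUE)
  ss_sub_in_pop <- colSums(n_sj * (p_s - p_p[pop_of_sub, , drop = FALSE])^2,
                           na.rm = TRUE)
  ss_pop <- colSums(n_pj * (p_p - matrix(pbar, r, m, byrow = TRUE))^2,
                    na.rm = TRUE)
  # degrees of freedom (per marker, based on represented units)
  r_eff <- colSums(n_pj > 0)
  B_eff <- colSums(n_sj > 0)
  df_a <- r_eff - 1
  df_b <- B_eff - r_eff
  df_w <- N - B_eff
  ms_a <- ss_pop / df_a
  ms_b <- ss_sub_in_pop / df_b
  ms_w <- ss_within_sub / df_w
  # unbalanced nested coefficients (Searle): E[MS_b] = sw + c1 sb;
  # E[MS_a] = sw + c2 sb + c3 sa
  sum_nsj2_over_np <- colSums(n_sj^2 / n_pj[pop_of_sub, , drop = FALSE],
                              na.rm = TRUE)
  s_w <- ms_w
  if (r == 1L) {
    # one population: two-level model among subpopulations only
    c1 <- (N - colSums(n_sj^2) / N) / df_b
    s_b <- (ms_b - ms_w) / c1
    s_a <- rep(0, m)
    ok <- is.finite(s_b) & is.finite(s_w) & pbar > 0 & pbar < 1 &
      df_b > 0 & df_w > 0
  } else if (B == r) {
    # subpopulations coincide with populations: two-level model among pops
    c3 <- (N - colSums(n_pj^2) / N) / df_a
    s_a <- (ms_a - ms_w) / c3
    s_b <- rep(0, m)
    ok <- is.finite(s_a) & is.finite(s_w) & pbar > 0 & pbar < 1 &
      df_a > 0 & df_w > 0
  } else {
    c1 <- (N - sum_nsj2_over_np) / df_b
    c2 <- (sum_nsj2_over_np - colSums(n_sj^2) / N) / df_a
    c3 <- (N - colSums(n_pj^2) / N) / df_a
    s_b <- (ms_b - ms_w) / c1
    s_a <- (ms_a - ms_w - c2 * s_b) / c3
    ok <- is.finite(s_a) & is.finite(s_b) & is.finite(s_w) &
      pbar > 0 & pbar < 1 & df_b > 0 & df_a > 0 & df_w > 0
  }
  list(s_a = s_a, s_b = s_b, s_w = s_w, ok = ok)
}

# multinomial G-statistic for differentiation of `groups` within permutation
# strata `strata` (strata = NULL means one stratum).
g_statistic <- function(g, groups, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, nrow(g))
  tot <- 0
  for (st in unique(strata)) {
    rows <- strata == st
    sub <- g[rows, , drop = FALSE]
    grp <- groups[rows]
    obs <- !is.na(sub)
    y <- sub; y[!obs] <- 0
    n_g <- rowsum(obs * 1, grp)      # groups x markers
    d_g <- rowsum(y * obs, grp)
    N <- colSums(n_g); D <- colSums(d_g)
    pb <- D / N
    e1 <- n_g * matrix(pb, nrow(n_g), ncol(n_g), byrow = TRUE)
    e0 <- n_g - e1
    o1 <- d_g; o0 <- n_g - d_g
    term <- function(o, e) {
      v <- o * log(o / e)
      v[!is.finite(v)] <- 0
      v
    }
    tot <- tot + 2 * sum(term(o1, e1) + term(o0, e0))
  }
  tot
}

#' Hierarchical F-statistics with permutation tests
#'
#' Three-level variance components (among populations; among subpopulations
#' within populations; within subpopulations) from a nested haploid
#' allele-frequency ANOVA, combined over markers by ratio of summed
#' components:
#' `F(pop, total) = sum(s_a) / sum(s_a + s_b + s_w)`,
#' `F(subpop, total) = sum(s_a + s_b) / sum(total)`,
#' `F(subpop, pop) = sum(s_b) / sum(s_b + s_w)`.
#'
#' Two permutation tests are run with a multinomial likelihood-ratio
#' (G) statistic: (i) individuals-within-subpopulations — subpopulation labels
#' permuted among individuals within each population, G measuring subpopulation
#' differentiation within populations; (ii) subpopulations-within-populations —
#' whole subpopulations permuted among populations (preserving each
#' population's subpopulation count), G measuring population differentiation.
#' Empirical p-values are `(1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param g post-QC genotype matrix.
#' @param pop,subpop factors; each subpopulation must nest within exactly one
#'   population.
#' @param n_perm permutations per test.
#' @param seed optional integer seed.
#' @return list (class `hier_f`) with `F` (2x2 matrix, rows Total/Population,
#'   columns Population/Subpopulation, the Population/Population cell fixed
#'   at 0), `components` (summed variance components), `tests` (observed G and
#'   p per test), `variance_pct` (percent among-group variance under the
#'   population-only and subpopulation-only one-level models).
#' @export
hierarchical_f <- function(g, pop, subpop, n_perm = 100, seed = NULL) {
  check_geno(g, allow_het = FALSE)
  pop <- check_partition(g, pop)
  subpop <- check_partition(g, subpop)
  map <- tapply(as.character(pop), subpop, function(x) unique(x))
  if (any(lengths(map) != 1)) stop("subpopulations must nest within populations")
  with_seed_if(seed, hierarchical_f_impl(g, pop, subpop, n_perm))
}

hierarchical_f_impl <- function(g, pop, subpop, n_perm) {
  pi <- as.integer(pop); si <- as.integer(subpop)
  comp <- nested_components(g, pi, si)
  ok <- comp$ok
  Sa <- sum(comp$s_a[ok]); Sb <- sum(comp$s_b[ok]); Sw <- sum(comp$s_w[ok])
  f_pop_total <- Sa / (Sa + Sb + Sw)
  f_sub_total <- (Sa + Sb) / (Sa + Sb + Sw)
  f_sub_pop <- Sb / (Sb + Sw)
  Fm <- matrix(c(f_pop_total, 0, f_sub_total, f_sub_pop), 2, 2,
               dimnames = list(c("Total", "Population"),
                               c("Population", "Subpopulation")))

  ## test (i): individuals within subpopulations (permute subpop labels within pops)
  g1_obs <- g_statistic(g, groups = si, strata = pi)
  ge1 <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    sp <- si
    for (p in unique(pi)) {
      rows <- which(pi == p)
      sp[rows] <- si[rows][sample.int(length(rows))]
    }
    ge1[b] <- g_statistic(g, groups = sp, strata = pi)
  }
  p1 <- (1 + sum(ge1 >= g1_obs)) / (1 + n_perm)

  ## test (ii): subpopulations within populations (permute whole subpops)
  subs <- sort(unique(si))
  pop_of_sub <- vapply(subs, function(s) pi[match(s, si)], 0L)
  testable <- length(unique(pop_of_sub)) > 1 &&
    any(table(pop_of_sub) > 1)
  g2_obs <- g_statistic(g, groups = pi)
  if (testable) {
    ge2 <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm_assign <- pop_of_sub[sample.int(length(subs))]
      pp <- perm_assign[match(si, subs)]
      ge2[b] <- g_statistic(g, groups = pp)
    }
    p2 <- (1 + sum(ge2 >= g2_obs)) / (1 + n_perm)
  } else {
    p2 <- NA_real_
  }

  ## one-level variance percentages
  one_level_pct <- function(labels) {
    if (length(unique(labels)) < 2) return(NA_real_)
    s <- wc_fst(g, labels)
    100 * attr(s, "theta_global")
  }
  structure(list(F = Fm,
                 components = c(among_pop = Sa, among_sub_within_pop = Sb,
                                within_sub = Sw),
                 tests = data.frame(
                   test = c("individuals_within_subpops", "subpops_within_pops"),
                   G = c(g1_obs, g2_obs), p = c(p1, p2),
                   stringsAsFactors = FALSE),
                 variance_pct = c(pop_model = one_level_pct(pop),
                                  subpop_model = one_level_pct(subpop)),
                 n_markers_used = sum(ok)),
            class = "hier_f")
}

#' R_ST between two groups (microsatellites, stepwise mutation model)
#'
#' Per locus `R_ST = (Sbar - S_W) / Sbar`, where `Sbar` is the bias-corrected
#' variance in allele size over the pooled sample and `S_W` the weighted
#' average within-group variance (weights `n_i - 1`). Loci monomorphic in the
#' pooled sample are skipped. Returned as per-locus values and their mean.
#'
#' @param msat integer allele-size matrix, samples x loci.
#' @param partition factor with two (or more) groups.
#' @return list with `per_locus` and `mean`.
#' @export
rst <- function(msat, partition) {
  partition <- check_partition(msat, partition)
  per <- apply(msat, 2, function(col) {
    keep <- !is.na(col)
    x <- col[keep]; grp <- partition[keep]
    if (length(unique(x)) < 2) return(NA_real_)
    sbar <- stats::var(x)
    vs <- tapply(x, grp, stats::var)
    ns <- tapply(x, grp, length)
    use <- !is.na(vs) & ns > 1
    sw <- sum(vs[use] * (ns[use] - 1)) / sum(ns[use] - 1)
    (sbar - sw) / sbar
  })
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Correlation between two per-SNP F_ST tracks
#'
#' Pearson correlation of per-marker theta between two scans of the same
#' marker set (e.g. a genetic-assignment partition vs a geographic partition).
#'
#' @param scanA,scanB [wc_fst()] results.
#' @return correlation coefficient.
#' @export
partition_correlation <- function(scanA, scanB) {
  shared <- intersect(scanA$marker_id, scanB$marker_id)
  a <- scanA$theta[match(shared, scanA$marker_id)]
  b <- scanB$theta[match(shared, scanB$marker_id)]
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 3) stop("fewer than 3 shared markers with defined theta")
  stats::cor(a[keep], b[keep])
}
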