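#' Pairwise LD (r^2) within linkage groups
#'
#' For haploid calls, `r^2 = D^2 / (pA(1-pA) pB(1-pB))` computed from observed
#' two-locus haplotype counts over samples non-missing at both markers, which
#' equals the squared Pearson correlation of the two 0/1 call vectors. Only
#' markers with minor allele frequency strictly above `maf_min` enter; pairs
#' with fewer than 4 co-called samples are skipped. Pairs are only formed
#' within a linkage group.
#'
#' @param g post-QC genotype matrix.
#' @param markers marker table.
#' @param maf_min MAF threshold (strict `>`).
#' @return data.frame (class `ld_table`) with columns linkage_group, m1, m2,
#'   cM1, cM2, dist_cM, n, r2.
#' @export
pairwise_r2 <- function(g, markers, maf_min = 0.05) {
  check_geno(g, allow_het = FALSE)
  check_markers(markers, g)
  p <- colMeans(g, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > maf_min
  g <- g[, keep, drop = FALSE]
  mk <- markers[match(colnames(g), markers$marker_id), ]
  out <- list()
  for (lgv in unique(mk$linkage_group)) {
    ids <- mk$marker_id[mk$linkage_group == lgv]
    ids <- ids[order(mk$cM[match(ids, mk$marker_id)], ids, method = "radix")]
    if (length(ids) < 2) next
    sub <- g[, ids, drop = FALSE]
    r <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    nmat <- crossprod(!is.na(sub))
    ut <- which(upper.tri(r), arr.ind = TRUE)
    r2 <- r[ut]^2
    n <- nmat[ut]
    ok <- n >= 4 & is.finite(r2)
    cM <- mk$cM[match(ids, mk$marker_id)]
    out[[lgv]] <- data.frame(linkage_group = lgv,
                             m1 = ids[ut[ok, 1]], m2 = ids[ut[ok, 2]],
                             cM1 = cM[ut[ok, 1]], cM2 = cM[ut[ok, 2]],
                             dist_cM = abs(cM[ut[ok, 2]] - cM[ut[ok, 1]]),
                             n = n[ok], r2 = r2[ok],
                             stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no marker pairs pass the MAF filter")
  ld <- do.call(rbind, out)
  rownames(ld) <- NULL
  class(ld) <- c("ld_table", "data.frame")
  ld
}

#' Region vs background LD contrast
#'
#' Mean `r^2` over pairs with both markers inside the region, over pairs with
#' both markers outside it (same linkage group), and over pairs within left
#' and right flanking windows of the same cM width (truncated at the map edge
#' with a warning).
#'
#' @param ld result of [pairwise_r2()].
#' @param region `(linkage_group, cM_lo, cM_hi)`.
#' @return named list of mean r^2 values and pair counts.
#' @export
region_ld_contrast <- function(ld, region) {
  region <- as_region(region)
  sub <- ld[ld$linkage_group == region$linkage_group, , drop = FALSE]
  if (!nrow(sub)) stop("no LD pairs on linkage group ", region$linkage_group)
  lo <- region$cM_lo; hi <- region$cM_hi; w <- hi - lo
  inr <- function(x, a, b) x >= a & x <= b
  inside <- inr(sub$cM1, lo, hi) & inr(sub$cM2, lo, hi)
  outside <- !inr(sub$cM1, lo, hi) & !inr(sub$cM2, lo, hi)
  lf <- c(lo - w, lo); rf <- c(hi, hi + w)
  map_lo <- min(sub$cM1, sub$cM2); map_hi <- max(sub$cM1, sub$cM2)
  if (lf[1] < map_lo || rf[2] > map_hi)
    warning("flank extends beyond the mapped marker range; truncated")
  left <- inr(sub$cM1, lf[1], lf[2]) & inr(sub$cM2, lf[1], lf[2]) & !inside
  right <- inr(sub$cM1, rf[1], rf[2]) & inr(sub$cM2, rf[1], rf[2]) & !inside
  m <- function(i) if (any(i)) mean(sub$r2[i]) else NA_real_
  list(inside = m(inside), outside = m(outside),
       left_flank = m(left), right_flank = m(right),
       n_pairs = c(inside = sum(inside), outside = sum(outside),
                   left = sum(left), right = sum(right)))
}

#' Distinct-haplotype counts per window
#'
#' Count of distinct complete (no-missing) haplotypes per 5-SNP window,
#' overall and optionally per group.
#'
#' @param hb a [build_haplotypes()] result.
#' @param partition optional factor of group labels.
#' @return data.frame: window, linkage_group, cM bounds, n_haplotypes, and one
#'   column per group when `partition` is given.
#' @export
window_haplotype_counts <- function(hb, partition = NULL) {
  stopifnot(inherits(hb, "haplo_blocks"))
  counts <- apply(hb$codes, 2, function(x) length(unique(stats::na.omit(x))))
  out <- cbind(hb$windows, n_haplotypes = counts)
  if (!is.null(partition)) {
    partition <- check_partition(hb$codes, partition)
    for (l in levels(partition)) {
      sub <- hb$codes[partition == l, , drop = FALSE]
      out[[paste0("n_", l)]] <-
        apply(sub, 2, function(x) length(unique(stats::na.omit(x))))
    }
  }
  rownames(out) <- NULL
  out
}

#' Region haplotype-frequency table by population
#'
#' Haplotype strings over all of a region's markers (samples missing at any
#' region marker are excluded), with per-population frequencies sorted by
#' pooled frequency, and the per-marker F_ST across the region annotated.
#'
#' @param g post-QC (ideally polarized) genotype matrix.
#' @param markers marker table.
#' @param region `(linkage_group, cM_lo, cM_hi)`.
#' @param partition factor of population labels.
#' @return list (class `region_haplotypes`) with `haplotypes` (data.frame:
#'   haplotype string, pooled and per-population frequency and count),
#'   `marker_theta` (per-marker F_ST scan over region markers), `markers`
#'   (region marker ids), `n_complete` (samples used per population).
#' @export
region_haplotype_table <- function(g, markers, region, partition) {
  check_geno(g, allow_het = FALSE)
  check_markers(markers, g)
  partition <- check_partition(g, partition)
  region <- as_region(region)
  mk <- markers[markers$marker_id %in% colnames(g), ]
  mk <- mk[marker_order(mk), ]
  ids <- mk$marker_id[mk$linkage_group == region$linkage_group &
                      mk$cM >= region$cM_lo & mk$cM <= region$cM_hi]
  if (!length(ids)) stop("region contains no markers")
  sub <- g[, ids, drop = FALSE]
  complete <- !apply(sub, 1, anyNA)
  strs <- apply(sub[complete, , drop = FALSE], 1, paste, collapse = "")
  grp <- partition[complete]
  lev <- levels(partition)
  tab <- table(haplotype = strs, group = factor(grp, levels = lev))
  pooled <- rowSums(tab)
  ord <- order(-pooled, rownames(tab))
  haps <- data.frame(haplotype = rownames(tab)[ord],
                     count = as.integer(pooled[ord]),
                     freq = as.numeric(pooled[ord] / sum(pooled)),
                     stringsAsFactors = FALSE)
  for (l in lev) {
    cnt <- as.integer(tab[ord, l])
    haps[[paste0("count_", l)]] <- cnt
    haps[[paste0("freq_", l)]] <- if (sum(tab[, l]) > 0)
      cnt / sum(tab[, l]) else NA_real_
  }
  scan <- wc_fst(sub, partition)
  structure(list(haplotypes = haps, marker_theta = scan, markers = ids,
                 n_complete = table(grp)),
            class = "region_haplotypes")
}
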