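#' Read a genotype matrix
#'
#' Reads haploid genotype calls from either a restricted VCF 4.2 dialect
#' (biallelic, GT-only; haploid `0`/`1`/`.` or simple diploid GT where
#' heterozygous calls map to the pre-QC `H` flag) or from the package's
#' genotype TSV dialect (columns `marker_id`, `ref`, `alt`, then one column per
#' sample; cells are the ref base, the alt base, `H` or `N`). Sample and
#' marker order are preserved from the file.
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`.
#' @return integer matrix, samples x markers, codes 0/1/2 (het flag)/NA, with
#'   a `markers` attribute holding the marker columns read from the file
#'   (`marker_id`, `linkage_group`, `pos`, `ref`, `alt` for VCF).
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1) stop("malformed VCF: no #CHROM header line")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) stop("VCF has no sample columns")
  samples <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  n <- length(samples)
  m <- length(body)
  g <- matrix(NA_integer_, n, m)
  marker_id <- chrom <- ref <- alt <- character(m)
  pos <- integer(m)
  map <- c("0" = 0L, "1" = 1L, "." = NA_integer_,
           "0/0" = 0L, "0|0" = 0L, "1/1" = 1L, "1|1" = 1L,
           "0/1" = GENO_HET, "1/0" = GENO_HET, "0|1" = GENO_HET,
           "1|0" = GENO_HET, "./." = NA_integer_, ".|." = NA_integer_)
  for (j in seq_len(m)) {
    f <- strsplit(body[j], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9 + n)
      stop("malformed VCF record at line ", hdr_i + j, ": expected ",
           9 + n, " fields, got ", length(f))
    gtf <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gti <- which(gtf == "GT")
    if (!length(gti)) stop("no GT in FORMAT at line ", hdr_i + j)
    calls <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gti[1])
    code <- map[calls]
    if (any(is.na(code) & !calls %in% names(map)))
      stop("unparseable GT at line ", hdr_i + j, ": ",
           calls[which(!calls %in% names(map))[1]])
    g[, j] <- unname(code)
    chrom[j] <- f[1]; pos[j] <- as.integer(f[2]); marker_id[j] <- f[3]
    ref[j] <- f[4]; alt[j] <- f[5]
  }
  dimnames(g) <- list(samples, marker_id)
  attr(g, "markers") <- data.frame(marker_id = marker_id, linkage_group = chrom,
                                   pos = pos, ref = ref, alt = alt,
                                   stringsAsFactors = FALSE)
  g
}

read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          header = TRUE, data.table = FALSE)
  need <- c("marker_id", "ref", "alt")
  if (!all(need %in% names(dt)))
    stop("genotype TSV lacks columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  samples <- setdiff(names(dt), need)
  m <- nrow(dt)
  g <- matrix(NA_integer_, length(samples), m,
              dimnames = list(samples, dt$marker_id))
  cells <- t(as.matrix(dt[, samples, drop = FALSE]))
  refm <- matrix(dt$ref, length(samples), m, byrow = TRUE)
  altm <- matrix(dt$alt, length(samples), m, byrow = TRUE)
  g[cells == refm] <- 0L
  g[cells == altm] <- 1L
  g[cells == "H"] <- GENO_HET
  bad <- cells != refm & cells != altm & cells != "H" & cells != "N"
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("unparseable genotype cell at marker row ", w[2], " (line ",
         w[2] + 1L, "), sample ", samples[w[1]], ": ", cells[w[1], w[2]])
  }
  attr(g, "markers") <- dt[, need]
  g
}

#' Quality-control filter for a pre-QC genotype matrix
#'
#' Applies, in this fixed order: (1) remove markers monomorphic among
#' non-missing haploid calls; (2) remove markers whose missing fraction is at
#' least `max_missing`; (3) remove markers whose heterozygote-flag fraction
#' exceeds `max_het`; then convert any residual `H` flags to missing. The
#' thresholds default to the rules used for inbred diversity panels: 15%
#' missing (boundary inclusive) and 10% observed heterozygosity (boundary
#' exclusive).
#'
#' @param g pre-QC genotype matrix (codes 0/1/2/NA).
#' @param max_missing,max_het thresholds as fractions.
#' @return list with `genotypes` (filtered matrix, H converted to NA) and
#'   `report` (counts removed per rule and surviving marker count).
#' @export
qc_filter <- function(g, max_missing = 0.15, max_het = 0.10) {
  check_geno(g, allow_het = TRUE)
  n <- nrow(g)
  report <- list(input = ncol(g))

  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  mono <- n0 == 0L | n1 == 0L
  report$monomorphic <- sum(mono)
  g <- g[, !mono, drop = FALSE]

  miss_frac <- colMeans(is.na(g))
  hi_miss <- miss_frac >= max_missing
  report$missing <- sum(hi_miss)
  g <- g[, !hi_miss, drop = FALSE]

  het_frac <- colMeans(g == GENO_HET, na.rm = TRUE)
  hi_het <- het_frac > max_het
  report$het <- sum(hi_het)
  g <- g[, !hi_het, drop = FALSE]

  g[g == GENO_HET] <- NA_integer_
  report$output <- ncol(g)
  if (ncol(g) == 0) stop("QC removed all markers")
  list(genotypes = g, report = report)
}

#' Polarize calls so 0 is the ancestral allele
#'
#' Recode calls so that 0 = ancestral allele wherever the marker table gives an
#' ancestral state. Markers whose ancestral state equals the alt allele are
#' flipped; markers with no ancestral state are flagged unpolarized; markers
#' whose ancestral state matches neither allele are flagged unpolarizable.
#' Unpolarized/unpolarizable markers keep their original coding (they remain
#' usable for F_ST etc., and are excluded from frequency-spectrum analyses).
#'
#' @param g post-QC genotype matrix (codes 0/1/NA).
#' @param markers marker table with `marker_id`, `ref`, `alt`,
#'   `ancestral_state` columns.
#' @return the recoded matrix, with attributes `polarized` (logical per
#'   marker) and `unpolarizable` (logical per marker).
#' @export
polarize <- function(g, markers) {
  check_geno(g, allow_het = FALSE)
  need <- c("marker_id", "ref", "alt", "ancestral_state")
  if (!all(need %in% names(markers)))
    stop("marker table lacks columns: ",
         paste(setdiff(need, names(markers)), collapse = ", "))
  mk <- markers[match(colnames(g), markers$marker_id), ]
  if (any(is.na(mk$marker_id)))
    stop("markers missing from marker table: ",
         paste(utils::head(colnames(g)[is.na(mk$marker_id)]), collapse = ", "))
  anc <- mk$ancestral_state
  flip <- !is.na(anc) & anc == mk$alt
  keep <- !is.na(anc) & anc == mk$ref
  unpolarizable <- !is.na(anc) & !flip & !keep
  polarized <- flip | keep
  g[, flip] <- 1L - g[, flip, drop = FALSE]
  attr(g, "polarized") <- stats::setNames(polarized, colnames(g))
  attr(g, "unpolarizable") <- stats::setNames(unpolarizable, colnames(g))
  g
}

#' Build 5-SNP haplotype windows
#'
#' Markers are sorted by (linkage group, cM, marker id) and cut into
#' consecutive non-overlapping windows of `window` markers per linkage group;
#' trailing windows with fewer than `window` markers are dropped. Each
#' distinct complete allele string in a window gets one integer haplotype
#' code; samples with any missing call in a window get code NA unless
#' `impute = "cluster_mode"`, in which case missing calls are first replaced
#' by the modal allele of the sample's cluster at that marker (ties broken
#' toward allele 0).
#'
#' @param g post-QC genotype matrix.
#' @param markers marker table (`marker_id`, `linkage_group`, `cM`).
#' @param window markers per window.
#' @param impute `"none"` or `"cluster_mode"`.
#' @param clusters factor of cluster labels per sample, required for
#'   `impute = "cluster_mode"`.
#' @return a `haplo_blocks` list: `windows` (data.frame of window id, linkage
#'   group, cM bounds), `members` (list of marker ids per window), `codes`
#'   (samples x windows integer matrix), `strings` (list of the code ->
#'   allele-string dictionary per window).
#' @export
build_haplotypes <- function(g, markers, window = 5L,
                             impute = c("none", "cluster_mode"),
                             clusters = NULL) {
  impute <- match.arg(impute)
  check_geno(g, allow_het = FALSE)
  check_markers(markers, g)
  if (impute == "cluster_mode") {
    if (is.null(clusters)) stop("cluster_mode imputation needs `clusters`")
    clusters <- check_partition(g, clusters)
    for (cl in levels(clusters)) {
      rows <- which(clusters == cl)
      sub <- g[rows, , drop = FALSE]
      mode1 <- colMeans(sub, na.rm = TRUE) > 0.5    # ties -> allele 0
      mode1[is.na(mode1)] <- FALSE
      fill <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(fill)) sub[fill] <- as.integer(mode1[fill[, 2]])
      g[rows, ] <- sub
    }
  }
  mk <- markers[markers$marker_id %in% colnames(g), ]
  mk <- mk[marker_order(mk), ]
  win_rows <- list(); members <- list(); codes <- list(); strings <- list()
  wid <- 0L
  for (lgv in unique(mk$linkage_group)) {
    ids <- mk$marker_id[mk$linkage_group == lgv]
    nwin <- length(ids) %/% window
    if (nwin == 0L) {
      warning("linkage group ", lgv, " has fewer than ", window,
              " markers; no windows built")
      next
    }
    for (w in seq_len(nwin)) {
      wid <- wid + 1L
      mem <- ids[((w - 1L) * window + 1L):(w * window)]
      sub <- g[, mem, drop = FALSE]
      str <- apply(sub, 1, function(r)
        if (anyNA(r)) NA_character_ else paste(r, collapse = ""))
      lev <- sort(unique(stats::na.omit(str)))
      cM <- markers$cM[match(mem, markers$marker_id)]
      win_rows[[wid]] <- data.frame(window = wid, linkage_group = lgv,
                                    cM_lo = min(cM), cM_hi = max(cM),
                                    stringsAsFactors = FALSE)
      members[[wid]] <- mem
      codes[[wid]] <- match(str, lev)
      strings[[wid]] <- lev
    }
  }
  if (wid == 0L) stop("no linkage group had enough markers for a window")
  code_mat <- do.call(cbind, codes)
  dimnames(code_mat) <- list(rownames(g), paste0("W", seq_len(wid)))
  structure(list(windows = do.call(rbind, win_rows), members = members,
                 codes = code_mat, strings = strings, window_size = window),
            class = "haplo_blocks")
}
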