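# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# All k! permutations of 1..k, one per row.
perms <- function(k) {
  k <- as.integer(k)
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(rep.int(i, nrow(sub)), sub + (sub >= i))
  }))
}

# Genotype matrices are plain integer matrices, samples x markers, with
# rownames = sample ids and colnames = marker ids. Codes: 0 = ancestral/ref,
# 1 = derived/alt, 2 = heterozygous flag (pre-QC only), NA = missing.
GENO_HET <- 2L

check_geno <- function(g, allow_het = TRUE) {
  if (!is.matrix(g) || !(is.numeric(g) || is.integer(g)))
    stop("genotype matrix must be a numeric matrix (samples x markers)")
  vals <- unique(as.vector(g))
  vals <- vals[!is.na(vals)]
  ok <- if (allow_het) c(0, 1, 2) else c(0, 1)
  if (length(setdiff(vals, ok)) > 0)
    stop("genotype matrix contains codes other than {",
         paste(ok, collapse = ","), ", NA}: ",
         paste(setdiff(vals, ok), collapse = ","))
  invisible(TRUE)
}

check_partition <- function(g, labels) {
  labels <- as.factor(labels)
  if (length(labels) != nrow(g))
    stop("partition length (", length(labels),
         ") does not match sample count (", nrow(g), ")")
  labels
}

# Marker tables are data.frames with at least columns
# marker_id, linkage_group, cM; annotation columns are optional.
check_markers <- function(markers, g = NULL) {
  need <- c("marker_id", "linkage_group", "cM")
  miss <- setdiff(need, names(markers))
  if (length(miss)) stop("marker table lacks columns: ", paste(miss, collapse = ", "))
  if (any(markers$cM < 0, na.rm = TRUE)) stop("cM positions must be non-negative")
  if (!is.null(g) && !all(colnames(g) %in% markers$marker_id))
    stop("genotype matrix contains markers absent from the marker table")
  invisible(TRUE)
}

# Sort order used everywhere markers are ordered along the map:
# (linkage group, cM, marker_id) with lexicographic id tie-break.
marker_order <- function(markers) {
  order(as.character(markers$linkage_group), markers$cM,
        as.character(markers$marker_id), method = "radix")
}

#' Great-circle distance matrix
#'
#' Haversine distances between samples on the WGS84 mean sphere
#' (radius 6371.0088 km).
#'
#' @param lat,lon numeric vectors of coordinates in decimal degrees.
#' @return symmetric matrix of pairwise distances in km.
#' @export
great_circle_km <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  if (any(abs(lat) > 90, na.rm = TRUE) || any(abs(lon) > 180, na.rm = TRUE))
    stop("coordinates outside [-90,90] x [-180,180]")
  r <- 6371.0088
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lat)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a <- clamp(a, 0, 1)
  d <- 2 * r * asin(sqrt(a))
  diag(d) <- 0
  dimnames(d) <- NULL
  d
}

# quantile threshold used for all outlier calls: empirical genome-wide
# percentile, ties at the threshold included upward (>=).
percentile_threshold <- function(x, percentile) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values for a percentile")
  stats::quantile(x, percentile / 100, names = FALSE, type = 7)
}
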