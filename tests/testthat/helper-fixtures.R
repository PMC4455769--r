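# Shared fixtures (memoised per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# medium simulated bundle with the default two regions
sim_medium <- function() fixture("sim_medium", function() {
  simulate_dataset(sim_config(samples_per_subpop = 10, snps_per_group = 80,
                              seed = 42))
})

# dense two-group bundle with one backbone region on 2H (for haplotype tests)
sim_regions <- function() fixture("sim_regions", function() {
  simulate_dataset(sim_config(
    samples_per_subpop = 10, snps_per_group = 250, n_linkage_groups = 2,
    region_specs = list(list(linkage_group = "2H", cM_lo = 60, cM_hi = 80,
                             n_backbone = c(6L, 2L), divergence = 0.5)),
    missing_rate = 0.01, het_error_rate = 0, seed = 19))
})

# small region-free panmictic-ish bundle
sim_small <- function() fixture("sim_small", function() {
  simulate_dataset(sim_config(samples_per_subpop = 6, snps_per_group = 40,
                              n_linkage_groups = 3, region_specs = list(),
                              seed = 7))
})

qc_geno <- function(bundle) qc_filter(bundle$genotypes)$genotypes

## ---- independent oracles ---------------------------------------------------

# Weir-Cockerham haploid theta via explicit scalar loops (no shared code with
# wc_fst's vectorised path).
oracle_wc <- function(counts, sizes) {
  r <- length(sizes)
  N <- sum(sizes)
  p <- counts / sizes
  pbar <- sum(counts) / N
  if (pbar <= 0 || pbar >= 1) return(c(a = NA, t = NA, theta = NA))
  nc <- (N - sum(sizes^2) / N) / (r - 1)
  msa <- 0; ssw <- 0
  for (i in seq_len(r)) {
    msa <- msa + sizes[i] * (p[i] - pbar)^2
    ssw <- ssw + sizes[i] * p[i] * (1 - p[i])
  }
  msa <- msa / (r - 1)
  msw <- ssw / (N - r)
  a <- (msa - msw) / nc
  c(a = a, t = a + msw, theta = a / (a + msw))
}

# build a genotype matrix realising exact per-group derived counts
geno_from_counts <- function(counts, sizes) {
  g <- matrix(NA_integer_, sum(sizes), length(1))
  calls <- integer(0); labels <- character(0)
  for (i in seq_along(sizes)) {
    calls <- c(calls, rep(1L, counts[i]), rep(0L, sizes[i] - counts[i]))
    labels <- c(labels, rep(paste0("G", i), sizes[i]))
  }
  m <- matrix(calls, ncol = 1)
  rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- "M1"
  list(g = m, partition = factor(labels))
}

# exhaustive rarefaction oracle: enumerate all g-subsets of the gene copies
oracle_alpha <- function(alleles, g) {
  n <- length(alleles)
  combs <- utils::combn(n, g)
  mean(apply(combs, 2, function(i) length(unique(alleles[i]))))
}

# exhaustive Mantel p at n = 5 (120 permutations, proportion >= observed)
oracle_mantel_p <- function(dA, dB) {
  ut <- upper.tri(dA)
  obs <- stats::cor(dA[ut], dB[ut])
  pm <- geodiff:::perms(5L)
  stats_all <- apply(pm, 1, function(i) stats::cor(dA[ut], dB[i, i][ut]))
  mean(stats_all >= obs - 1e-12)
}

# toy marker table for hand-built matrices
toy_markers <- function(g, lg = "1H", cM = NULL) {
  m <- ncol(g)
  data.frame(marker_id = colnames(g),
             linkage_group = rep_len(lg, m),
             cM = cM %||% seq_len(m),
             ref = rep("A", m), alt = rep("G", m),
             ancestral_state = rep("A", m),
             genic = rep(TRUE, m),
             codon_effect = rep("synonymous", m),
             centromeric = rep(FALSE, m),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_cluster_table <- function(b, g = NULL) {
  g <- g %||% qc_filter(b$genotypes)$genotypes
  sub <- b$truth$subpop
  obs <- !is.na(g); y <- g; y[!obs] <- 0L
  structure(list(counts = rowsum(y * obs, sub), sizes = rowsum(obs * 1, sub),
                 env = matrix(b$truth$env_gradient_subpop, ncol = 1),
                 labels = as.integer(sub), n_clusters = nlevels(sub)),
            class = "pop_freq_table")
}

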