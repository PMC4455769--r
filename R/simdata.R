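#' Synthetic-data generator configuration
#'
#' Builds the configuration for [simulate_dataset()]. The defaults describe the
#' statistical world the downstream analyses assume: two primary populations
#' (a diverse "Western-like" population 1 and an "Eastern-like" population 2)
#' separated by an impassable mountain line, three subpopulations nested in
#' each, seven linkage groups, and two high-LD / high-differentiation
#' "rearrangement" regions on linkage groups 2H and 5H built from a small
#' number of backbone haplotypes per population.
#'
#' Population and subpopulation allele frequencies follow a nested
#' Balding-Nichols model: given an ancestral frequency `p0`, each population
#' draws `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` with `F = F_pop`, and each
#' subpopulation repeats the draw around its population frequency with
#' `F = F_subpop`. Ancestral frequencies are drawn
#' `Uniform(ascertainment_maf_min, 1 - ascertainment_maf_min)`, emulating
#' ascertainment of array SNPs in a diversity discovery panel (no rare
#' ancestral variants enter the panel).
#'
#' @param n_pops number of primary populations.
#' @param n_subpops_per_pop subpopulations nested in each population.
#' @param samples_per_subpop haploid samples per subpopulation (>= 2).
#' @param n_linkage_groups number of linkage groups, named `1H..nH`.
#' @param snps_per_group markers per linkage group.
#' @param map_length_cM genetic map length per linkage group.
#' @param F_pop,F_subpop Balding-Nichols drift parameters in (0,1) for the
#'   population and subpopulation levels. Defaults are the two-level
#'   F-statistics reported for the wild-barley panel this package is modelled
#'   on (0.042 population/total, 0.155 subpopulation/population).
#' @param region_specs list of region descriptions, each a list with elements
#'   `linkage_group`, `cM_lo`, `cM_hi`, `n_backbone` (scalar or one count per
#'   population) and `divergence` (population frequency divergence in (0,1)).
#'   Inside a region every sample carries one of its population's few backbone
#'   haplotypes, which creates high LD and high F_ST.
#' @param n_env_snps number of non-region markers given a true environmental
#'   effect (a logit-scale shift of subpopulation frequencies along the
#'   longitude-driven environmental gradient).
#' @param env_effect_size absolute logit-scale effect per environmental SNP
#'   (slope of the allele-frequency cline per SD of the gradient). The
#'   default 4 is a strong cline — the derived allele sweeps from rare to
#'   near-fixed across the sampled range, comparable to the steepest spatial
#'   gradients reported for diversity panels of this kind.
#' @param env_noise_sd standard deviation of the noise added to each
#'   environmental variable (the geographic signal has unit variance).
#' @param ascertainment_maf_min lower bound of the ancestral frequency
#'   spectrum (ascertainment emulation).
#' @param missing_rate,het_error_rate per-call rates of missing codes and of
#'   spurious heterozygote flags injected after genotype draws.
#' @param seed integer seed; the seed fully determines the output.
#' @return a `sim_config` list.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_pops = 2L,
                       n_subpops_per_pop = 3L,
                       samples_per_subpop = 47L,
                       n_linkage_groups = 7L,
                       snps_per_group = 333L,
                       map_length_cM = 150,
                       F_pop = 0.042,
                       F_subpop = 0.155,
                       region_specs = list(
                         list(linkage_group = "2H", cM_lo = 67, cM_hi = 74,
                              n_backbone = c(6L, 2L), divergence = 0.5),
                         list(linkage_group = "5H", cM_lo = 47, cM_hi = 52,
                              n_backbone = c(6L, 2L), divergence = 0.5)),
                       n_env_snps = 0L,
                       env_effect_size = 4,
                       env_noise_sd = 1,
                       ascertainment_maf_min = 0.1,
                       missing_rate = 0.05,
                       het_error_rate = 0.002,
                       seed = 1L) {
  cfg <- list(n_pops = as.integer(n_pops),
              n_subpops_per_pop = as.integer(n_subpops_per_pop),
              samples_per_subpop = as.integer(samples_per_subpop),
              n_linkage_groups = as.integer(n_linkage_groups),
              snps_per_group = as.integer(snps_per_group),
              map_length_cM = as.numeric(map_length_cM),
              F_pop = as.numeric(F_pop),
              F_subpop = as.numeric(F_subpop),
              region_specs = region_specs,
              n_env_snps = as.integer(n_env_snps),
              env_effect_size = as.numeric(env_effect_size),
              env_noise_sd = as.numeric(env_noise_sd),
              ascertainment_maf_min = as.numeric(ascertainment_maf_min),
              missing_rate = as.numeric(missing_rate),
              het_error_rate = as.numeric(het_error_rate),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_pops >= 1, cfg$n_subpops_per_pop >= 1)
  if (cfg$samples_per_subpop < 2)
    stop("samples_per_subpop must be >= 2")
  rates <- c(cfg$missing_rate, cfg$het_error_rate, cfg$ascertainment_maf_min)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$F_pop < 0 || cfg$F_pop >= 1 || cfg$F_subpop < 0 || cfg$F_subpop >= 1)
    stop("drift parameters must lie in [0, 1)")
  lgs <- paste0(seq_len(cfg$n_linkage_groups), "H")
  seen <- list()
  for (rs in cfg$region_specs) {
    if (!all(c("linkage_group", "cM_lo", "cM_hi") %in% names(rs)))
      stop("region_spec needs linkage_group, cM_lo, cM_hi")
    if (!rs$linkage_group %in% lgs)
      stop("region on unknown linkage group: ", rs$linkage_group)
    if (rs$cM_lo < 0 || rs$cM_hi > cfg$map_length_cM || rs$cM_lo >= rs$cM_hi)
      stop("region cM interval must lie within [0, map_length_cM]")
    for (old in seen) {
      if (old$linkage_group == rs$linkage_group &&
          rs$cM_lo < old$cM_hi && old$cM_lo < rs$cM_hi)
        stop("overlapping region_specs on ", rs$linkage_group)
    }
    seen[[length(seen) + 1L]] <- rs
  }
  invisible(TRUE)
}

# Balding-Nichols draw: Beta around parent frequency p with dispersion F.
# F = 0 degenerates to the parent frequency itself.
rbn <- function(p, f) {
  if (f <= 0) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  q <- stats::rbeta(length(p), a, b)
  # guard against numerically fixed draws so markers stay usable
  clamp(q, 1e-6, 1 - 1e-6)
}

#' Simulate a full synthetic dataset
#'
#' Generates a haploid genotype matrix with nested population structure, a
#' marker/annotation table, sample coordinates with isolation by distance, an
#' environmental-variable table driven by geography, and the ground truth
#' needed to verify every downstream stage.
#'
#' Construction, in order: ancestral frequencies (ascertainment-bounded
#' uniform); nested Balding-Nichols population and subpopulation frequencies;
#' optional logit-scale environmental effects on selected SNPs; Bernoulli
#' haploid calls; backbone-haplotype override inside each configured region
#' (every sample carries one of its population's backbone haplotypes there);
#' marker coding flips for a random subset (so ref is not always ancestral and
#' [polarize()] has work to do); geography on a km plane split by a
#' "mountain" meridian, mapped to lat/lon; environmental variables as linear
#' functions of standardised coordinates plus Gaussian noise; and finally
#' injection of missing and heterozygote-flag codes at the configured rates.
#'
#' @param config a [sim_config()].
#' @return a list (class `sim_bundle`) with elements `genotypes` (samples x
#'   markers integer matrix, codes 0/1/2=het flag/NA), `markers`, `samples`,
#'   `env` (data.frames) and `truth` (true labels, region marker sets,
#'   backbone haplotypes and choices, per-SNP environmental effects, true
#'   subpopulation frequencies, per-marker coding flips).
#' @examples
#' b <- simulate_dataset(sim_config(samples_per_subpop = 4, snps_per_group = 30,
#'                                  region_specs = list(), seed = 7))
#' dim(b$genotypes)
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n_sub_total <- cfg$n_pops * cfg$n_subpops_per_pop
  n <- n_sub_total * cfg$samples_per_subpop
  m <- cfg$n_linkage_groups * cfg$snps_per_group
  lgs <- paste0(seq_len(cfg$n_linkage_groups), "H")

  sample_id <- sprintf("S%03d", seq_len(n))
  pop <- factor(rep(paste0("P", seq_len(cfg$n_pops)),
                    each = cfg$n_subpops_per_pop * cfg$samples_per_subpop))
  subpop <- factor(rep(sprintf("P%d.%d",
                               rep(seq_len(cfg$n_pops), each = cfg$n_subpops_per_pop),
                               rep(seq_len(cfg$n_subpops_per_pop), cfg$n_pops)),
                       each = cfg$samples_per_subpop))
  sub_of_pop <- rep(seq_len(cfg$n_pops), each = cfg$n_subpops_per_pop)

  ## --- marker map -----------------------------------------------------------
  lg <- rep(lgs, each = cfg$snps_per_group)
  cM <- as.vector(vapply(seq_len(cfg$n_linkage_groups), function(i)
    sort(stats::runif(cfg$snps_per_group, 0, cfg$map_length_cM)),
    numeric(cfg$snps_per_group)))
  marker_id <- sprintf("%s_%04d", lg, rep(seq_len(cfg$snps_per_group),
                                          cfg$n_linkage_groups))
  bases <- c("A", "C", "G", "T")
  anc_base <- sample(bases, m, replace = TRUE)
  der_base <- vapply(anc_base, function(b) sample(setdiff(bases, b), 1L), "")

  ## --- frequencies ----------------------------------------------------------
  p0 <- stats::runif(m, cfg$ascertainment_maf_min, 1 - cfg$ascertainment_maf_min)
  pop_freq <- vapply(seq_len(cfg$n_pops), function(k) rbn(p0, cfg$F_pop),
                     numeric(m))                      # m x n_pops
  sub_freq <- matrix(NA_real_, m, n_sub_total)
  for (s in seq_len(n_sub_total))
    sub_freq[, s] <- rbn(pop_freq[, sub_of_pop[s]], cfg$F_subpop)

  ## --- regions --------------------------------------------------------------
  region_markers <- list()
  for (ri in seq_along(cfg$region_specs)) {
    rs <- cfg$region_specs[[ri]]
    region_markers[[ri]] <- which(lg == rs$linkage_group &
                                  cM >= rs$cM_lo & cM <= rs$cM_hi)
  }
  in_region <- if (length(region_markers)) unlist(region_markers) else integer(0)

  ## --- environmental-effect SNPs -------------------------------------------
  env_effect <- numeric(m)
  env_idx <- integer(0)
  if (cfg$n_env_snps > 0) {
    free <- setdiff(seq_len(m), in_region)
    env_idx <- sort(sample(free, min(cfg$n_env_snps, length(free))))
    env_effect[env_idx] <- cfg$env_effect_size * sample(c(-1, 1), length(env_idx),
                                                        replace = TRUE)
  }

  ## --- geography (km plane, mountain line at x = 0) -------------------------
  side <- ifelse(as.integer(pop) == 1L, -1, 1)       # pop 1 west of the line
  pop_center_x <- side * 400
  sub_center_x <- sub_center_y <- numeric(n_sub_total)
  for (s in seq_len(n_sub_total)) {
    sgn <- if (sub_of_pop[s] == 1L) -1 else 1
    cx <- sgn * 400 + stats::rnorm(1, 0, 150)
    # subpopulations never cross the mountain line
    if (sign(cx) != sgn) cx <- sgn * abs(cx)
    sub_center_x[s] <- cx
    sub_center_y[s] <- stats::rnorm(1, 0, 150)
  }
  si <- as.integer(subpop)
  x_km <- sub_center_x[si] + stats::rnorm(n, 0, 80)
  x_km <- ifelse(sign(x_km) != side, side * abs(x_km), x_km)  # stay on own side
  y_km <- sub_center_y[si] + stats::rnorm(n, 0, 80)
  lat <- 35 + y_km / 111.1949
  lon <- 48 + x_km / (111.1949 * cos(lat * pi / 180))

  ## environmental gradient (longitude-driven, the "precipitation" axis).
  ## Effects act on each sample's own local environment, so allele
  ## frequencies at effect SNPs form a continuous spatial cline rather than a
  ## step coinciding with the population split.
  z_env <- as.numeric(scale(x_km))
  z_sub_env <- as.numeric(scale(sub_center_x))
  if (n_sub_total == 1L) z_sub_env <- 0

  ## --- genotype draws -------------------------------------------------------
  geno <- matrix(0L, n, m, dimnames = list(sample_id, marker_id))
  for (s in seq_len(n_sub_total)) {
    rows <- which(si == s)
    pmat <- matrix(sub_freq[, s], length(rows), m, byrow = TRUE)
    if (length(env_idx)) {
      shift <- outer(z_env[rows], env_effect[env_idx])
      pmat[, env_idx] <- clamp(invlogit(logit(pmat[, env_idx]) + shift),
                               1e-6, 1 - 1e-6)
    }
    geno[rows, ] <- matrix(as.integer(stats::runif(length(rows) * m) < pmat),
                           length(rows), m)
  }

  ## --- backbone haplotypes in regions ---------------------------------------
  backbones <- list()
  backbone_choice <- matrix(NA_integer_, n, length(region_markers),
                            dimnames = list(sample_id, NULL))
  for (ri in seq_along(region_markers)) {
    idx <- region_markers[[ri]]
    rs <- cfg$region_specs[[ri]]
    nb <- rep_len(as.integer(rs$n_backbone %||% 2L), cfg$n_pops)
    div <- as.numeric(rs$divergence %||% 0.5)
    # per-population target frequencies diverge around the ancestral value
    offs <- if (cfg$n_pops == 1L) 0 else
      seq(-0.5, 0.5, length.out = cfg$n_pops) * div
    pop_bb <- list()
    for (k in seq_len(cfg$n_pops)) {
      q <- clamp(p0[idx] + offs[k], 0.05, 0.95)
      hap <- matrix(as.integer(stats::runif(nb[k] * length(idx)) <
                               rep(q, each = nb[k])), nb[k], length(idx))
      pop_bb[[k]] <- hap
      rows <- which(as.integer(pop) == k)
      pick <- sample.int(nb[k], length(rows), replace = TRUE)
      geno[rows, idx] <- hap[pick, , drop = FALSE]
      backbone_choice[rows, ri] <- pick
    }
    backbones[[ri]] <- pop_bb
  }

  ## --- coding flips (ref allele not always ancestral) -----------------------
  flip <- stats::runif(m) < 0.3
  geno[, flip] <- 1L - geno[, flip]
  ref <- ifelse(flip, der_base, anc_base)
  alt <- ifelse(flip, anc_base, der_base)
  ancestral_state <- anc_base
  no_anc <- stats::runif(m) < 0.08        # outgroup base unavailable
  third <- stats::runif(m) < 0.02         # outgroup base matches neither allele
  ancestral_state[no_anc] <- NA_character_
  for (j in which(third & !no_anc))
    ancestral_state[j] <- sample(setdiff(bases, c(ref[j], alt[j])), 1L)

  ## --- annotation -----------------------------------------------------------
  genic <- stats::runif(m) < 0.75
  codon_effect <- ifelse(genic,
    sample(c("synonymous", "nonsynonymous", "noncoding"), m, TRUE,
           prob = c(0.35, 0.30, 0.35)),
    sample(c("noncoding", "unknown"), m, TRUE, prob = c(0.7, 0.3)))
  centromeric <- abs(cM - cfg$map_length_cM / 2) <= 5

  ## --- environment ----------------------------------------------------------
  zlat <- as.numeric(scale(lat))
  zlon <- as.numeric(scale(lon))
  load1 <- c(tmean = 0.95, tmin = 0.85, tseas = 0.75,
             prec = 0.15, pwin = 0.10, alt = -0.30)
  load2 <- c(tmean = 0.15, tmin = 0.25, tseas = -0.10,
             prec = -0.90, pwin = -0.85, alt = 0.80)
  env <- sapply(names(load1), function(v)
    load1[[v]] * zlat + load2[[v]] * zlon + stats::rnorm(n, 0, cfg$env_noise_sd))
  env <- as.data.frame(env)
  names(env) <- c("temp_mean", "temp_min", "temp_seasonality",
                  "precip_annual", "precip_winter", "altitude")
  env <- cbind(sample_id = sample_id, env, stringsAsFactors = FALSE)

  ## --- error injection ------------------------------------------------------
  nm <- n * m
  miss <- which(stats::runif(nm) < cfg$missing_rate)
  het <- which(stats::runif(nm) < cfg$het_error_rate)
  geno[het] <- GENO_HET
  geno[miss] <- NA_integer_

  markers <- data.frame(marker_id = marker_id, linkage_group = lg, cM = cM,
                        ref = ref, alt = alt, ancestral_state = ancestral_state,
                        genic = genic, codon_effect = codon_effect,
                        centromeric = centromeric, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_id, latitude = lat, longitude = lon,
                        stringsAsFactors = FALSE)
  truth <- list(pop = pop, subpop = subpop,
                pop_of_subpop = stats::setNames(sub_of_pop, levels(subpop)),
                region_markers = lapply(region_markers, function(i) marker_id[i]),
                backbones = backbones, backbone_choice = backbone_choice,
                env_effect = stats::setNames(env_effect, marker_id),
                env_gradient = stats::setNames(z_env, sample_id),
                env_gradient_subpop = stats::setNames(z_sub_env, levels(subpop)),
                sub_freq = `dimnames<-`(sub_freq, list(marker_id, levels(subpop))),
                pop_freq = `dimnames<-`(pop_freq, list(marker_id,
                                                       paste0("P", seq_len(cfg$n_pops)))),
                flip = stats::setNames(flip, marker_id),
                ancestral_allele_is_ref = stats::setNames(!flip, marker_id))
  structure(list(genotypes = geno, markers = markers, samples = samples,
                 env = env, truth = truth, config = cfg),
            class = "sim_bundle")
}

#' Write a simulated bundle to plain-text fixture files
#'
#' Writes the genotype matrix both as a haploid VCF 4.2 (`genotypes.vcf`,
#' heterozygote flags encoded as `0/1`, missing as `.`) and as the package's
#' genotype TSV dialect (`genotypes.tsv`: one row per marker, columns
#' `marker_id`, `ref`, `alt`, then one column per sample with cells drawn from
#' the ref base, the alt base, `H` and `N`), plus `markers.csv`, `samples.csv`,
#' `env.csv`, the ground truth as `truth.json`, and `manifest.csv` with md5
#' checksums. Output is byte-identical across runs for the same bundle.
#'
#' @param bundle result of [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_fixture <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir)
  g <- bundle$genotypes
  mk <- bundle$markers

  ## VCF ---------------------------------------------------------------------
  pos <- as.integer(round(mk$cM * 1000))
  # enforce strictly increasing positions within a linkage group
  for (lgv in unique(mk$linkage_group)) {
    i <- which(mk$linkage_group == lgv)
    p <- pos[i]
    for (k in seq_along(p)[-1]) if (p[k] <= p[k - 1]) p[k] <- p[k - 1] + 1L
    pos[i] <- p
  }
  gt <- matrix(".", nrow(g), ncol(g))
  gt[which(g == 0L)] <- "0"
  gt[which(g == 1L)] <- "1"
  gt[which(g == GENO_HET)] <- "0/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=geodiff_simdata",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- paste(mk$linkage_group, pos, mk$marker_id, mk$ref, mk$alt, ".", ".",
                ".", "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), file.path(out_dir, "genotypes.vcf"))

  ## TSV dialect -------------------------------------------------------------
  cells <- matrix("N", nrow(g), ncol(g))
  refm <- matrix(mk$ref, nrow(g), ncol(g), byrow = TRUE)
  altm <- matrix(mk$alt, nrow(g), ncol(g), byrow = TRUE)
  cells[which(g == 0L)] <- refm[which(g == 0L)]
  cells[which(g == 1L)] <- altm[which(g == 1L)]
  cells[which(g == GENO_HET)] <- "H"
  tsv <- data.frame(marker_id = mk$marker_id, ref = mk$ref, alt = mk$alt,
                    t(cells), stringsAsFactors = FALSE)
  names(tsv) <- c("marker_id", "ref", "alt", rownames(g))
  data.table::fwrite(tsv, file.path(out_dir, "genotypes.tsv"), sep = "\t")

  ## tables ------------------------------------------------------------------
  data.table::fwrite(mk, file.path(out_dir, "markers.csv"))
  data.table::fwrite(bundle$samples, file.path(out_dir, "samples.csv"))
  data.table::fwrite(bundle$env, file.path(out_dir, "env.csv"))

  truth <- bundle$truth
  truth$pop <- as.character(truth$pop)
  truth$subpop <- as.character(truth$subpop)
  truth$backbone_choice <- as.data.frame(truth$backbone_choice)
  truth$sub_freq <- NULL; truth$pop_freq <- NULL   # bulky; regenerate from seed
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  files <- c("genotypes.vcf", "genotypes.tsv", "markers.csv", "samples.csv",
             "env.csv", "truth.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
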