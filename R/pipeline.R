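#' Default pipeline configuration
#'
#' A nested list controlling [run_pipeline()]. Either `sim` (a [sim_config()]
#' argument list) or `input` (paths to genotype/marker/sample/env files) must
#' be present. Every stochastic stage carries an explicit seed. The config
#' round-trips losslessly through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param sim list of [sim_config()] arguments (NULL to read files instead).
#' @param input list with `genotypes`, `format`, `markers`, `samples`, `env`
#'   paths (used when `sim` is NULL; `env` optional).
#' @param seed master seed; stage seeds default to offsets from it.
#' @param scale one of `"test"` (small, minutes) or `"full"` (publication-scale
#'   sampler sizes: 1e5/1e5 assignment sweeps, 3e4 covariance iterations,
#'   5e4 Bayes-factor draws).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = list(), input = NULL, seed = 1L,
                            scale = c("test", "full")) {
  scale <- match.arg(scale)
  big <- scale == "full"
  cfg <- list(
    sim = sim, input = input, seed = as.integer(seed),
    qc = list(max_missing = 0.15, max_het = 0.10),
    haplotype_window = 5L,
    assign = list(K = 2L,
                  n_burn = if (big) 1e5 else 500,
                  n_iter = if (big) 1e5 else 500,
                  n_runs = if (big) 10 else 3),
    regions = NULL,                      # NULL = take from sim config
    percentiles = c(95, 99),
    env = list(target_mean_size = 17,
               cov_iter = if (big) 3e4 else 2000,
               bf_draws = if (big) 5e4 else 500,
               bf_estimates = if (big) 5 else 2),
    mantel_perm = 999,
    hierf_perm = 100)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: data acquisition (simulate or read), QC,
#' polarisation, haplotype windows, genotype PCA + Velicer MAP + Ward
#' stratification, Mantel test, Procrustes rotation onto geography, genetic
#' assignment, F_ST scans (population and subpopulation level) with
#' hierarchical F-statistics, LD scan and region contrasts, environmental PCA
#' and Bayenv-style Bayes factors, SPA scores, percentile outlier calling and
#' enrichment. Writes per-stage CSVs plus `manifest.json` (seeds, stage log,
#' file checksums) under `out_dir` and returns the result bundle invisibly.
#' Stages whose inputs are absent (e.g. no environment table) are skipped and
#' noted in the manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- list(); res <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  wcsv <- function(x, f) {
    data.table::fwrite(as.data.frame(x), file.path(out_dir, f))
    f
  }
  files <- character(0)

  ## data ---------------------------------------------------------------------
  if (!is.null(config$sim)) {
    bundle <- t_stage("simulate", {
      args <- config$sim
      if (is.null(args$seed)) args$seed <- config$seed
      simulate_dataset(do.call(sim_config, args))
    })
    g0 <- bundle$genotypes; markers <- bundle$markers
    samples <- bundle$samples; env <- bundle$env
    regions <- config$regions %||% lapply(bundle$config$region_specs, function(r)
      r[c("linkage_group", "cM_lo", "cM_hi")])
    truth_pop <- bundle$truth$pop; truth_sub <- bundle$truth$subpop
  } else {
    inp <- config$input
    g0 <- t_stage("read", read_genotypes(inp$genotypes, inp$format %||% "vcf"))
    markers <- as.data.frame(data.table::fread(inp$markers))
    samples <- as.data.frame(data.table::fread(inp$samples))
    env <- if (!is.null(inp$env)) as.data.frame(data.table::fread(inp$env))
    regions <- config$regions
    truth_pop <- truth_sub <- NULL
  }

  ## qc + polarize + haplotypes ----------------------------------------------
  qc <- t_stage("qc", qc_filter(g0, config$qc$max_missing, config$qc$max_het))
  g <- qc$genotypes
  files <- c(files, wcsv(data.frame(rule = names(qc$report),
                                    count = unlist(qc$report)), "qc_report.csv"))
  if ("ancestral_state" %in% names(markers))
    g <- t_stage("polarize", polarize(g, markers))
  hb <- t_stage("haplotypes",
                build_haplotypes(g, markers, config$haplotype_window))

  ## structure ----------------------------------------------------------------
  pca <- t_stage("pca", genotype_pca(g))
  nmap <- t_stage("velicer", velicer_map(geno_impute(g), k_max = 20L))
  n_pcs <- max(2L, nmap$n_components)
  assign_res <- t_stage("assign", gibbs_assign(
    g, config$assign$K, config$assign$n_burn, config$assign$n_iter,
    config$assign$n_runs, seed = config$seed + 11L))
  pop <- factor(assign_res$labels)
  files <- c(files, wcsv(data.frame(sample_id = rownames(g), assign_res$Q,
                                    label = assign_res$labels), "assignment.csv"))
  sub_k <- min(nrow(g), max(2L, 2L * config$assign$K))
  subpop <- factor(ward_clusters(pca$scores[, seq_len(n_pcs), drop = FALSE],
                                 sub_k)$labels)

  ## geography ----------------------------------------------------------------
  dgeo <- great_circle_km(samples$latitude, samples$longitude)
  dgen <- allele_sharing_dist(g)
  mt <- t_stage("mantel", mantel(dgen, dgeo, config$mantel_perm,
                                 seed = config$seed + 23L))
  pro <- t_stage("procrustes", procrustes_to_geography(
    pca$scores[, 1:2], cbind(samples$longitude, samples$latitude)))

  ## F_ST ---------------------------------------------------------------------
  scan_pop <- t_stage("fst", wc_fst(g, pop))
  hier <- if (nlevels(pop) > 1 && nlevels(subpop) > nlevels(pop))
    t_stage("hierf", tryCatch(
      hierarchical_f(g, pop, interaction(pop, subpop, drop = TRUE),
                     n_perm = config$hierf_perm, seed = config$seed + 31L),
      error = function(e) NULL))
  mk_scan <- markers[match(scan_pop$marker_id, markers$marker_id), ]
  fst_out <- call_outliers(scan_pop$theta, config$percentiles[1],
                           truncate_at_zero = TRUE)
  files <- c(files, wcsv(cbind(mk_scan[, c("marker_id", "linkage_group", "cM")],
                               a = scan_pop$a, t = scan_pop$t,
                               theta = scan_pop$theta,
                               fst_outlier = fst_out$flag), "fst_scan.csv"))

  ## LD + regions -------------------------------------------------------------
  ld <- t_stage("ld", pairwise_r2(g, markers))
  region_rows <- list()
  for (ri in seq_along(regions)) {
    r <- as_region(regions[[ri]])
    rf <- region_fst(scan_pop, markers, r)
    rl <- region_ld_contrast(ld, r)
    region_rows[[ri]] <- data.frame(
      region = paste0(r$linkage_group, ":", r$cM_lo, "-", r$cM_hi),
      fst = rf$theta, n_markers = rf$n_markers,
      r2_inside = rl$inside, r2_outside = rl$outside)
  }
  if (length(region_rows))
    files <- c(files, wcsv(do.call(rbind, region_rows), "regions.csv"))

  ## diversity ----------------------------------------------------------------
  div_rows <- lapply(levels(pop), function(l) {
    idx <- which(pop == l)
    pp <- percent_pairwise_difference(g, idx)
    data.frame(group = l, n = length(idx), S = segregating_sites(g, idx),
               pct_pairwise = pp[["mean"]], pct_pairwise_sd = pp[["sd"]])
  })
  div <- do.call(rbind, div_rows)
  div$private <- private_snps(g, pop)[div$group]
  files <- c(files, wcsv(div, "diversity.csv"))

  ## environment --------------------------------------------------------------
  env_res <- NULL
  if (!is.null(env)) {
    epc <- t_stage("env_pca", env_pca(env))
    clusters <- t_stage("clusters", make_population_clusters(
      g, pca$scores[, seq_len(n_pcs), drop = FALSE], epc$scores,
      config$env$target_mean_size))
    cov <- t_stage("covariance", estimate_covariance(
      clusters, n_iter = config$env$cov_iter, seed = config$seed + 41L))
    bf1 <- t_stage("bayes_factor", bayes_factor(
      clusters, clusters$env[, 1], cov, n_draws = config$env$bf_draws,
      n_estimates = config$env$bf_estimates, seed = config$seed + 43L))
    spa <- t_stage("spa", spa_score(g, cbind(samples$longitude,
                                             samples$latitude)))
    bf_out <- call_outliers(bf1$log10_bf, config$percentiles[1])
    spa_out <- call_outliers(spa$score, config$percentiles[1])
    files <- c(files, wcsv(cbind(
      mk_scan[, c("marker_id", "linkage_group", "cM")],
      theta = scan_pop$theta, log10_bf_pc1 = bf1$log10_bf,
      spa_score = spa$score, fst_outlier = fst_out$flag,
      bf_outlier = bf_out$flag, spa_outlier = spa_out$flag), "env_scan.csv"))
    enr <- if (any(fst_out$flag) && "genic" %in% names(markers))
      t_stage("enrichment", enrichment_resample(
        scan_pop$marker_id[fst_out$flag], markers, "genic_vs_nongenic",
        seed = config$seed + 47L))
    env_res <- list(env_pca = epc, clusters = clusters, cov = cov, bf = bf1,
                    spa = spa, enrichment = enr)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("geodiff")),
                   seed = config$seed,
                   stages_run = names(log), stage_seconds = log,
                   skipped = if (is.null(env)) "environment stages" else character(0),
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  checks <- data.frame(file = files,
                       md5 = unname(tools::md5sum(file.path(out_dir, files))))
  data.table::fwrite(checks, file.path(out_dir, "checksums.csv"))
  invisible(list(genotypes = g, markers = markers, samples = samples,
                 qc = qc$report, pca = pca, velicer = nmap,
                 assignment = assign_res, pop = pop, subpop = subpop,
                 mantel = mt, procrustes = pro, fst = scan_pop, hierf = hier,
                 ld = ld, regions = if (length(region_rows))
                   do.call(rbind, region_rows), diversity = div,
                 env = env_res, truth = list(pop = truth_pop, sub = truth_sub),
                 manifest = manifest))
}

#' Command-line entry point
#'
#' Backs the `geodiff` executable script (`inst/exec/geodiff`). Subcommands:
#' `run <config.json> <out_dir>` (full pipeline), `simulate <out_dir>`
#' (fixture generation), `qc --in --format --out`. A `--seed` option
#' overrides the config seed.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 ok, 1 data error, 2 usage/config error), invisibly.
#' @export
geodiff_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: geodiff <run|simulate|qc> [options]"
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]; rest <- args[-1]
  seed_i <- which(rest == "--seed")
  seed <- if (length(seed_i)) as.integer(rest[seed_i + 1]) else NULL
  if (length(seed_i)) rest <- rest[-c(seed_i, seed_i + 1)]
  status <- tryCatch({
    if (cmd == "run") {
      if (length(rest) < 2) stop(usage, call. = FALSE)
      cfg <- read_pipeline_config(rest[1])
      if (!is.null(seed)) cfg$seed <- seed
      run_pipeline(cfg, rest[2])
      0L
    } else if (cmd == "simulate") {
      if (length(rest) < 1) stop(usage, call. = FALSE)
      b <- simulate_dataset(sim_config(seed = seed %||% 1L))
      write_fixture(b, rest[1])
      0L
    } else if (cmd == "qc") {
      opt <- parse_kv(rest)
      g <- read_genotypes(opt[["in"]], opt[["format"]] %||% "vcf")
      qc <- qc_filter(g)
      data.table::fwrite(data.frame(rule = names(qc$report),
                                    count = unlist(qc$report)), opt[["out"]])
      0L
    } else {
      message(usage); 2L
    }
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

parse_kv <- function(args) {
  keys <- grep("^--", args)
  stats::setNames(as.list(args[keys + 1]), sub("^--", "", args[keys]))
}
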