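#' Simulation configuration for a multi-environment wheat trial
#'
#' Builds the parameter set used by [simulate_markers()], [simulate_trial()]
#' and [simulate_physiology()]. Defaults emulate a soft winter-wheat diversity
#' panel of 242 inbred lines genotyped at ~19k GBS SNPs and evaluated in four
#' environments in an un-replicated augmented design with three repeated
#' checks per block. Variance defaults give a plot-level grain-yield
#' heritability of about 0.33, inside the 0.20-0.41 range typical of such
#' trials.
#'
#' @param n_lines number of inbred lines (including checks).
#' @param n_markers number of biallelic SNP markers.
#' @param n_envs number of environments.
#' @param n_blocks_per_env incomplete blocks per environment.
#' @param check_ids labels of the lines used as repeated checks (analogues of
#'   the three commercial check varieties of an augmented design). Must be a
#'   subset of the generated line labels \code{LINE_1..n_lines} or custom
#'   labels supplied via \code{line_ids}.
#' @param line_ids optional explicit line labels (length \code{n_lines}).
#' @param maf_range range (min, max) in (0, 0.5] from which ancestral minor
#'   allele frequencies are drawn uniformly.
#' @param missing_rate fraction in [0, 1) of genotype calls masked as missing.
#' @param het_rate residual heterozygote rate (inbred panel: default 0).
#' @param n_families number of sub-populations (families) used to give the
#'   panel a realistic genetic structure; lines are assigned round-robin.
#' @param fst Wright's fixation index controlling between-family marker
#'   divergence (Balding-Nichols model); 0 gives an unstructured panel.
#' @param var_genetic genetic variance of true line values, (kg/ha)^2.
#' @param var_ge genotype-by-environment variance, (kg/ha)^2.
#' @param var_error plot residual variance, (kg/ha)^2.
#' @param env_means per-environment yield intercepts, kg/ha.
#' @param block_sd standard deviation of block effects, kg/ha.
#' @param n_qtl number of markers carrying yield effects (default: 300 or
#'   \code{n_markers}, whichever is smaller).
#' @param physio_loadings named vector of per-trait regression coefficients of
#'   the trait on the true genetic-plus-GE value (kg/ha scale). The canopy
#'   temperature loading is negative by default: cooler canopies go with
#'   higher yield.
#' @param physio_noise_sd named vector of per-trait measurement noise SDs.
#' @param trait_means named vector of per-trait means (SPAD units, degrees C,
#'   MT percent).
#' @param ndvi_intercept_mean,ndvi_intercept_sd mean/SD of the per-plot NDVI
#'   decay intercept b in NDVI(AGDD) = b + m AGDD.
#' @param ndvi_slope_mean,ndvi_slope_sd mean/SD of the per-plot senescence
#'   slope m, per degree C day.
#' @param ndvi_slope_loading coefficient of the slope on the true
#'   genetic-plus-GE value (negative: high-yield lines senesce slower).
#' @param ndvi_noise_sd measurement noise SD of each NDVI reading.
#' @param agdd_points six strictly increasing thermal-time stamps (degree C
#'   day after planting) at which NDVI is read.
#' @param agdd_pm thermal time at physiological maturity, degree C day.
#' @param dth_mean,dth_sd mean and residual SD of days to heading.
#' @param dth_loading coefficient of DTH on the true genetic-plus-GE value.
#' @param seed integer seed; identical configs give bit-identical output.
#'
#' @return A list of class \code{"sim_config"}.
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 50, n_markers = 500, n_envs = 2,
#'                   n_blocks_per_env = 3, seed = 11)
#' mk <- simulate_markers(cfg)
#' dim(mk$dosage)
sim_config <- function(n_lines = 242,
                       n_markers = 19353,
                       n_envs = 4,
                       n_blocks_per_env = 12,
                       check_ids = c("LINE_1", "LINE_2", "LINE_3"),
                       line_ids = NULL,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.10,
                       het_rate = 0,
                       n_families = 10,
                       fst = 0.15,
                       var_genetic = 60000,
                       var_ge = 30000,
                       var_error = 120000,
                       env_means = NULL,
                       block_sd = 150,
                       n_qtl = NULL,
                       physio_loadings = c(SPAD = 0.006, CT = -0.001, MT = 0.010),
                       physio_noise_sd = c(SPAD = 3.9, CT = 0.7, MT = 9.5),
                       trait_means = c(SPAD = 50, CT = 27, MT = 57),
                       ndvi_intercept_mean = 1.0,
                       ndvi_intercept_sd = 0.02,
                       ndvi_slope_mean = -5e-4,
                       ndvi_slope_sd = 1e-4,
                       ndvi_slope_loading = -1.6e-7,
                       ndvi_noise_sd = 0.02,
                       agdd_points = c(400, 550, 700, 850, 1000, 1150),
                       agdd_pm = 1300,
                       dth_mean = 107,
                       dth_sd = 3.6,
                       dth_loading = -0.006,
                       seed = 1L) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 0.5]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (any(c(var_genetic, var_ge, var_error) < 0)) {
    stop("variance components must be non-negative")
  }
  if (is.null(n_qtl)) n_qtl <- min(300, n_markers)
  if (n_qtl > n_markers) stop("n_qtl cannot exceed n_markers")
  if (length(agdd_points) != 6) stop("agdd_points must hold six thermal-time stamps")
  if (any(diff(agdd_points) <= 0)) stop("agdd_points must be strictly increasing")
  if (is.null(env_means)) {
    env_means <- c(3500, 2250, 4650, 4800)[seq_len(min(n_envs, 4))]
    if (n_envs > 4) env_means <- c(env_means, rep(3800, n_envs - 4))
  }
  if (length(env_means) != n_envs) stop("env_means must have one entry per environment")
  if (is.null(line_ids)) line_ids <- sprintf("LINE_%d", seq_len(n_lines))
  if (length(line_ids) != n_lines || anyDuplicated(line_ids)) {
    stop("line_ids must be ", n_lines, " unique labels")
  }
  if (!all(check_ids %in% line_ids)) {
    stop("check_ids must be a subset of the line labels")
  }
  structure(list(
    n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
    n_envs = as.integer(n_envs), n_blocks_per_env = as.integer(n_blocks_per_env),
    check_ids = check_ids, line_ids = line_ids,
    maf_range = maf_range, missing_rate = missing_rate, het_rate = het_rate,
    n_families = as.integer(n_families), fst = fst,
    var_genetic = var_genetic, var_ge = var_ge, var_error = var_error,
    env_means = env_means, block_sd = block_sd, n_qtl = as.integer(n_qtl),
    physio_loadings = physio_loadings, physio_noise_sd = physio_noise_sd,
    trait_means = trait_means,
    ndvi_intercept_mean = ndvi_intercept_mean,
    ndvi_intercept_sd = ndvi_intercept_sd,
    ndvi_slope_mean = ndvi_slope_mean, ndvi_slope_sd = ndvi_slope_sd,
    ndvi_slope_loading = ndvi_slope_loading, ndvi_noise_sd = ndvi_noise_sd,
    agdd_points = agdd_points, agdd_pm = agdd_pm,
    dth_mean = dth_mean, dth_sd = dth_sd, dth_loading = dth_loading,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_lines, "lines x", x$n_markers, "markers,",
      x$n_envs, "environments,", x$n_blocks_per_env, "blocks/env\n")
  cat("  variances (G / GE / error):", x$var_genetic, "/", x$var_ge, "/",
      x$var_error, " seed:", x$seed, "\n")
  invisible(x)
}
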