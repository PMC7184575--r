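#' Simulate a structured inbred marker panel
#'
#' Draws biallelic SNP dosages (alternate-allele counts 0/1/2) for an inbred
#' panel with sub-population structure. Ancestral allele frequencies are drawn
#' uniformly from \code{maf_range}; family-specific frequencies follow the
#' Balding-Nichols model with fixation index \code{fst}, which produces the
#' family blocks that a genomic relationship matrix and a PCA-plus-k-means
#' stratification can recover. Heterozygotes occur at \code{het_rate}
#' (default 0) and calls are masked missing at \code{missing_rate}.
#'
#' @param config a [sim_config()] object.
#' @return A list of class \code{"sim_markers"} with elements
#'   \item{dosage}{lines x markers matrix with \code{NA} for missing calls,}
#'   \item{complete}{the same matrix before masking (simulation truth),}
#'   \item{family}{factor of family membership per line.}
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_lines < 2) stop("need at least 2 lines")
  if (config$n_markers < 1) stop("need at least 1 marker")
  set.seed(config$seed)
  n <- config$n_lines
  m <- config$n_markers
  p0 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  family <- factor(rep_len(seq_len(config$n_families), n))
  dosage <- matrix(0L, n, m,
                   dimnames = list(config$line_ids, sprintf("SNP_%d", seq_len(m))))
  fst <- config$fst
  for (fam in levels(family)) {
    idx <- which(family == fam)
    if (fst > 0) {
      shape <- (1 - fst) / fst
      pf <- stats::rbeta(m, p0 * shape, (1 - p0) * shape)
    } else {
      pf <- p0
    }
    # inbred lines: a line is fixed for the alternate allele with prob pf
    dosage[idx, ] <- 2L * matrix(
      stats::rbinom(length(idx) * m, 1L, rep(pf, each = length(idx))),
      nrow = length(idx))
  }
  if (config$het_rate > 0) {
    het <- matrix(stats::runif(n * m) < config$het_rate, n, m)
    dosage[het] <- 1L
  }
  complete <- dosage
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    dosage[miss] <- NA
  }
  structure(list(dosage = dosage, complete = complete, family = family),
            class = "sim_markers")
}

#' Simulate plot-level yields for an augmented multi-environment trial
#'
#' Generates true genetic values as a sum of QTL effects over the simulated
#' markers (\code{g = X beta}, with the effects rescaled so the population
#' variance of \code{g} hits \code{var_genetic} exactly), i.i.d. line-by-
#' environment deviations with variance \code{var_ge}, block effects, and
#' plot residuals. The field layout is an un-replicated augmented design:
#' every non-check line appears once per environment and every check appears
#' once in each block.
#'
#' @param markers a \code{"sim_markers"} object from [simulate_markers()].
#' @param config the same [sim_config()] used to generate the markers.
#' @return A list of class \code{"sim_trial"} with
#'   \item{plots}{plot-level data.frame (environment, block, genotype,
#'     is_check, GY),}
#'   \item{truth}{ground truth: named vector \code{g}, matrix \code{ge}
#'     (lines x environments), QTL indices and effects, block effects and the
#'     configured variance components.}
#' @export
simulate_trial <- function(markers, config) {
  stopifnot(inherits(markers, "sim_markers"), inherits(config, "sim_config"))
  if (!identical(rownames(markers$dosage), config$line_ids)) {
    stop("markers were not generated for this config's lines")
  }
  if (!all(config$check_ids %in% config$line_ids)) {
    stop("check_ids must be a subset of the line labels")
  }
  set.seed(config$seed + 1L)
  n <- config$n_lines
  X <- markers$complete
  qtl <- sort(sample.int(config$n_markers, config$n_qtl))
  beta <- stats::rnorm(config$n_qtl)
  g <- drop(X[, qtl, drop = FALSE] %*% beta)
  g <- g - mean(g)
  vg <- mean(g^2)                      # population variance
  if (config$var_genetic > 0) {
    if (vg < .Machine$double.eps) stop("degenerate QTL draw: zero genetic variance")
    scale <- sqrt(config$var_genetic / vg)
    g <- g * scale
    beta <- beta * scale
  } else {
    g <- rep(0, n)
    beta <- rep(0, config$n_qtl)
  }
  names(g) <- config$line_ids
  envs <- sprintf("ENV_%d", seq_len(config$n_envs))
  ge <- matrix(stats::rnorm(n * config$n_envs, sd = sqrt(config$var_ge)),
               n, config$n_envs, dimnames = list(config$line_ids, envs))
  blocks <- sprintf("B%d", seq_len(config$n_blocks_per_env))
  block_eff <- matrix(stats::rnorm(config$n_envs * config$n_blocks_per_env,
                                   sd = config$block_sd),
                      config$n_envs, config$n_blocks_per_env,
                      dimnames = list(envs, blocks))
  test_lines <- setdiff(config$line_ids, config$check_ids)
  plot_list <- vector("list", config$n_envs)
  for (i in seq_len(config$n_envs)) {
    # shuffle test entries over blocks as evenly as possible; checks in every block
    shuffled <- sample(test_lines)
    blk_test <- sort(rep_len(seq_len(config$n_blocks_per_env), length(shuffled)))
    df_test <- data.frame(environment = envs[i],
                          block = blocks[blk_test],
                          genotype = shuffled,
                          is_check = FALSE,
                          stringsAsFactors = FALSE)
    df_check <- expand.grid(block = blocks, genotype = config$check_ids,
                            stringsAsFactors = FALSE)
    df_check <- data.frame(environment = envs[i], block = df_check$block,
                           genotype = df_check$genotype, is_check = TRUE,
                           stringsAsFactors = FALSE)
    plot_list[[i]] <- rbind(df_test, df_check)
  }
  plots <- do.call(rbind, plot_list)
  rownames(plots) <- NULL
  eps <- stats::rnorm(nrow(plots), sd = sqrt(config$var_error))
  ei <- match(plots$environment, envs)
  li <- match(plots$genotype, config$line_ids)
  bi <- match(plots$block, blocks)
  plots$GY <- config$env_means[ei] + g[li] + ge[cbind(li, ei)] +
    block_eff[cbind(ei, bi)] + eps
  truth <- list(g = g, ge = ge, qtl = qtl, beta = beta,
                block_eff = block_eff,
                var_genetic = config$var_genetic, var_ge = config$var_ge,
                var_error = config$var_error, env_means = config$env_means)
  structure(list(plots = plots, truth = truth, config = config),
            class = "sim_trial")
}

#' Add simulated physiological traits to a trial
#'
#' Each scalar trait (SPAD, CT, MT) is generated as
#' \code{mean + loading * (g + ge) + noise} at the plot level; canopy
#' temperature gets a negative loading by default (cooler canopy, higher
#' yield). Membrane thermostability is realised through a pair of
#' conductivity readings \code{T1, T2} constructed so that
#' \code{MT = (1 - T1/T2) * 100} carries the configured loading. NDVI readings
#' follow a per-plot linear decay \code{b + m * AGDD} at the six configured
#' thermal-time stamps, the slope \code{m} loading on the true value; days to
#' heading is drawn with its own loading.
#'
#' @param trial a \code{"sim_trial"} from [simulate_trial()].
#' @param config the [sim_config()] used throughout.
#' @return The trial with \code{plots} gaining columns DTH, SPAD, CT, T1, T2,
#'   NDVI_1..6, AGDD_1..6 and AGDD_PM, and \code{truth} gaining the per-plot
#'   NDVI slope/intercept (\code{ndvi_slope}, \code{ndvi_intercept}).
#' @export
simulate_physiology <- function(trial, config) {
  stopifnot(inherits(trial, "sim_trial"), inherits(config, "sim_config"))
  if (length(config$agdd_points) != 6) {
    stop("agdd_points must hold six thermal-time stamps")
  }
  set.seed(config$seed + 2L)
  plots <- trial$plots
  li <- match(plots$genotype, names(trial$truth$g))
  ei <- match(plots$environment, colnames(trial$truth$ge))
  gge <- trial$truth$g[li] + trial$truth$ge[cbind(li, ei)]
  np <- nrow(plots)

  plots$DTH <- config$dth_mean + config$dth_loading * gge +
    stats::rnorm(np, sd = config$dth_sd)
  for (tr in c("SPAD", "CT", "MT")) {
    val <- config$trait_means[[tr]] + config$physio_loadings[[tr]] * gge +
      stats::rnorm(np, sd = config$physio_noise_sd[[tr]])
    if (tr == "MT") {
      t2 <- abs(stats::rnorm(np, 100, 5)) + 1
      plots$T2 <- t2
      plots$T1 <- (1 - val / 100) * t2
    } else {
      plots[[tr]] <- val
    }
  }
  b <- stats::rnorm(np, config$ndvi_intercept_mean, config$ndvi_intercept_sd)
  m <- config$ndvi_slope_mean + config$ndvi_slope_loading * gge +
    stats::rnorm(np, sd = config$ndvi_slope_sd)
  n_clipped <- 0L
  for (k in 1:6) {
    ndvi <- b + m * config$agdd_points[k] +
      stats::rnorm(np, sd = config$ndvi_noise_sd)
    out_of_range <- ndvi < 0 | ndvi > 1
    n_clipped <- n_clipped + sum(out_of_range)
    plots[[paste0("NDVI_", k)]] <- pmin(pmax(ndvi, 0), 1)
    plots[[paste0("AGDD_", k)]] <- config$agdd_points[k]
  }
  if (n_clipped > 0) {
    warning(n_clipped, " NDVI readings clipped to [0, 1]")
  }
  plots$AGDD_PM <- config$agdd_pm
  trial$plots <- plots
  trial$truth$ndvi_slope <- m
  trial$truth$ndvi_intercept <- b
  trial
}

#' Simulate daily temperatures per environment
#'
#' A light-weight weather generator supplying the daily minimum/maximum
#' temperature series from which accumulated growing degree days are
#' computed. Temperatures follow a seasonal ramp plus noise, warm enough that
#' thermal time accumulates every day.
#'
#' @param config a [sim_config()].
#' @param n_days number of days from planting.
#' @return data.frame with columns environment, day, tmin, tmax.
#' @export
simulate_weather <- function(config, n_days = 160) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  envs <- sprintf("ENV_%d", seq_len(config$n_envs))
  out <- lapply(seq_along(envs), function(i) {
    day <- seq_len(n_days)
    base <- 8 + 12 * day / n_days + stats::rnorm(n_days, sd = 1.5) + (i - 1) * 0.5
    spread <- 4 + abs(stats::rnorm(n_days, 4, 1))
    data.frame(environment = envs[i], day = day,
               tmin = base - spread / 2, tmax = base + spread / 2)
  })
  do.call(rbind, out)
}
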