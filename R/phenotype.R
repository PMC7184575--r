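#' Membrane thermostability from paired conductivity readings
#'
#' \code{MT = (1 - T1/T2) * 100}, where \code{T1} is the conductivity after
#' the heat treatment and \code{T2} the conductivity after autoclaving
#' (total electrolytes). Values are percentages, at most 100; negative values
#' (T1 > T2) indicate a data problem and raise a warning.
#'
#' @param t1 conductivity after heat treatment (>= 0), vectorised.
#' @param t2 conductivity after autoclaving (> 0), vectorised.
#' @return MT percent.
#' @export
#' @examples
#' membrane_thermostability(20, 80)   # 75
membrane_thermostability <- function(t1, t2) {
  if (any(t2 <= 0, na.rm = TRUE)) stop("t2 must be positive")
  if (any(t1 < 0, na.rm = TRUE)) stop("t1 must be non-negative")
  mt <- (1 - t1 / t2) * 100
  if (any(mt < 0, na.rm = TRUE)) {
    warning("negative MT value(s): T1 exceeds T2 — check the readings")
  }
  mt
}

#' Accumulated growing degree days
#'
#' Cumulative sum of daily \code{max(0, (tmax + tmin)/2 - t_base)} from the
#' first day of the series (planting).
#'
#' @param tmin,tmax aligned daily temperature series, degrees C.
#' @param t_base base temperature, degrees C (default 0, a common choice for
#'   winter wheat).
#' @return AGDD series, degree C day.
#' @export
accumulate_gdd <- function(tmin, tmax, t_base = 0) {
  if (length(tmin) != length(tmax)) stop("tmin and tmax must be aligned")
  if (any(tmax < tmin, na.rm = TRUE)) stop("tmax must be >= tmin for every day")
  cumsum(pmax(0, (tmax + tmin) / 2 - t_base))
}

#' Fit the linear NDVI decay over thermal time
#'
#' Ordinary least squares line \code{NDVI = b + m * AGDD} through the
#' available (AGDD, NDVI) pairs; the slope \code{m} is the rate of senescence
#' (RS).
#'
#' @param ndvi NDVI readings (missing allowed).
#' @param agdd matching thermal-time stamps, degree C day.
#' @return list with \code{slope} (per degree C day) and \code{intercept}.
#' @export
fit_ndvi_decay <- function(ndvi, agdd) {
  if (length(ndvi) != length(agdd)) stop("ndvi and agdd must be aligned")
  ok <- !is.na(ndvi) & !is.na(agdd)
  if (sum(ok) < 2) stop("need at least 2 non-missing (ndvi, agdd) pairs")
  x <- agdd[ok]; y <- ndvi[ok]
  vx <- mean((x - mean(x))^2)
  if (vx < .Machine$double.eps) stop("AGDD stamps have zero variance")
  m <- mean((x - mean(x)) * (y - mean(y))) / vx
  list(slope = m, intercept = mean(y) - m * mean(x))
}

#' Stay-green: predicted NDVI at physiological maturity
#'
#' Evaluates the fitted decay line at the thermal time of physiological
#' maturity: \code{SG = m * AGDD_PM + b}. NDVI is physically bounded in
#' [0, 1]; by default out-of-range predictions are returned as-is with a
#' warning, or clipped on request.
#'
#' @param slope,intercept decay-line coefficients from [fit_ndvi_decay()].
#' @param agdd_pm thermal time at physiological maturity, degree C day.
#' @param clip clip the result to [0, 1]? Default FALSE.
#' @return SG value (unitless).
#' @export
#' @examples
#' stay_green(-5e-4, 0.8, 1000)   # 0.3
stay_green <- function(slope, intercept, agdd_pm, clip = FALSE) {
  sg <- slope * agdd_pm + intercept
  out <- sg < 0 | sg > 1
  if (clip) {
    sg <- pmin(pmax(sg, 0), 1)
  } else if (any(out, na.rm = TRUE)) {
    warning(sum(out, na.rm = TRUE), " SG value(s) outside [0, 1]")
  }
  sg
}

#' Add derived physiological traits to a plot table
#'
#' Computes MT from the conductivity pair (T1, T2), and per-plot RS (decay
#' slope) and SG (predicted NDVI at maturity) from the NDVI_1..6 readings and
#' their AGDD_1..6 stamps plus AGDD_PM.
#'
#' @param plots plot-level data.frame with columns T1, T2, NDVI_1..6,
#'   AGDD_1..6, AGDD_PM (any subset; only available traits are derived).
#' @return the plot table with MT, RS and SG columns appended.
#' @export
derive_plot_traits <- function(plots) {
  if (all(c("T1", "T2") %in% names(plots))) {
    plots$MT <- membrane_thermostability(plots$T1, plots$T2)
  }
  ndvi_cols <- paste0("NDVI_", 1:6)
  agdd_cols <- paste0("AGDD_", 1:6)
  if (all(c(ndvi_cols, agdd_cols, "AGDD_PM") %in% names(plots))) {
    nd <- as.matrix(plots[, ndvi_cols])
    ag <- as.matrix(plots[, agdd_cols])
    rs <- numeric(nrow(plots)); sg <- numeric(nrow(plots))
    for (i in seq_len(nrow(plots))) {
      f <- fit_ndvi_decay(nd[i, ], ag[i, ])
      rs[i] <- f$slope
      sg[i] <- f$slope * plots$AGDD_PM[i] + f$intercept
    }
    plots$RS <- rs
    plots$SG <- sg
  }
  plots
}

#' Genotype least-squares means from the augmented-trial mixed model
#'
#' Fits, per environment (default) or jointly, a mixed model with genotype as
#' a fixed effect and block (and environment, in the joint model) as random
#' effects, optionally with days-to-heading as a fixed covariate; returns the
#' genotype LSmeans (adjusted means, evaluated at the mean DTH when the
#' covariate is used) and their standard errors. Variance components are
#' estimated by REML through \pkg{lme4}. With a single block and no
#' covariate the model degenerates gracefully to per-genotype raw means.
#'
#' @param plots plot table with environment, block, genotype and the trait.
#' @param trait column name to analyse (e.g. \code{"GY"}).
#' @param dth_covariate include DTH as a fixed covariate? Default FALSE.
#' @param by_environment fit each environment separately (default TRUE,
#'   matching per-environment reporting) or one joint model with environment
#'   and block-within-environment random.
#' @return data.frame of class \code{"lsmeans_table"} with columns genotype,
#'   environment, trait, lsmean, se and attribute \code{dth_corrected}.
#' @export
compute_lsmeans <- function(plots, trait, dth_covariate = FALSE,
                            by_environment = TRUE) {
  if (!trait %in% names(plots)) stop("trait '", trait, "' not found")
  if (dth_covariate && !"DTH" %in% names(plots)) {
    stop("DTH column required for the covariate model")
  }
  dat <- plots[!is.na(plots[[trait]]), , drop = FALSE]
  dropped <- setdiff(unique(plots$genotype), unique(dat$genotype))
  if (length(dropped)) {
    warning("genotype(s) with no observation excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  one_fit <- function(d, joint) {
    d$genotype <- factor(d$genotype)
    d$y <- d[[trait]]
    fixed <- if (dth_covariate) "y ~ 0 + genotype + DTH" else "y ~ 0 + genotype"
    rand <- if (joint) {
      "(1 | environment) + (1 | environment:block)"
    } else if (length(unique(d$block)) > 1) {
      "(1 | block)"
    } else {
      NULL
    }
    if (is.null(rand)) {
      fit <- stats::lm(stats::as.formula(fixed), data = d)
      cf <- stats::coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))
    } else {
      fml <- stats::as.formula(paste(fixed, "+", rand))
      fit <- tryCatch(
        suppressMessages(
          lme4::lmer(fml, data = d, REML = TRUE,
                     control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                 check.nobs.vs.nRE = "ignore"))),
        error = function(e) stop("REML fit failed for trait '", trait,
                                 "': ", conditionMessage(e)))
      cf <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    }
    gi <- grep("^genotype", names(cf))
    ls <- cf[gi]
    if (dth_covariate) ls <- ls + cf[["DTH"]] * mean(d$DTH, na.rm = TRUE)
    data.frame(genotype = sub("^genotype", "", names(cf)[gi]),
               lsmean = unname(ls), se = unname(se[gi]),
               stringsAsFactors = FALSE)
  }
  if (by_environment) {
    res <- do.call(rbind, lapply(split(dat, dat$environment), function(d) {
      out <- one_fit(d, joint = FALSE)
      out$environment <- d$environment[1]
      out
    }))
  } else {
    if (length(unique(dat$environment)) < 2) {
      stop("joint model needs at least 2 environments")
    }
    res <- one_fit(dat, joint = TRUE)
    res <- do.call(rbind, lapply(unique(dat$environment), function(e) {
      r <- res; r$environment <- e; r
    }))
  }
  rownames(res) <- NULL
  res$trait <- trait
  res <- res[, c("genotype", "environment", "trait", "lsmean", "se")]
  attr(res, "dth_corrected") <- dth_covariate
  class(res) <- c("lsmeans_table", "data.frame")
  res
}

#' Broad-sense heritability per environment
#'
#' Fits the random-genotype, random-block model to one environment's plots by
#' REML and returns \code{H2 = var_G / (var_G + var_e)}. \pkg{lme4} variance
#' estimates are non-negative by construction, so no truncation is needed.
#' Replication (here, the repeated checks of the augmented design) must be
#' present for the residual variance to be identifiable.
#'
#' @param plots plot table.
#' @param trait trait column name.
#' @param environment environment label to analyse.
#' @return list of class \code{"heritability"}: trait, environment, var_G,
#'   var_e, H2.
#' @export
heritability <- function(plots, trait, environment) {
  d <- plots[plots$environment == environment & !is.na(plots[[trait]]), ,
             drop = FALSE]
  if (nrow(d) == 0) stop("no data for environment ", environment)
  if (!any(duplicated(d$genotype))) {
    stop("no genotype replicated in ", environment,
         ": residual variance is not identifiable")
  }
  d$y <- d[[trait]]
  d$genotype <- factor(d$genotype)
  rand <- if (length(unique(d$block)) > 1) {
    "y ~ (1 | genotype) + (1 | block)"
  } else {
    "y ~ (1 | genotype)"
  }
  fit <- suppressMessages(
    lme4::lmer(stats::as.formula(rand), data = d, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_g <- vc$vcov[vc$grp == "genotype"]
  var_e <- vc$vcov[vc$grp == "Residual"]
  structure(list(trait = trait, environment = environment,
                 var_G = var_g, var_e = var_e,
                 H2 = var_g / (var_g + var_e)),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("H2(%s, %s) = %.3f  [var_G = %.3g, var_e = %.3g]\n",
              x$trait, x$environment, x$H2, x$var_G, x$var_e))
  invisible(x)
}

#' Pearson correlations between grain yield and other traits
#'
#' Correlates each trait's LSmeans with the grain-yield LSmeans within one
#' environment, with a t-based two-sided P-value and the usual significance
#' stars (* 0.05, ** 0.01, *** 0.001). Traits with zero variance are
#' reported as missing.
#'
#' @param lsm a \code{"lsmeans_table"} covering GY and other traits (stack
#'   tables from several [compute_lsmeans()] calls with \code{rbind}).
#' @param environment environment label.
#' @param yield_trait name of the yield trait (default \code{"GY"}).
#' @return data.frame with trait, n, r, p_value, stars.
#' @export
trait_yield_correlations <- function(lsm, environment, yield_trait = "GY") {
  d <- lsm[lsm$environment == environment, , drop = FALSE]
  wide <- stats::reshape(d[, c("genotype", "trait", "lsmean")],
                         idvar = "genotype", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^lsmean\\.", "", names(wide))
  if (!yield_trait %in% names(wide)) {
    stop("no '", yield_trait, "' LSmeans for environment ", environment)
  }
  traits <- setdiff(names(wide), c("genotype", yield_trait))
  out <- lapply(traits, function(tr) {
    ok <- stats::complete.cases(wide[[tr]], wide[[yield_trait]])
    n <- sum(ok)
    if (n < 3 || stats::sd(wide[[tr]][ok]) == 0 ||
        stats::sd(wide[[yield_trait]][ok]) == 0) {
      return(data.frame(trait = tr, n = n, r = NA_real_, p_value = NA_real_,
                        stars = "", stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(wide[[tr]][ok], wide[[yield_trait]][ok])
    stars <- if (ct$p.value < 0.001) "***" else if (ct$p.value < 0.01) "**"
             else if (ct$p.value < 0.05) "*" else ""
    data.frame(trait = tr, n = n, r = unname(ct$estimate),
               p_value = ct$p.value, stars = stars, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
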