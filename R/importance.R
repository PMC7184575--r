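#' Elastic-net coefficients by coordinate descent
#'
#' Minimises \code{(1/2n) ||y - X b||^2 + lambda (alpha ||b||_1 +
#' (1 - alpha)/2 ||b||_2^2)} by cyclic coordinate descent with covariance
#' updates. Inputs are used as given: standardize \code{X} and center
#' \code{y} beforehand (as [tune_and_rank()] does) for the penalty to act on
#' a common scale. \code{alpha = 1} is the LASSO, \code{alpha = 0} ridge.
#'
#' @param X predictor matrix (n x p), no intercept column.
#' @param y centered response.
#' @param alpha elastic-net mixing parameter in [0, 1].
#' @param lambda penalty level (>= 0).
#' @param tol convergence threshold on the largest coefficient change
#'   (default 1e-7).
#' @param max_iter cap on full coordinate sweeps (default 2000). On
#'   near-collinear designs the smallest penalties can keep drifting along a
#'   flat valley with coefficient changes just above \code{tol}; the cap
#'   stops them once the objective is numerically converged.
#' @param beta_init optional warm-start coefficients.
#' @return numeric coefficient vector (named by column).
#' @export
fit_elastic_net <- function(X, y, alpha, lambda, tol = 1e-7,
                            max_iter = 2000L, beta_init = NULL) {
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite inputs")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be non-negative")
  n <- nrow(X); p <- ncol(X)
  Cxx <- crossprod(X) / n
  cxy <- drop(crossprod(X, y)) / n
  beta <- if (is.null(beta_init)) numeric(p) else beta_init
  thr <- lambda * alpha
  for (iter in seq_len(max_iter)) {
    max_change <- 0
    for (j in seq_len(p)) {
      rho <- cxy[j] - sum(Cxx[j, ] * beta) + Cxx[j, j] * beta[j]
      bj <- sign(rho) * max(abs(rho) - thr, 0) /
        (Cxx[j, j] + lambda * (1 - alpha))
      change <- abs(bj - beta[j])
      if (change > max_change) max_change <- change
      beta[j] <- bj
    }
    if (max_change < tol) break
  }
  names(beta) <- colnames(X)
  beta
}

#' Penalty path for the elastic net
#'
#' Log-spaced grid of \code{n_lambda} values from \code{lambda_max} (the
#' smallest penalty zeroing every coefficient, \code{max |X'y| / (n alpha)})
#' down \code{decades} orders of magnitude. For \code{alpha = 0} the ridge
#' path reuses the \code{alpha = 0.001} entry point, the usual convention.
#'
#' @param X,y standardized predictors and centered response.
#' @param alpha elastic-net mixing parameter.
#' @param n_lambda grid size (default 50).
#' @param decades span of the grid in log10 units (default 4).
#' @return decreasing numeric vector of penalties.
#' @export
lambda_path <- function(X, y, alpha, n_lambda = 50, decades = 4) {
  a <- max(alpha, 0.001)
  lmax <- max(abs(crossprod(X, y))) / (nrow(X) * a)
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = n_lambda))
}

#' Configuration for trait-importance ranking
#'
#' @param alpha_grid elastic-net mixing values to scan (default
#'   0, 0.25, 0.5, 0.75, 1).
#' @param n_lambda penalties per alpha (log-spaced path, default 50).
#' @param cv_folds folds per repeat (default 10).
#' @param cv_repeats repeats of the cross-validation (default 20).
#' @param seed integer seed for fold assignment.
#' @param dth_corrected regress days-to-heading out of the response first?
#' @return list of class \code{"importance_config"}.
#' @export
importance_config <- function(alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                              n_lambda = 50, cv_folds = 10, cv_repeats = 20,
                              seed = 1L, dth_corrected = FALSE) {
  if (length(alpha_grid) == 0 || n_lambda < 1) stop("empty tuning grid")
  if (cv_folds < 2) stop("cv_folds must be at least 2")
  structure(list(alpha_grid = alpha_grid, n_lambda = as.integer(n_lambda),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats), seed = as.integer(seed),
                 dth_corrected = dth_corrected),
            class = "importance_config")
}

#' Rank trait importance by tuned penalized regression
#'
#' Standardizes the traits and centers the yield response (optionally after
#' regressing days-to-heading out of it), scans the (alpha, lambda) grid by
#' repeated k-fold cross-validation, selects the pair with the smallest mean
#' squared error (ties: larger lambda, then larger alpha), refits on all
#' data, and reports each trait's importance as
#' \code{100 |beta| / max |beta|}.
#'
#' @param X traits matrix (lines x traits), raw scale.
#' @param y grain-yield LSmeans per line.
#' @param config an [importance_config()].
#' @param dth optional days-to-heading vector (required when
#'   \code{config$dth_corrected}).
#' @return list of class \code{"importance_result"}: chosen \code{alpha} and
#'   \code{lambda} (on the unit-variance response scale),
#'   \code{coefficients} per standardized trait in response units,
#'   \code{importance} (max 100), and the \code{cv_mse} surface.
#' @export
tune_and_rank <- function(X, y, config = importance_config(), dth = NULL) {
  stopifnot(inherits(config, "importance_config"))
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 traits")
  n <- nrow(X)
  if (n <= config$cv_folds) stop("need more lines than folds")
  if (config$dth_corrected) {
    if (is.null(dth)) stop("dth required when dth_corrected")
    y <- stats::resid(stats::lm(y ~ dth))
  }
  mu <- colMeans(X)
  sds <- apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
  if (any(sds < .Machine$double.eps)) {
    stop("zero-variance trait(s): ",
         paste(colnames(X)[sds < .Machine$double.eps], collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  yc <- y - mean(y)
  # unit-variance response: the penalty grid and the convergence tolerance
  # are meaningful on this scale regardless of the trait's units
  sd_y <- sqrt(mean(yc^2))
  if (sd_y < .Machine$double.eps) stop("response has zero variance")
  yc <- yc / sd_y

  paths <- lapply(config$alpha_grid,
                  function(a) lambda_path(Xs, yc, a, config$n_lambda))
  err <- lapply(seq_along(config$alpha_grid),
                function(i) matrix(0, config$cv_repeats * config$cv_folds,
                                   config$n_lambda))
  set.seed(config$seed)
  row_i <- 0L
  for (rep_i in seq_len(config$cv_repeats)) {
    fold_id <- sample(rep_len(seq_len(config$cv_folds), n))
    for (fold in seq_len(config$cv_folds)) {
      row_i <- row_i + 1L
      test <- fold_id == fold
      Xtr <- Xs[!test, , drop = FALSE]; ytr <- yc[!test]
      Xte <- Xs[test, , drop = FALSE];  yte <- yc[test]
      for (ai in seq_along(config$alpha_grid)) {
        beta <- numeric(ncol(Xs))
        for (li in seq_along(paths[[ai]])) {
          beta <- fit_elastic_net(Xtr, ytr, config$alpha_grid[ai],
                                  paths[[ai]][li], beta_init = beta)
          pred <- drop(Xte %*% beta)
          err[[ai]][row_i, li] <- mean((yte - pred)^2)
        }
      }
    }
  }
  surface <- do.call(rbind, lapply(seq_along(config$alpha_grid), function(ai) {
    data.frame(alpha = config$alpha_grid[ai], lambda = paths[[ai]],
               mse = colMeans(err[[ai]]))
  }))
  # smallest MSE; ties resolved toward stronger penalty, then more sparsity
  ord <- order(surface$mse, -surface$lambda, -surface$alpha)
  best <- surface[ord[1], ]
  beta <- fit_elastic_net(Xs, yc, best$alpha, best$lambda) * sd_y
  if (all(beta == 0)) {
    warning("all coefficients zero at the selected penalty")
    importance <- stats::setNames(rep(0, length(beta)), names(beta))
  } else {
    importance <- 100 * abs(beta) / max(abs(beta))
  }
  structure(list(alpha = best$alpha, lambda = best$lambda,
                 coefficients = beta, importance = importance,
                 cv_mse = surface, dth_corrected = config$dth_corrected),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("Elastic-net trait importance (alpha = %.2f, lambda = %.4g%s)\n",
              x$alpha, x$lambda,
              if (x$dth_corrected) ", DTH-corrected" else ""))
  imp <- sort(x$importance, decreasing = TRUE)
  print(round(imp, 1))
  invisible(x)
}
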