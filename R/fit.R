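#' Specification of the six multi-kernel prediction models
#'
#' The six model forms combine a genomic main-effect kernel (G), a
#' physiological-trait main-effect kernel (P) and their environment
#' interaction kernels (GE, PE), always with fixed environment effects:
#' \tabular{ll}{
#'   \code{G}    \tab y = mu + E + u_G + e \cr
#'   \code{G+GE} \tab y = mu + E + u_G + u_GE + e \cr
#'   \code{G+PE} \tab y = mu + E + u_G + u_PE + e \cr
#'   \code{P}    \tab y = mu + E + u_P + e \cr
#'   \code{P+PE} \tab y = mu + E + u_P + u_PE + e \cr
#'   \code{P+GE} \tab y = mu + E + u_P + u_GE + e
#' }
#'
#' @param name one of \code{"G"}, \code{"G+GE"}, \code{"G+PE"}, \code{"P"},
#'   \code{"P+PE"}, \code{"P+GE"}.
#' @return list of class \code{"model_spec"} with \code{name} and
#'   \code{kernels} (names of the required record-level kernels).
#' @export
model_spec <- function(name) {
  forms <- list(
    "G"    = "G_main",
    "G+GE" = c("G_main", "GE"),
    "G+PE" = c("G_main", "PE"),
    "P"    = "P_main",
    "P+PE" = c("P_main", "PE"),
    "P+GE" = c("P_main", "GE"))
  name <- match.arg(name, names(forms))
  structure(list(name = name, kernels = forms[[name]]), class = "model_spec")
}

#' Gibbs-chain configuration
#'
#' @param n_iter total iterations (default 12000).
#' @param burn_in discarded initial iterations (default 2000).
#' @param thin keep every \code{thin}-th post-burn-in draw (default 5).
#' @param seed integer seed; same seed and data give identical chains.
#' @param df_prior prior degrees of freedom of the scaled-inverse-chi-square
#'   priors on every variance component (default 5).
#' @param fix_variances optional named list of kernel variance components to
#'   hold fixed (no sampling), e.g. \code{list(G_main = 40)}.
#' @param fix_residual optional fixed residual variance.
#' @return list of class \code{"chain_config"}.
#' @export
chain_config <- function(n_iter = 12000, burn_in = 2000, thin = 5, seed = 1L,
                         df_prior = 5, fix_variances = NULL,
                         fix_residual = NULL) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (burn_in < 0 || thin < 1) stop("burn_in >= 0 and thin >= 1 required")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 df_prior = df_prior, fix_variances = fix_variances,
                 fix_residual = fix_residual),
            class = "chain_config")
}

#' Eigendecompose a record-level kernel for sampling
#'
#' One decomposition per kernel is reused across chain iterations (and can be
#' shared across cross-validation folds, since masking changes only the
#' response). Eigenvalues below \code{tol * max} are dropped, giving
#' reduced-rank sampling in the kernel's column space.
#'
#' @param K symmetric PSD matrix.
#' @param tol relative eigenvalue cut-off (default 1e-8).
#' @return list of class \code{"kernel_eigen"} with \code{vectors} (n x m),
#'   \code{values} (length m) and \code{n}.
#' @export
kernel_eigen <- function(K, tol = 1e-8) {
  e <- eigen(K, symmetric = TRUE)
  mx <- max(e$values)
  if (mx <= 0) stop("kernel has no positive eigenvalues")
  if (min(e$values) < -tol * mx) {
    stop("kernel is not positive semi-definite beyond tolerance")
  }
  keep <- e$values > tol * mx
  structure(list(vectors = e$vectors[, keep, drop = FALSE],
                 values = e$values[keep], n = nrow(K)),
            class = "kernel_eigen")
}

#' Fit a multi-kernel BLUP model by Gibbs sampling
#'
#' Bayesian fit of \code{y = X b + sum_k u_k + e}, where \code{X} holds the
#' intercept and fixed environment effects, each \code{u_k ~ N(0, s2_k K_k)}
#' for a record-level kernel \code{K_k}, and \code{e ~ N(0, s2_e I)}.
#' Kernel effects are sampled in the eigenbasis of their kernel (diagonal
#' full conditionals); variance components get scaled-inverse-chi-square
#' full conditionals with prior mode set so the phenotypic variance is split
#' equally over the components a priori. Records with missing \code{y} are
#' excluded from the likelihood by data augmentation (their response is
#' refreshed from the current model each sweep), so masked lines are
#' predicted through the kernels jointly across environments — the mechanism
#' behind whole-line cross-validation masking.
#'
#' @param y response vector, one entry per design record (LSmeans of grain
#'   yield), NA for records to predict.
#' @param design a [record_design()].
#' @param spec a [model_spec()].
#' @param kernels named list holding at least the record-level kernels the
#'   spec requires; entries may be plain matrices or pre-computed
#'   [kernel_eigen()] objects.
#' @param chain a [chain_config()].
#' @return object of class \code{"mkblup_fit"}: posterior means of fixed
#'   effects (\code{b}, with design matrix column names), per-kernel random
#'   effects \code{u} (records x kernels), variance components
#'   (\code{varcomp}: mean, sd, effective sample size), \code{gebv} (summed
#'   random effects per record), \code{fitted}, and the inputs.
#' @export
fit_mkblup <- function(y, design, spec, kernels, chain = chain_config()) {
  stopifnot(inherits(design, "record_design"), inherits(spec, "model_spec"),
            inherits(chain, "chain_config"))
  n <- nrow(design$records)
  if (length(y) != n) stop("y must have one entry per design record")
  missing_kernels <- setdiff(spec$kernels, names(kernels))
  if (length(missing_kernels)) {
    stop("model ", spec$name, " needs kernel(s): ",
         paste(missing_kernels, collapse = ", "))
  }
  eigs <- lapply(kernels[spec$kernels], function(K) {
    if (inherits(K, "kernel_eigen")) K else kernel_eigen(K)
  })
  for (e in eigs) if (e$n != n) stop("kernel dimension does not match design")
  obs <- !is.na(y)
  if (!any(obs)) stop("all responses are missing")
  for (env in design$env_levels) {
    if (!any(obs & design$records$environment == env)) {
      stop("no observed record in environment ", env)
    }
  }

  env <- factor(design$records$environment)
  X <- if (nlevels(env) > 1) {
    stats::model.matrix(~env)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  p <- ncol(X)
  XtX_inv <- solve(crossprod(X))
  chol_XtX_inv <- chol(XtX_inv)

  nk <- length(eigs)
  vy <- stats::var(y[obs])
  df0 <- chain$df_prior
  n_comp <- nk + 1
  # prior scale: mode df0*S0/(df0+2) equals an equal share of var(y)
  S0 <- vapply(eigs, function(e) {
    mean_diag <- sum(e$values) / e$n
    (vy / n_comp) * (df0 + 2) / df0 / mean_diag
  }, numeric(1))
  S0_e <- (vy / n_comp) * (df0 + 2) / df0

  set.seed(chain$seed)
  y_cur <- y
  y_cur[!obs] <- mean(y[obs])
  b <- rep(0, p)
  delta <- lapply(eigs, function(e) rep(0, length(e$values)))
  u <- lapply(eigs, function(e) rep(0, n))
  s2 <- rep(vy / n_comp, nk)
  names(s2) <- names(eigs)
  for (k in names(s2)) {
    if (!is.null(chain$fix_variances[[k]])) s2[k] <- chain$fix_variances[[k]]
  }
  s2_e <- if (is.null(chain$fix_residual)) vy / n_comp else chain$fix_residual

  n_keep <- length(seq(chain$burn_in + 1, chain$n_iter, by = chain$thin))
  sum_b <- rep(0, p)
  sum_u <- matrix(0, n, nk, dimnames = list(NULL, names(eigs)))
  vc_draws <- matrix(0, n_keep, nk + 1,
                     dimnames = list(NULL, c(names(eigs), "residual")))
  kept <- 0L

  for (it in seq_len(chain$n_iter)) {
    # fixed effects | rest
    r <- if (nk > 0) y_cur - Reduce(`+`, u) else y_cur
    b_hat <- XtX_inv %*% crossprod(X, r)
    b <- drop(b_hat + sqrt(s2_e) * drop(crossprod(chol_XtX_inv, stats::rnorm(p))))
    xb <- drop(X %*% b)

    # kernel effects | rest, in the eigenbasis
    for (k in seq_len(nk)) {
      others <- if (nk > 1) Reduce(`+`, u[-k]) else 0
      rk <- y_cur - xb - others
      e <- eigs[[k]]
      rt <- drop(crossprod(e$vectors, rk))
      prec <- 1 / s2_e + 1 / (s2[k] * e$values)
      mu_d <- (rt / s2_e) / prec
      delta[[k]] <- mu_d + stats::rnorm(length(mu_d)) / sqrt(prec)
      u[[k]] <- drop(e$vectors %*% delta[[k]])
      if (is.null(chain$fix_variances[[names(eigs)[k]]])) {
        ss <- sum(delta[[k]]^2 / e$values)
        df <- df0 + length(e$values)
        s2[k] <- (ss + df0 * S0[k]) / stats::rchisq(1, df)
      }
      if (!is.finite(s2[k]) || s2[k] <= 0) {
        stop("divergent chain at iteration ", it, " (component ",
             names(eigs)[k], ")")
      }
    }

    fitted_all <- xb + if (nk > 0) Reduce(`+`, u) else 0
    if (is.null(chain$fix_residual)) {
      e_res <- (y_cur - fitted_all)[obs]
      df <- df0 + sum(obs)
      s2_e <- (sum(e_res^2) + df0 * S0_e) / stats::rchisq(1, df)
    }
    if (!is.finite(s2_e) || s2_e <= 0) {
      stop("divergent chain at iteration ", it, " (residual)")
    }

    # data augmentation for masked records
    if (any(!obs)) {
      y_cur[!obs] <- fitted_all[!obs] +
        stats::rnorm(sum(!obs), sd = sqrt(s2_e))
    }

    if (it > chain$burn_in && (it - chain$burn_in) %% chain$thin == 0) {
      kept <- kept + 1L
      sum_b <- sum_b + b
      for (k in seq_len(nk)) sum_u[, k] <- sum_u[, k] + u[[k]]
      vc_draws[kept, ] <- c(s2, s2_e)
    }
  }

  b_mean <- sum_b / kept
  names(b_mean) <- colnames(X)
  u_mean <- sum_u / kept
  gebv <- rowSums(u_mean)
  varcomp <- data.frame(
    component = colnames(vc_draws),
    mean = colMeans(vc_draws),
    sd = apply(vc_draws, 2, stats::sd),
    ess = apply(vc_draws, 2, ess_batch_means),
    row.names = NULL)
  structure(list(
    model = spec$name, b = b_mean, u = u_mean, gebv = gebv,
    fitted = drop(X %*% b_mean) + gebv, varcomp = varcomp,
    y = y, design = design, spec = spec, chain = chain,
    n_draws = kept), class = "mkblup_fit")
}

# effective sample size by the batch-means method: var(x) / var(mean)
ess_batch_means <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  b <- max(2L, floor(sqrt(n)))
  nb <- floor(n / b)
  means <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  var_mean <- stats::var(means) / nb
  if (var_mean <= 0) return(NA_real_)
  min(n, stats::var(x) / var_mean)
}

#' @export
print.mkblup_fit <- function(x, ...) {
  cat("Multi-kernel BLUP fit: model", x$model, "on",
      nrow(x$design$records), "records (", x$n_draws, "posterior draws )\n")
  cat("Variance components (posterior mean):\n")
  print(x$varcomp, digits = 4)
  invisible(x)
}

#' Genomic estimated breeding values from a fit
#'
#' The GEBV of a record is the posterior mean of its summed random kernel
#' effects; the fixed environment effect is excluded by default so values
#' are comparable across environments.
#'
#' @param object an \code{"mkblup_fit"}.
#' @param records optional data.frame (genotype, environment) restricting the
#'   output; default all design records.
#' @param include_fixed add the fixed part (intercept + environment effect)?
#' @param ... unused.
#' @return data.frame genotype, environment, gebv.
#' @export
predict.mkblup_fit <- function(object, records = NULL, include_fixed = FALSE,
                               ...) {
  des <- object$design$records
  out <- data.frame(genotype = des$genotype, environment = des$environment,
                    gebv = object$gebv, stringsAsFactors = FALSE)
  if (include_fixed) out$gebv <- object$fitted
  if (!is.null(records)) {
    key_all <- paste(des$genotype, des$environment, sep = "\r")
    key_want <- paste(records$genotype, records$environment, sep = "\r")
    idx <- match(key_want, key_all)
    if (anyNA(idx)) {
      stop("record(s) absent from the fitted design: ",
           paste(utils::head(key_want[is.na(idx)], 5), collapse = "; "))
    }
    out <- out[idx, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
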