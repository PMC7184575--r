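#' Stratify lines into genetic groups (PCA + k-means)
#'
#' The clustering stage of a discriminant analysis of principal components:
#' markers are centered/standardized, lines are projected on the leading
#' principal components (by default the smallest number explaining at least
#' 80% of the variance), and k-means partitions the scores into
#' \code{k_groups}. The discriminant step itself is omitted — only the group
#' memberships matter for building leakage-free cross-validation folds.
#'
#' @param m imputed dosage matrix (lines x markers).
#' @param k_groups number of genetic groups (default 10).
#' @param n_pcs number of principal components to retain; default chooses
#'   the smallest number explaining >= \code{var_explained}.
#' @param var_explained target cumulative variance fraction (default 0.8).
#' @param seed integer seed (k-means initialisation).
#' @return named factor of group labels, one per line.
#' @export
stratify_lines <- function(m, k_groups = 10, n_pcs = NULL,
                           var_explained = 0.8, seed = 1L) {
  if (k_groups > nrow(m)) stop("k_groups cannot exceed the number of lines")
  if (anyNA(m)) stop("markers must be imputed before stratification")
  sds <- apply(m, 2, stats::sd)
  m <- m[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  if (is.null(n_pcs)) {
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_pcs <- which(cum >= var_explained)[1]
  }
  n_pcs <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k_groups, nstart = 25, iter.max = 100)
  structure(factor(km$cluster), names = rownames(m))
}

#' Assign genetic groups to cross-validation folds
#'
#' Whole groups are assigned to folds so lines of the same group never appear
#' in both training and validation sets. Assignment is greedy after a random
#' shuffle: groups in decreasing size order each go to the currently smallest
#' fold, which keeps fold sizes within one group's size of n/f.
#'
#' @param groups named factor of group labels per line (from
#'   [stratify_lines()]).
#' @param f number of folds (default 5).
#' @param seed integer seed (order of equal-sized groups).
#' @return list of class \code{"stratified_folds"}: \code{groups},
#'   \code{folds} (named integer per line), \code{f}, \code{seed}.
#' @export
assign_folds <- function(groups, f = 5, seed = 1L) {
  if (nlevels(droplevels(groups)) < f) {
    stop("fewer groups (", nlevels(droplevels(groups)),
         ") than folds (", f, "); reduce f")
  }
  sizes <- table(droplevels(groups))
  set.seed(seed)
  ord <- sample(names(sizes))                 # random tie-breaking
  ord <- ord[order(-sizes[ord])]              # largest first (stable)
  fold_of_group <- stats::setNames(integer(length(ord)), ord)
  fold_sizes <- numeric(f)
  for (gname in ord) {
    tgt <- which.min(fold_sizes)
    fold_of_group[gname] <- tgt
    fold_sizes[tgt] <- fold_sizes[tgt] + sizes[[gname]]
  }
  folds <- fold_of_group[as.character(groups)]
  names(folds) <- names(groups)
  structure(list(groups = groups, folds = folds, f = as.integer(f),
                 seed = as.integer(seed)),
            class = "stratified_folds")
}

#' Group-respecting five-fold cross-validation of the prediction models
#'
#' For each model and each fold, every record of the fold's validation lines
#' is masked across all environments, the model is refit, and the masked
#' records' GEBVs are correlated (Pearson) with their observed values within
#' each environment. Reported per model and environment:
#' \code{r_p} (mean predictive correlation over folds), the
#' heritability-adjusted accuracy \code{r_GY = r_p / sqrt(H2)}, and its
#' standard error \code{SE = sd(r) / sqrt(f * H2)}. Response to selection is
#' evaluated on each fold's validation lines (see
#' [response_to_selection()]) and aggregated as mean with
#' \code{SE = sd(RTS) / sqrt(f)}.
#'
#' @param y response per design record (observed LSmeans of grain yield).
#' @param design a [record_design()].
#' @param specs list of [model_spec()] objects (or model-name strings).
#' @param kernels named list of record-level kernels (see
#'   [build_model_kernels()]).
#' @param folds a [stratified_folds()] covering the design's lines.
#' @param h2 named vector of grain-yield heritability per environment.
#' @param chain a [chain_config()]; fold fits use \code{seed + fold}.
#' @param intensity selected fraction for response to selection.
#' @return list of class \code{"cv_result"} with \code{accuracy} and
#'   \code{rts} data.frames, per-fold correlations, and \code{gebv} (pooled
#'   out-of-fold GEBV per record).
#' @export
cross_validate <- function(y, design, specs, kernels, folds, h2,
                           chain = chain_config(), intensity = 0.10) {
  stopifnot(inherits(folds, "stratified_folds"))
  recs <- design$records
  if (!all(recs$genotype %in% names(folds$folds))) {
    stop("folds do not cover every genotype in the design")
  }
  if (!all(design$env_levels %in% names(h2))) {
    stop("h2 must be named by environment and cover all environments")
  }
  specs <- lapply(specs, function(s) if (inherits(s, "model_spec")) s
                  else model_spec(s))
  needed <- unique(unlist(lapply(specs, `[[`, "kernels")))
  eigs <- lapply(kernels[needed], function(K) {
    if (inherits(K, "kernel_eigen")) K else kernel_eigen(K)
  })
  acc_rows <- list(); rts_rows <- list(); fold_rows <- list()
  gebv_all <- list()
  for (spec in specs) {
    pooled <- rep(NA_real_, nrow(recs))
    for (fold in seq_len(folds$f)) {
      val_lines <- names(folds$folds)[folds$folds == fold]
      mask <- recs$genotype %in% val_lines
      y_train <- y
      y_train[mask] <- NA
      ch <- chain
      ch$seed <- chain$seed + fold
      fit <- fit_mkblup(y_train, design, spec, eigs, ch)
      pooled[mask] <- fit$gebv[mask]
      for (env in design$env_levels) {
        sel <- mask & recs$environment == env & !is.na(y)
        if (sum(sel) < 3) next
        r <- stats::cor(fit$gebv[sel], y[sel])
        rts <- response_to_selection(
          stats::setNames(fit$gebv[sel], recs$genotype[sel]),
          stats::setNames(y[sel], recs$genotype[sel]),
          h2 = h2[[env]], intensity = intensity)
        fold_rows[[length(fold_rows) + 1]] <- data.frame(
          model = spec$name, environment = env, fold = fold, r = r,
          S = rts$S, R = rts$R, stringsAsFactors = FALSE)
      }
    }
    gebv_all[[spec$name]] <- pooled
  }
  per_fold <- do.call(rbind, fold_rows)
  for (key in unique(paste(per_fold$model, per_fold$environment, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    d <- per_fold[per_fold$model == parts[1] &
                    per_fold$environment == parts[2], ]
    H2 <- h2[[parts[2]]]
    if (H2 <= 0) {
      warning("H2 = 0 in ", parts[2], ": adjusted accuracy undefined")
      r_gy <- NA_real_; se <- NA_real_
    } else {
      r_gy <- mean(d$r) / sqrt(H2)
      se <- stats::sd(d$r) / sqrt(nrow(d) * H2)
    }
    acc_rows[[key]] <- data.frame(
      model = parts[1], environment = parts[2], f = nrow(d),
      r_p = mean(d$r), H2 = H2, r_GY = r_gy, SE = se,
      stringsAsFactors = FALSE)
    rts_rows[[key]] <- data.frame(
      model = parts[1], environment = parts[2], f = nrow(d),
      S = mean(d$S), R = mean(d$R), SE = stats::sd(d$R) / sqrt(nrow(d)),
      stringsAsFactors = FALSE)
  }
  accuracy <- do.call(rbind, acc_rows); rownames(accuracy) <- NULL
  rts <- do.call(rbind, rts_rows); rownames(rts) <- NULL
  structure(list(
    accuracy = accuracy,
    rts = rts,
    per_fold = per_fold,
    gebv = data.frame(recs, gebv_all, check.names = FALSE)),
    class = "cv_result")
}

#' Response to selection from a GEBV ranking
#'
#' Lines are ranked by GEBV (descending, ties broken by line id for
#' reproducibility) and the top \code{ceiling(intensity * n)} form the
#' selected set. The selection differential is
#' \code{S = mean(y[selected]) - mean(y)} and the response to selection is
#' the breeder's-equation value \code{R = H2 * S}.
#'
#' @param gebv named vector of GEBVs per line.
#' @param y named vector of observed yields for the same lines (kg/ha).
#' @param h2 broad-sense heritability of yield in the environment.
#' @param intensity selected fraction in (0, 1), default 0.10.
#' @return list of class \code{"selection_result"}: selected line ids,
#'   \code{mu_S}, \code{mu_P}, \code{S}, \code{R}, \code{H2},
#'   \code{intensity}.
#' @export
response_to_selection <- function(gebv, y, h2, intensity = 0.10) {
  if (intensity <= 0 || intensity >= 1) stop("intensity must lie in (0, 1)")
  common <- intersect(names(gebv), names(y))
  if (length(common) != length(gebv) || length(common) != length(y)) {
    stop("gebv and y must cover the same lines")
  }
  gebv <- gebv[common]; y <- y[common]
  n_sel <- ceiling(intensity * length(gebv))
  ord <- order(-gebv, names(gebv))
  sel <- names(gebv)[ord[seq_len(n_sel)]]
  mu_s <- mean(y[sel]); mu_p <- mean(y)
  structure(list(selected = sel, mu_S = mu_s, mu_P = mu_p,
                 S = mu_s - mu_p, R = h2 * (mu_s - mu_p),
                 H2 = h2, intensity = intensity),
            class = "selection_result")
}

#' Heritability-adjusted prediction accuracy
#'
#' \code{r_GY = r_p / sqrt(H2)} with standard error
#' \code{SE = sd_r / sqrt(f * H2)}.
#'
#' @param r_p mean predictive correlation across folds.
#' @param h2 heritability of the trait in the environment.
#' @param sd_r standard deviation of the per-fold correlations (optional).
#' @param f number of folds.
#' @return list with \code{r_GY} and (when \code{sd_r} is given) \code{SE}.
#' @export
adjusted_accuracy <- function(r_p, h2, sd_r = NULL, f = 5) {
  if (h2 <= 0) stop("adjusted accuracy undefined for H2 <= 0")
  out <- list(r_GY = r_p / sqrt(h2))
  if (!is.null(sd_r)) out$SE <- sd_r / sqrt(f * h2)
  out
}
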