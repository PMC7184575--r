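#' Physiological relationship matrix P = SS'/m
#'
#' Assembles the lines x traits matrix S of trait LSmeans (averaged over
#' environments when several are present), centers and standardizes each
#' trait across lines with the population standard deviation, and returns
#' \code{P = S S' / m} with \code{m} the number of traits used. Traits with
#' no usable values or zero variance are dropped with a warning (mirroring
#' trait-by-environment gaps in real trials); line-level missing values are
#' imputed by the trait mean before standardization and the imputed cells are
#' reported in the \code{"imputed"} attribute.
#'
#' @param lsm a \code{"lsmeans_table"} (stacked over traits).
#' @param traits trait names to use; default all traits present except GY and
#'   DTH.
#' @return symmetric PSD lines x lines matrix with attributes
#'   \code{traits_used}, \code{m} and \code{imputed}.
#' @export
compute_physio_kernel <- function(lsm, traits = NULL) {
  if (is.null(traits)) traits <- setdiff(unique(lsm$trait), c("GY", "DTH"))
  traits <- intersect(traits, unique(lsm$trait))
  if (length(traits) == 0) stop("no usable traits for the P kernel")
  agg <- stats::aggregate(lsmean ~ genotype + trait,
                          data = lsm[lsm$trait %in% traits, ],
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  wide <- stats::reshape(agg, idvar = "genotype", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^lsmean\\.", "", names(wide))
  lines <- wide$genotype
  S <- as.matrix(wide[, setdiff(names(wide), "genotype"), drop = FALSE])
  rownames(S) <- lines
  S[is.nan(S)] <- NA
  imputed <- which(is.na(S), arr.ind = TRUE)
  keep <- logical(ncol(S))
  for (j in seq_len(ncol(S))) {
    v <- S[, j]
    if (all(is.na(v))) next
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    mu <- mean(v)
    sd_pop <- sqrt(mean((v - mu)^2))
    if (sd_pop < .Machine$double.eps) next
    S[, j] <- (v - mu) / sd_pop
    keep[j] <- TRUE
  }
  if (!all(keep)) {
    warning("trait(s) dropped (all-missing or zero variance): ",
            paste(colnames(S)[!keep], collapse = ", "))
  }
  S <- S[, keep, drop = FALSE]
  if (ncol(S) == 0) stop("no usable traits for the P kernel")
  P <- tcrossprod(S) / ncol(S)
  P <- (P + t(P)) / 2
  attr(P, "traits_used") <- colnames(S)
  attr(P, "m") <- ncol(S)
  if (nrow(imputed)) attr(P, "imputed") <- imputed
  P
}

#' Record design for multi-environment model fitting
#'
#' Defines the ordered (genotype, environment) records indexing the response
#' vector and the incidence of lines and environments. Records are sorted
#' environment-major so interaction kernels are block-diagonal.
#'
#' @param genotypes,environments parallel vectors, one entry per record; or
#'   leave \code{environments = NULL} and pass a \code{"lsmeans_table"} as
#'   \code{genotypes} to take its (genotype, environment) pairs.
#' @return list of class \code{"record_design"} with \code{records} (a
#'   data.frame), \code{line_levels}, \code{env_levels}.
#' @export
record_design <- function(genotypes, environments = NULL) {
  if (is.null(environments)) {
    stopifnot(inherits(genotypes, "lsmeans_table"))
    df <- unique(genotypes[, c("genotype", "environment")])
    genotypes <- df$genotype
    environments <- df$environment
  }
  stopifnot(length(genotypes) == length(environments))
  rec <- data.frame(genotype = as.character(genotypes),
                    environment = as.character(environments),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(rec)) stop("duplicate (genotype, environment) records")
  rec <- rec[order(rec$environment, rec$genotype), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec,
                 line_levels = sort(unique(rec$genotype)),
                 env_levels = sort(unique(rec$environment))),
            class = "record_design")
}

#' Expand a line-level kernel to the record level
#'
#' Maps a lines x lines kernel K to records via the line incidence:
#' \code{Z_g K Z_g'}; entry (r, s) equals K(line_r, line_s) regardless of
#' environment.
#'
#' @param K symmetric kernel with line names on rows/columns.
#' @param design a [record_design()].
#' @return records x records matrix.
#' @export
expand_main_kernel <- function(K, design) {
  stopifnot(inherits(design, "record_design"))
  idx <- match(design$records$genotype, rownames(K))
  if (anyNA(idx)) {
    stop("genotype(s) absent from the kernel: ",
         paste(utils::head(design$records$genotype[is.na(idx)], 5),
               collapse = ", "))
  }
  out <- K[idx, idx, drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Environment-interaction (reaction-norm) kernel
#'
#' The covariance structure of genotype-by-environment (or physiology-by-
#' environment) deviations: the Hadamard product of the record-expanded
#' line kernel and the same-environment indicator,
#' \code{(Z_g K Z_g') o (Z_E Z_E')}. Entries for record pairs in different
#' environments are exactly zero, so under environment-sorted records the
#' kernel is block-diagonal.
#'
#' @inheritParams expand_main_kernel
#' @return records x records matrix.
#' @export
interaction_kernel <- function(K, design) {
  main <- expand_main_kernel(K, design)
  env <- design$records$environment
  same_env <- outer(env, env, "==")
  main * same_env
}

#' Check positive semi-definiteness of a kernel
#'
#' @param K symmetric matrix.
#' @param tol relative eigenvalue tolerance (default 1e-8).
#' @return TRUE invisibly; error if the minimum eigenvalue is below
#'   \code{-tol * max eigenvalue}.
#' @export
check_psd <- function(K, tol = 1e-8) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev))) {
    stop("kernel is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  invisible(TRUE)
}

#' Build all record-level kernels for the six prediction models
#'
#' @param G line-level genomic kernel (from [compute_grm()]), or NULL.
#' @param P line-level physiological kernel (from
#'   [compute_physio_kernel()]), or NULL.
#' @param design a [record_design()].
#' @return named list with the available entries among \code{G_main},
#'   \code{P_main}, \code{GE}, \code{PE}.
#' @export
build_model_kernels <- function(G = NULL, P = NULL, design) {
  out <- list()
  if (!is.null(G)) {
    out$G_main <- expand_main_kernel(G, design)
    out$GE <- interaction_kernel(G, design)
  }
  if (!is.null(P)) {
    out$P_main <- expand_main_kernel(P, design)
    out$PE <- interaction_kernel(P, design)
  }
  if (length(out) == 0) stop("supply at least one of G or P")
  out
}

#' Write / read a kernel as CSV with ids
#' @param K matrix with (or without) dimnames.
#' @param path file path.
#' @param ids optional row/col ids to attach.
#' @export
write_kernel_csv <- function(K, path, ids = rownames(K)) {
  df <- data.frame(id = ids, K, check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_csv
#' @export
read_kernel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  K
}
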