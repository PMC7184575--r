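#' Read alternate-allele dosages from a biallelic VCF
#'
#' Extracts the GT field of an uncompressed (or bgzipped) VCF into a lines x
#' markers dosage matrix (alternate-allele count). Phased and unphased calls
#' are both accepted; any multiallelic record is rejected with an error.
#' Marker ids keep the VCF ID when present, else \code{CHROM_POS} (1-based).
#'
#' @param path VCF file.
#' @return numeric matrix, lines in rows, \code{NA} for missing calls.
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) {
    stop("multiallelic records are not supported; split or drop them first")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  no_id <- is.na(ids) | ids == "." | ids == ""
  if (any(no_id)) {
    ids[no_id] <- paste(vcfR::getCHROM(v), vcfR::getPOS(v), sep = "_")[no_id]
  }
  gt[gt == "."] <- NA
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), ids))
  clean <- gsub("\\|", "/", gt)
  a1 <- substr(clean, 1, 1)
  a2 <- substr(clean, 3, 3)
  val <- (a1 == "1") + (a2 == "1")
  val[a1 == "." | a2 == "." | is.na(clean)] <- NA
  dos[] <- t(val)
  if (anyDuplicated(colnames(dos))) stop("duplicate marker ids in VCF")
  dos
}

marker_maf <- function(m) {
  p <- colMeans(m, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter markers on missingness and minor allele frequency
#'
#' Drops markers whose missing-call fraction exceeds \code{max_missing} or
#' whose minor allele frequency (computed on non-missing calls) falls below
#' \code{min_maf}. Boundary values are retained: only \emph{more than}
#' \code{max_missing} missing or MAF strictly \emph{less than} \code{min_maf}
#' removes a marker. Marker order is preserved.
#'
#' @param m lines x markers dosage matrix (0/1/2, NA missing).
#' @param max_missing maximum tolerated missing fraction (default 0.80).
#' @param min_maf minimum tolerated MAF (default 0.05).
#' @return the filtered matrix, with a \code{"qc"} attribute listing counts
#'   removed per rule.
#' @export
filter_markers <- function(m, max_missing = 0.80, min_maf = 0.05) {
  if (is.null(dim(m)) || ncol(m) == 0) stop("empty marker matrix")
  miss <- colMeans(is.na(m))
  maf <- marker_maf(m)
  maf[is.nan(maf)] <- 0          # fully missing column: treated as MAF 0
  over_missing <- miss > max_missing
  low_maf <- !over_missing & maf < min_maf
  keep <- !(over_missing | low_maf)
  if (!any(keep)) stop("all markers removed by QC filters")
  out <- m[, keep, drop = FALSE]
  attr(out, "qc") <- list(
    n_input = ncol(m),
    n_removed_missing = sum(over_missing),
    n_removed_maf = sum(low_maf),
    n_retained = sum(keep),
    max_missing = max_missing, min_maf = min_maf)
  out
}

#' Impute missing dosages
#'
#' A deliberately simple stand-in for LD-based imputation: replaces each
#' missing call with the column (marker) mean, or with the marker's major
#' allele dosage.
#'
#' @param m dosage matrix after [filter_markers()].
#' @param method \code{"column_mean"} (fractional dosages) or
#'   \code{"major_allele"}.
#' @return complete dosage matrix.
#' @export
impute_markers <- function(m, method = c("column_mean", "major_allele")) {
  method <- match.arg(method)
  if (!anyNA(m)) return(m)
  full_missing <- colSums(!is.na(m)) == 0
  if (any(full_missing)) {
    stop("column(s) with all calls missing: ",
         paste(colnames(m)[full_missing], collapse = ", "))
  }
  fill <- if (method == "column_mean") {
    colMeans(m, na.rm = TRUE)
  } else {
    p <- colMeans(m, na.rm = TRUE) / 2
    ifelse(p > 0.5, 2, 0)
  }
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- fill[idx[, 2]]
  m
}

#' Allelic-independence filter by Fisher's exact test
#'
#' For each marker, tabulates presence/absence of the reference and alternate
#' alleles across lines (a line with no call counts as lacking both — in
#' genotyping-by-sequencing that is a locus with no reads) and tests the 2x2
#' table with Fisher's exact test. A truly biallelic locus in an inbred panel
#' shows strongly dependent (complementary) allele presence, so markers are
#' \emph{retained} when independence is rejected at \code{alpha}. Markers
#' with an allele present in no line are removed with a distinct reason.
#' Intended to run before imputation, while heterozygote and missing-call
#' information is intact.
#'
#' @param m dosage matrix (0/1/2 with NA missing).
#' @param alpha significance level for rejecting independence (default 0.001).
#' @return filtered matrix with a \code{"fisher"} attribute holding counts
#'   retained / removed as independent / removed as degenerate.
#' @export
fisher_allelic_filter <- function(m, alpha = 0.001) {
  n <- nrow(m)
  keep <- logical(ncol(m))
  degenerate <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    d <- m[, j]
    n_het <- sum(d == 1, na.rm = TRUE)
    n_ref <- sum(d == 0, na.rm = TRUE)
    n_alt <- sum(d == 2, na.rm = TRUE)
    n_none <- sum(is.na(d))
    # rows: ref allele present / absent; cols: alt allele present / absent
    tab <- matrix(c(n_het, n_alt, n_ref, n_none), 2, 2)
    if (n_het + n_ref == 0 || n_het + n_alt == 0) {
      degenerate[j] <- TRUE
      next
    }
    keep[j] <- stats::fisher.test(tab)$p.value < alpha
  }
  if (!any(keep)) stop("all markers removed by the allelic-independence filter")
  out <- m[, keep, drop = FALSE]
  attr(out, "fisher") <- list(
    n_input = ncol(m), n_retained = sum(keep),
    n_removed_independent = sum(!keep & !degenerate),
    n_removed_degenerate = sum(degenerate), alpha = alpha)
  out
}

#' Genomic relationship matrix G = XX'/n
#'
#' Centers each marker column by its mean and scales by its standard
#' deviation, then forms \code{G = X X' / n} with \code{n} the number of
#' markers. With the default population (divide-by-N) standard deviation the
#' mean of \code{diag(G)} is exactly 1.
#'
#' @param m complete (imputed) dosage matrix; every column must vary.
#' @param sd_type \code{"population"} (default) or \code{"sample"} scaling.
#' @return symmetric positive semi-definite lines x lines matrix with a
#'   \code{"n_markers_used"} attribute.
#' @export
compute_grm <- function(m, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (anyNA(m)) stop("marker matrix must be imputed before computing G")
  n_lines <- nrow(m)
  mu <- colMeans(m)
  X <- sweep(m, 2, mu)
  ss <- colMeans(X^2)
  if (sd_type == "sample") ss <- ss * n_lines / (n_lines - 1)
  zero <- ss < .Machine$double.eps
  if (any(zero)) {
    stop("zero-variance marker(s): ",
         paste(utils::head(colnames(m)[zero], 5), collapse = ", "),
         " — filter before computing G")
  }
  X <- sweep(X, 2, sqrt(ss), "/")
  G <- tcrossprod(X) / ncol(m)
  G <- (G + t(G)) / 2
  attr(G, "n_markers_used") <- ncol(m)
  G
}

#' Run the full marker QC chain
#'
#' Optional allelic-independence filter, missingness/MAF filter, imputation,
#' and genomic relationship matrix, returning all intermediates plus a QC
#' report.
#'
#' @param m raw dosage matrix.
#' @param max_missing,min_maf passed to [filter_markers()].
#' @param impute_method passed to [impute_markers()].
#' @param fisher if TRUE, apply [fisher_allelic_filter()] first (off by
#'   default: GBS pipelines usually apply it upstream during SNP calling).
#' @param fisher_alpha significance level for the allelic filter.
#' @return list with \code{markers} (imputed matrix), \code{G}, and
#'   \code{report} (counts per rule).
#' @export
genotype_qc <- function(m, max_missing = 0.80, min_maf = 0.05,
                        impute_method = "column_mean",
                        fisher = FALSE, fisher_alpha = 0.001) {
  report <- list(n_input = ncol(m))
  if (fisher) {
    m <- fisher_allelic_filter(m, alpha = fisher_alpha)
    report$fisher <- attr(m, "fisher")
  }
  m <- filter_markers(m, max_missing = max_missing, min_maf = min_maf)
  report$filter <- attr(m, "qc")
  m <- impute_markers(m, method = impute_method)
  G <- compute_grm(m)
  report$n_final <- ncol(m)
  list(markers = m, G = G, report = report)
}
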