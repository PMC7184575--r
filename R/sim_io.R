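#' Write a dosage matrix as CSV
#'
#' Lines in rows (first column \code{line_id}), markers in columns. Missing
#' calls are written as empty cells.
#'
#' @param dosage lines x markers numeric matrix with dimnames.
#' @param path output file.
#' @export
write_dosage_csv <- function(dosage, path) {
  df <- data.frame(line_id = rownames(dosage), dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a dosage matrix from CSV
#'
#' Inverse of [write_dosage_csv()]: first column line ids, remaining columns
#' one marker each, empty/NA cells treated as missing.
#'
#' @param path CSV file.
#' @return lines x markers numeric matrix with dimnames.
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate line ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate marker ids in ", path)
  bad <- m[!is.na(m)]
  if (any(bad < 0 | bad > 2)) stop("dosages must lie in [0, 2]")
  m
}

#' Write a dosage matrix as a minimal biallelic VCF
#'
#' Emits one biallelic record per marker (REF=A, ALT=C, placeholder
#' positions) with unphased GT calls: dosage 0 -> 0/0, 1 -> 0/1, 2 -> 1/1,
#' missing -> ./. . The file round-trips through [read_vcf_dosage()].
#'
#' @param dosage lines x markers matrix of 0/1/2 dosages with NA for missing.
#' @param path output VCF path (uncompressed).
#' @export
write_vcf <- function(dosage, path) {
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("dosage matrix needs line and marker names")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mkblup",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosage)), collapse = "\t")
  ), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  n_mark <- ncol(dosage)
  rows <- character(n_mark)
  for (j in seq_len(n_mark)) {
    d <- dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    rows[j] <- paste(c("1", j, colnames(dosage)[j], "A", "C", ".", "PASS",
                       ".", "GT", gt), collapse = "\t")
  }
  writeLines(rows, con)
  invisible(path)
}

#' Write plot-level phenotypes, ground truth and config to disk
#'
#' @param trial a \code{"sim_trial"} (optionally with physiology columns).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "sim_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_plots <- file.path(dir, "plots.csv")
  utils::write.csv(trial$plots, p_plots, row.names = FALSE)
  gt <- data.frame(genotype = names(trial$truth$g), g = trial$truth$g,
                   trial$truth$ge, check.names = FALSE)
  p_truth <- file.path(dir, "ground_truth.csv")
  utils::write.csv(gt, p_truth, row.names = FALSE)
  p_cfg <- file.path(dir, "sim_config.txt")
  write_sim_config(trial$config, p_cfg)
  invisible(c(plots = p_plots, truth = p_truth, config = p_cfg))
}

#' Write a simulation config as a key=value text file
#' @param config a [sim_config()].
#' @param path output file.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  fmt <- function(v) paste(format(v, digits = 15, trim = TRUE), collapse = ",")
  keys <- names(config)
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    if (!is.null(names(v)) && any(nzchar(names(v)))) {
      paste0(k, "=", paste(names(v), unname(v), sep = ":", collapse = ","))
    } else {
      paste0(k, "=", fmt(v))
    }
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
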