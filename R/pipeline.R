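#' Pipeline configuration
#'
#' Declares the inputs, stages and parameters for an end-to-end run: either a
#' [sim_config()] (synthetic study) or paths to a dosage CSV and a plot-level
#' phenotype CSV. One global seed deterministically derives every stage seed
#' (simulation uses the sim config's own seed; stratification, chains and
#' importance use fixed offsets from \code{seed}), so stages are individually
#' reproducible.
#'
#' @param out_dir output directory.
#' @param sim optional [sim_config()] for a synthetic run.
#' @param genotype_csv,plots_csv optional input files (used when \code{sim}
#'   is NULL).
#' @param models model names to fit/cross-validate.
#' @param traits physiological traits for the P kernel (NULL: all available).
#' @param k_groups,folds stratification groups and CV folds.
#' @param chain a [chain_config()] template for all fits.
#' @param dth_covariate use DTH-corrected LSmeans?
#' @param importance an [importance_config()] for the trait-importance stage.
#' @param run_cv,run_importance stage toggles.
#' @param intensity selection intensity for response to selection.
#' @param seed global seed.
#' @param force recompute stages even when cached outputs exist.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir, sim = NULL, genotype_csv = NULL,
                            plots_csv = NULL,
                            models = c("G", "G+GE", "G+PE", "P", "P+PE", "P+GE"),
                            traits = NULL, k_groups = 10, folds = 5,
                            chain = chain_config(), dth_covariate = FALSE,
                            importance = importance_config(),
                            run_cv = TRUE, run_importance = TRUE,
                            intensity = 0.10, seed = 1L, force = FALSE) {
  if (is.null(sim) && (is.null(genotype_csv) || is.null(plots_csv))) {
    stop("supply either a sim config or both genotype_csv and plots_csv")
  }
  if (!is.null(genotype_csv) && !file.exists(genotype_csv)) {
    stop("genotype_csv not found: ", genotype_csv)
  }
  if (!is.null(plots_csv) && !file.exists(plots_csv)) {
    stop("plots_csv not found: ", plots_csv)
  }
  structure(list(out_dir = out_dir, sim = sim, genotype_csv = genotype_csv,
                 plots_csv = plots_csv, models = models, traits = traits,
                 k_groups = k_groups, folds = folds, chain = chain,
                 dth_covariate = dth_covariate, importance = importance,
                 run_cv = run_cv,
                 run_importance = run_importance, intensity = intensity,
                 seed = as.integer(seed), force = force),
            class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("out_dir", "force"))]
  digest_input <- paste(utils::capture.output(utils::str(cfg, digits.d = 15)),
                        collapse = "\n")
  tmp <- tempfile()
  writeLines(digest_input, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: data simulation (or ingest), marker QC and
#' genomic kernel, derived physiological traits and LSmeans/heritability,
#' physiological kernel and record-level interaction kernels, model
#' cross-validation with response to selection, and trait-importance
#' ranking. Each stage writes CSV outputs plus an internal cache under
#' \code{out_dir}; re-running with an unchanged configuration skips completed
#' stages unless \code{force}. A JSON manifest records the configuration
#' hash, per-stage parameters and the md5 of every written file.
#'
#' @param config a [pipeline_config()].
#' @return list of class \code{"pipeline_result"} with the stage outputs and
#'   the manifest (also written to \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  old_hash <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path)$config_hash,
             error = function(e) NULL)
  } else NULL
  reuse <- identical(old_hash, hash) && !config$force
  stages_run <- character()

  stage <- function(name, compute) {
    cache <- file.path(cache_dir, paste0(name, ".rds"))
    if (reuse && file.exists(cache)) {
      return(readRDS(cache))
    }
    res <- compute()
    saveRDS(res, cache)
    stages_run <<- c(stages_run, name)
    res
  }

  # -- data ------------------------------------------------------------
  dat <- stage("data", function() {
    if (!is.null(config$sim)) {
      mk <- simulate_markers(config$sim)
      trial <- simulate_physiology(simulate_trial(mk, config$sim), config$sim)
      write_dosage_csv(mk$dosage, file.path(config$out_dir, "dosage.csv"))
      write_sim_trial(trial, config$out_dir)
      list(dosage = mk$dosage, plots = trial$plots, truth = trial$truth)
    } else {
      list(dosage = read_dosage_csv(config$genotype_csv),
           plots = utils::read.csv(config$plots_csv, stringsAsFactors = FALSE),
           truth = NULL)
    }
  })

  # -- marker QC + genomic kernel --------------------------------------
  qc <- stage("genotype_qc", function() {
    res <- genotype_qc(dat$dosage)
    write_kernel_csv(res$G, file.path(config$out_dir, "G.csv"))
    jsonlite::write_json(res$report, file.path(config$out_dir, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res
  })

  # -- phenotypes -------------------------------------------------------
  pheno <- stage("phenotype", function() {
    plots <- derive_plot_traits(dat$plots)
    envs <- unique(plots$environment)
    h2 <- vapply(envs, function(e) heritability(plots, "GY", e)$H2, numeric(1))
    names(h2) <- envs
    lsm_gy <- compute_lsmeans(plots, "GY", dth_covariate = config$dth_covariate)
    trait_cols <- intersect(c("SPAD", "CT", "MT", paste0("NDVI_", 1:6),
                              "RS", "SG", "DTH"), names(plots))
    lsm_traits <- do.call(rbind, lapply(trait_cols, function(tr) {
      compute_lsmeans(plots, tr)
    }))
    lsm_all <- rbind(lsm_gy, lsm_traits)
    class(lsm_all) <- class(lsm_gy)
    utils::write.csv(lsm_all, file.path(config$out_dir, "lsmeans.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(environment = envs, H2 = h2),
                     file.path(config$out_dir, "heritability.csv"),
                     row.names = FALSE)
    list(plots = plots, h2 = h2, lsm_gy = lsm_gy, lsm_traits = lsm_traits)
  })

  # -- kernels ----------------------------------------------------------
  kern <- stage("kernels", function() {
    design <- record_design(pheno$lsm_gy)
    P <- compute_physio_kernel(pheno$lsm_traits,
                               traits = config$traits %||%
                                 setdiff(unique(pheno$lsm_traits$trait), "DTH"))
    common <- intersect(rownames(qc$G), rownames(P))
    keep <- design$records$genotype %in% common
    design <- record_design(design$records$genotype[keep],
                            design$records$environment[keep])
    kernels <- build_model_kernels(G = qc$G, P = P, design = design)
    write_kernel_csv(P, file.path(config$out_dir, "P.csv"))
    utils::write.csv(design$records, file.path(config$out_dir, "design.csv"),
                     row.names = FALSE)
    list(design = design, P = P, kernels = kernels)
  })

  y <- pheno$lsm_gy$lsmean[match(
    paste(kern$design$records$genotype, kern$design$records$environment),
    paste(pheno$lsm_gy$genotype, pheno$lsm_gy$environment))]

  # -- cross-validation + response to selection -------------------------
  cv <- NULL
  if (config$run_cv) {
    cv <- stage("cv", function() {
      groups <- stratify_lines(qc$markers, k_groups = config$k_groups,
                               seed = config$seed + 10L)
      folds <- assign_folds(groups, f = config$folds,
                            seed = config$seed + 11L)
      ch <- config$chain
      ch$seed <- config$seed + 20L
      res <- cross_validate(y, kern$design, as.list(config$models),
                            kern$kernels, folds, pheno$h2, chain = ch,
                            intensity = config$intensity)
      utils::write.csv(res$accuracy, file.path(config$out_dir, "accuracy.csv"),
                       row.names = FALSE)
      utils::write.csv(res$rts, file.path(config$out_dir, "rts.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(line = names(folds$folds),
                                  group = as.character(folds$groups),
                                  fold = folds$folds),
                       file.path(config$out_dir, "folds.csv"),
                       row.names = FALSE)
      res
    })
  }

  # -- trait importance -------------------------------------------------
  imp <- NULL
  if (config$run_importance) {
    imp <- stage("importance", function() {
      traits <- setdiff(attr(kern$P, "traits_used"), "DTH")
      wide <- stats::reshape(
        pheno$lsm_traits[pheno$lsm_traits$trait %in% c(traits, "DTH"),
                         c("genotype", "trait", "lsmean")],
        idvar = "genotype", timevar = "trait", direction = "wide")
      names(wide) <- sub("^lsmean\\.", "", names(wide))
      agg <- stats::aggregate(. ~ genotype, data = wide, FUN = mean,
                              na.rm = TRUE, na.action = NULL)
      gy <- stats::aggregate(lsmean ~ genotype, data = pheno$lsm_gy, mean)
      merged <- merge(agg, gy, by = "genotype")
      Xmat <- as.matrix(merged[, traits, drop = FALSE])
      ok <- stats::complete.cases(Xmat, merged$lsmean)
      cfg <- config$importance
      cfg$seed <- config$seed + 30L
      cfg$dth_corrected <- config$dth_covariate
      res <- tune_and_rank(Xmat[ok, , drop = FALSE], merged$lsmean[ok],
                           cfg, dth = merged$DTH[ok])
      utils::write.csv(
        data.frame(trait = names(res$importance),
                   coefficient = unname(res$coefficients),
                   importance = unname(res$importance)),
        file.path(config$out_dir, "importance.csv"), row.names = FALSE)
      res
    })
  }

  outputs <- list.files(config$out_dir, pattern = "\\.(csv|json|txt)$",
                        full.names = TRUE)
  outputs <- setdiff(outputs, manifest_path)
  manifest <- list(
    config_hash = hash,
    seed = config$seed,
    models = config$models,
    stages_run = stages_run,
    files = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  structure(list(qc = qc, pheno = pheno, design = kern$design,
                 kernels = kern$kernels, cv = cv, importance = imp,
                 manifest = manifest),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
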