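# shared fixtures, all generated in code

# small deterministic dosage matrix with names
tiny_dosage <- function(n_lines = 6, n_markers = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(0:2, n_lines * n_markers, replace = TRUE),
              n_lines, n_markers,
              dimnames = list(sprintf("L%d", seq_len(n_lines)),
                              sprintf("M%d", seq_len(n_markers))))
  storage.mode(m) <- "double"
  m
}

random_psd <- function(n, seed = 1, ids = sprintf("L%d", seq_len(n))) {
  set.seed(seed)
  A <- matrix(rnorm(n * (n + 2)), n)
  K <- tcrossprod(A) / (n + 2)
  dimnames(K) <- list(ids, ids)
  K
}

# record-level simulation on the scale of the prediction models:
# y = env mean + g + ge + residual, one record per line x environment
record_sim <- function(n_lines, n_envs, var_g, var_ge, var_e,
                       n_markers = 1000, seed = 1, env_means = NULL) {
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers, n_envs = n_envs,
                    var_genetic = var_g, var_ge = var_ge, var_error = var_e,
                    env_means = env_means %||% rep(0, n_envs),
                    block_sd = 0, missing_rate = 0,
                    n_qtl = min(300, n_markers), seed = seed)
  mk <- simulate_markers(cfg)
  tr <- simulate_trial(mk, cfg)
  G <- compute_grm(impute_markers(filter_markers(mk$dosage, min_maf = 0.01)))
  envs <- colnames(tr$truth$ge)
  des <- record_design(rep(rownames(G), n_envs), rep(envs, each = n_lines))
  li <- match(des$records$genotype, names(tr$truth$g))
  ei <- match(des$records$environment, envs)
  set.seed(seed + 500)
  y <- cfg$env_means[ei] + tr$truth$g[li] + tr$truth$ge[cbind(li, ei)] +
    rnorm(nrow(des$records), sd = sqrt(var_e))
  list(cfg = cfg, markers = mk, G = G, design = des, y = y,
       g = tr$truth$g, ge = tr$truth$ge, truth = tr$truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed-form single-kernel BLUP: u = s2g K (s2g K + s2e I)^-1 (y - X b_GLS)
blup_oracle <- function(y, K, X, s2g, s2e) {
  V <- s2g * K + diag(s2e, nrow(K))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  drop(s2g * K %*% Vi %*% (y - drop(X %*% b)))
}
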