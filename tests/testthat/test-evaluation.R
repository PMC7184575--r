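test_that("PCA + k-means stratification recovers planted families", {
  cfg <- sim_config(n_lines = 100, n_markers = 1000, n_families = 10,
                    fst = 0.4, missing_rate = 0, seed = 12)
  mk <- simulate_markers(cfg)
  groups <- stratify_lines(mk$dosage, k_groups = 10, seed = 1)
  ari <- mclust::adjustedRandIndex(groups, mk$family)
  expect_gt(ari, 0.95)

  one <- stratify_lines(mk$dosage, k_groups = 1, seed = 1)
  expect_equal(nlevels(droplevels(one)), 1)

  # permuting line order: same partition up to label switching
  perm <- sample(nrow(mk$dosage))
  gp <- stratify_lines(mk$dosage[perm, ], k_groups = 10, seed = 1)
  expect_equal(mclust::adjustedRandIndex(gp, groups[perm]), 1)

  expect_error(stratify_lines(mk$dosage, k_groups = 200), "exceed")
})

test_that("fold assignment keeps groups whole and sizes balanced", {
  set.seed(13)
  sizes <- sample(21:35, 10, replace = TRUE)   # panel-like group sizes
  groups <- factor(rep(seq_len(10), times = sizes))
  names(groups) <- sprintf("L%d", seq_along(groups))
  folds <- assign_folds(groups, f = 5, seed = 2)
  n <- length(groups)
  fold_sizes <- table(folds$folds)
  expect_length(fold_sizes, 5)
  expect_true(all(abs(fold_sizes - n / 5) <= max(sizes)))
  # exhaustive: no group split across folds
  for (g in levels(groups)) {
    expect_length(unique(folds$folds[groups == g]), 1)
  }

  # singleton groups degenerate to a plain balanced random partition
  singletons <- factor(seq_len(40))
  names(singletons) <- sprintf("S%d", 1:40)
  f2 <- assign_folds(singletons, f = 5, seed = 3)
  expect_true(all(table(f2$folds) == 8))

  expect_error(assign_folds(factor(c(1, 1, 2)), f = 5), "fewer groups")
})

test_that("accuracy adjustment follows the heritability formulas", {
  expect_equal(adjusted_accuracy(0.3, 0.36)$r_GY, 0.5)
  a <- adjusted_accuracy(0.3, 0.25, sd_r = 0.10, f = 5)
  expect_equal(a$SE, 0.10 / sqrt(5 * 0.25))
  expect_equal(a$SE, 0.0894, tolerance = 1e-3)
  # monotone decreasing in H2 for fixed r_p
  h2s <- c(0.2, 0.4, 0.6, 0.8)
  vals <- vapply(h2s, function(h) adjusted_accuracy(0.3, h)$r_GY, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(adjusted_accuracy(0.3, 0), "undefined")
})

test_that("response to selection matches its formula and brute force", {
  y <- setNames(rep(5, 12), sprintf("L%d", 1:12))
  gebv <- setNames(rnorm(12), names(y))
  r0 <- response_to_selection(gebv, y, h2 = 0.4)
  expect_equal(r0$S, 0)
  expect_equal(r0$R, 0)

  # R = H2 * S arithmetic
  y2 <- setNames(c(rep(200, 2), rep(100, 18)), sprintf("L%d", 1:20))
  gebv2 <- setNames(seq(20, 1), names(y2))   # selects L1, L2
  r2 <- response_to_selection(gebv2, y2, h2 = 0.5)
  expect_equal(r2$S, 200 - mean(y2))
  expect_equal(r2$R, 0.5 * r2$S)
  expect_equal(length(r2$selected), ceiling(0.1 * 20))

  # perfect predictor: S equals the best over all subsets of that size
  set.seed(14)
  y3 <- setNames(rnorm(20, 3000, 400), sprintf("L%d", 1:20))
  r3 <- response_to_selection(y3, y3, h2 = 0.3)
  best <- max(combn(y3, 2, mean))
  expect_equal(r3$mu_S, best)

  # random rankings average to S ~ 0
  ss <- vapply(1:200, function(i) {
    shuffled <- setNames(sample(unname(y3)), names(y3))
    response_to_selection(shuffled, y3, h2 = 1)$S
  }, numeric(1))
  expect_lt(abs(mean(ss)), 100)

  expect_error(response_to_selection(y3, y3, h2 = 1, intensity = 0), "intensity")
  expect_error(response_to_selection(y3[-1], y3, h2 = 1), "same lines")
})

test_that("cross-validation is leakage-free and exact in the noise-free limit", {
  cfg <- sim_config(n_lines = 60, n_markers = 20, n_qtl = 20,
                    var_genetic = 40, var_ge = 0, var_error = 0,
                    missing_rate = 0, n_envs = 1, env_means = 0,
                    block_sd = 0, seed = 15)
  mk <- simulate_markers(cfg)
  tr <- simulate_trial(mk, cfg)
  G <- compute_grm(impute_markers(filter_markers(mk$dosage, min_maf = 0.01)))
  des <- record_design(rownames(G), rep("ENV_1", nrow(G)))
  y <- unname(tr$truth$g[des$records$genotype])
  ks <- build_model_kernels(G = G, design = des)
  groups <- factor(seq_len(nrow(G)))
  names(groups) <- rownames(G)
  folds <- assign_folds(groups, f = 5, seed = 4)
  ch <- chain_config(n_iter = 2000, burn_in = 400, thin = 2, seed = 5)
  cv <- cross_validate(y, des, list("G"), ks, folds, c(ENV_1 = 1), chain = ch)
  expect_gt(min(cv$per_fold$r), 0.95)
  expect_equal(cv$accuracy$r_GY, cv$accuracy$r_p)   # H2 = 1

  # mutating the masked (validation) responses cannot change their GEBVs
  y_mut <- y
  v1 <- names(folds$folds)[folds$folds == 1]
  idx1 <- des$records$genotype %in% v1
  y_mut[idx1] <- 999999
  cv2 <- cross_validate(y_mut, des, list("G"), ks, folds, c(ENV_1 = 1),
                        chain = ch)
  expect_equal(cv2$gebv$G[idx1], cv$gebv$G[idx1])
})

test_that("models with interaction kernels beat G-only when GE is informative", {
  r_gy <- sapply(1:3, function(s) {
    rs <- record_sim(80, 3, var_g = 30, var_ge = 0, var_e = 40,
                     n_markers = 800, seed = s + 30)
    # GE deviations drawn from the reaction-norm covariance itself, so the
    # interaction kernel is informative by construction
    set.seed(s + 900)
    ev <- eigen(rs$G, symmetric = TRUE)
    half <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
    li <- match(rs$design$records$genotype, rownames(rs$G))
    for (e in rs$design$env_levels) {
      ge_e <- sqrt(30) * drop(half %*% rnorm(nrow(rs$G)))
      sel <- rs$design$records$environment == e
      rs$y[sel] <- rs$y[sel] + ge_e[li[sel]]
    }
    ks <- build_model_kernels(G = rs$G, design = rs$design)
    groups <- stratify_lines(impute_markers(rs$markers$dosage),
                             k_groups = 8, seed = s)
    folds <- assign_folds(groups, f = 5, seed = s)
    h2 <- setNames(rep(0.4, 3), rs$design$env_levels)
    ch <- chain_config(n_iter = 1200, burn_in = 300, thin = 2, seed = s)
    cv <- cross_validate(rs$y, rs$design, list("G", "G+GE"), ks, folds, h2,
                         chain = ch)
    tapply(cv$accuracy$r_GY, cv$accuracy$model, mean)[c("G", "G+GE")]
  })
  expect_gt(mean(r_gy["G+GE", ] - r_gy["G", ]), 0)
})
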