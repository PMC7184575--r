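test_that("membrane thermostability follows (1 - T1/T2) x 100", {
  expect_equal(membrane_thermostability(20, 80), 75)
  expect_equal(membrane_thermostability(50, 50), 0)
  expect_equal(membrane_thermostability(0, 123.4), 100)
  expect_equal(membrane_thermostability(c(20, 0), c(80, 10)), c(75, 100))
  expect_error(membrane_thermostability(10, 0), "positive")
  expect_error(membrane_thermostability(-1, 10), "non-negative")
  expect_warning(membrane_thermostability(90, 80), "negative MT")
})

test_that("thermal time accumulates clamped daily means", {
  expect_equal(accumulate_gdd(rep(10, 10), rep(20, 10))[10], 150)
  expect_true(all(accumulate_gdd(rep(-10, 5), rep(-2, 5)) == 0))
  set.seed(1)
  tmin <- rnorm(30, 5, 6); tmax <- tmin + abs(rnorm(30, 6, 2))
  # independent loop oracle
  acc <- 0; oracle <- numeric(30)
  for (i in 1:30) {
    acc <- acc + max(0, (tmin[i] + tmax[i]) / 2)
    oracle[i] <- acc
  }
  expect_equal(accumulate_gdd(tmin, tmax), oracle)
  expect_equal(accumulate_gdd(tmin, tmax, t_base = 5),
               cumsum(pmax(0, (tmin + tmax) / 2 - 5)))
  expect_error(accumulate_gdd(1:3, 1:4), "aligned")
  expect_error(accumulate_gdd(10, 5), "tmax")
})

test_that("NDVI decay fit recovers exact lines and matches the OLS oracle", {
  agdd <- c(100, 250, 400, 550, 700, 850)
  f <- fit_ndvi_decay(0.8 - 5e-4 * agdd, agdd)
  expect_equal(f$slope, -5e-4, tolerance = 1e-12)
  expect_equal(f$intercept, 0.8, tolerance = 1e-12)

  f2 <- fit_ndvi_decay(c(0.8, 0.6), c(100, 300))
  expect_equal(f2$slope, -0.001)
  expect_equal(f2$intercept, 0.9)

  set.seed(2)
  y <- 0.9 - 4e-4 * agdd + rnorm(6, 0, 0.05)
  f3 <- fit_ndvi_decay(y, agdd)
  A <- cbind(1, agdd)
  coef <- solve(crossprod(A), crossprod(A, y))   # normal-equations oracle
  expect_equal(f3$intercept, coef[1], tolerance = 1e-10)
  expect_equal(f3$slope, coef[2], tolerance = 1e-10)

  # missing points are dropped; degenerate inputs error
  f4 <- fit_ndvi_decay(c(0.8, NA, 0.6), c(100, 200, 300))
  expect_equal(f4$slope, -0.001)
  expect_error(fit_ndvi_decay(c(0.8, NA), c(100, 300)), "at least 2")
  expect_error(fit_ndvi_decay(c(0.8, 0.6), c(100, 100)), "zero variance")
})

test_that("stay-green evaluates the decay line at maturity", {
  expect_equal(stay_green(-5e-4, 0.8, 1000), 0.3)
  expect_equal(stay_green(0, 0.77, 5000), 0.77)
  expect_warning(sg <- stay_green(-1e-3, 0.8, 1000), "outside")
  expect_equal(sg, -0.2)
  expect_equal(stay_green(-1e-3, 0.8, 1000, clip = TRUE), 0)
})

test_that("senescence slope is shift-invariant and scale-equivariant in AGDD", {
  agdd <- c(100, 250, 400, 550, 700, 850)
  set.seed(3)
  y <- 0.85 - 3e-4 * agdd + rnorm(6, 0, 0.02)
  f <- fit_ndvi_decay(y, agdd)
  fs <- fit_ndvi_decay(y, agdd + 500)
  expect_equal(fs$slope, f$slope, tolerance = 1e-12)
  expect_equal(fs$intercept, f$intercept - 500 * f$slope, tolerance = 1e-10)
  fc <- fit_ndvi_decay(y, agdd * 3)
  expect_equal(fc$slope, f$slope / 3, tolerance = 1e-12)
})

test_that("derived traits populate MT, RS and SG columns consistently", {
  cfg <- sim_config(n_lines = 20, n_markers = 60, n_envs = 1,
                    n_blocks_per_env = 2, missing_rate = 0, seed = 5,
                    ndvi_noise_sd = 0)
  tr <- simulate_physiology(simulate_trial(simulate_markers(cfg), cfg), cfg)
  plots <- derive_plot_traits(tr$plots)
  expect_equal(plots$RS, unname(tr$truth$ndvi_slope), tolerance = 1e-10)
  expect_equal(plots$SG,
               unname(tr$truth$ndvi_slope * cfg$agdd_pm +
                        tr$truth$ndvi_intercept),
               tolerance = 1e-10)
  expect_equal(plots$MT, membrane_thermostability(plots$T1, plots$T2))
})

test_that("LSmeans reduce to raw means in balanced designs", {
  # balanced complete design, two blocks, no covariate
  set.seed(6)
  d <- expand.grid(genotype = sprintf("G%d", 1:8), block = c("B1", "B2"),
                   stringsAsFactors = FALSE)
  d$environment <- "E1"
  d$GY <- rnorm(nrow(d), 100, 10)
  lsm <- compute_lsmeans(d, "GY")
  raw <- tapply(d$GY, d$genotype, mean)
  expect_equal(lsm$lsmean[match(names(raw), lsm$genotype)], as.numeric(raw),
               tolerance = 1e-6)

  # single block: per-genotype means exactly
  d1 <- d[d$block == "B1", ]
  lsm1 <- compute_lsmeans(d1, "GY")
  expect_equal(lsm1$lsmean[match(d1$genotype, lsm1$genotype)], d1$GY)
})

test_that("LSmeans beat raw means on augmented designs with block effects", {
  wins <- vapply(1:10, function(s) {
    cfg <- sim_config(n_lines = 80, n_markers = 200, n_envs = 1,
                      n_blocks_per_env = 4, env_means = 0, block_sd = 300,
                      var_genetic = 40000, var_ge = 0, var_error = 20000,
                      missing_rate = 0, n_qtl = 60, seed = s)
    tr <- simulate_trial(simulate_markers(cfg), cfg)
    lsm <- compute_lsmeans(tr$plots, "GY")
    g <- tr$truth$g[lsm$genotype]
    raw <- tapply(tr$plots$GY, tr$plots$genotype, mean)[lsm$genotype]
    rmse_ls <- sqrt(mean((scale(lsm$lsmean, scale = FALSE) -
                            scale(g, scale = FALSE))^2))
    rmse_raw <- sqrt(mean((scale(raw, scale = FALSE) -
                             scale(g, scale = FALSE))^2))
    rmse_ls < rmse_raw
  }, logical(1))
  expect_gte(sum(wins), 8)
})

test_that("a DTH covariate orthogonal to genotype leaves LSmeans unchanged", {
  set.seed(7)
  d <- expand.grid(genotype = sprintf("G%d", 1:10), block = c("B1", "B2", "B3"),
                   stringsAsFactors = FALSE)
  d$environment <- "E1"
  d$DTH <- rnorm(nrow(d), 110, 3)          # independent of genotype
  d$GY <- rnorm(nrow(d), 100, 10)
  lsm0 <- compute_lsmeans(d, "GY", dth_covariate = FALSE)
  lsm1 <- compute_lsmeans(d, "GY", dth_covariate = TRUE)
  expect_true(attr(lsm1, "dth_corrected"))
  expect_equal(lsm1$lsmean, lsm0$lsmean, tolerance = 0.15)
})

test_that("heritability recovers symmetric and null variance structures", {
  h2_est <- function(vg, ve, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(n_lines = 200, n_markers = 200, n_envs = 1,
                        n_blocks_per_env = 3, env_means = 0, block_sd = 5,
                        var_genetic = vg, var_ge = 0, var_error = ve,
                        missing_rate = 0, n_qtl = 60, seed = s)
      tr <- simulate_trial(simulate_markers(cfg), cfg)
      heritability(tr$plots, "GY", "ENV_1")$H2
    }, numeric(1))
  }
  est <- h2_est(50, 50, 1:10)
  expect_true(all(est >= 0 & est <= 1))
  expect_lt(abs(mean(est) - 0.5), 0.05)

  # null case on a fully replicated design: identical genotypes give H2 ~ 0
  null_est <- vapply(1:4, function(s) {
    set.seed(s)
    d <- expand.grid(genotype = sprintf("G%d", 1:50),
                     block = sprintf("B%d", 1:4), stringsAsFactors = FALSE)
    d$environment <- "E1"
    d$GY <- rnorm(nrow(d), 100, 10)
    heritability(d, "GY", "E1")$H2
  }, numeric(1))
  expect_lt(mean(null_est), 0.05)

  d <- data.frame(environment = "E1", block = "B1",
                  genotype = sprintf("G%d", 1:10), GY = rnorm(10))
  expect_error(heritability(d, "GY", "E1"), "replicated")
})

test_that("trait-yield correlations report r, P and stars", {
  set.seed(8)
  gy <- rnorm(50, 3000, 400)
  lsm <- rbind(
    data.frame(genotype = sprintf("G%d", 1:50), environment = "E1",
               trait = "GY", lsmean = gy, se = 1),
    data.frame(genotype = sprintf("G%d", 1:50), environment = "E1",
               trait = "SAME", lsmean = gy, se = 1),
    data.frame(genotype = sprintf("G%d", 1:50), environment = "E1",
               trait = "NEG", lsmean = -gy, se = 1),
    data.frame(genotype = sprintf("G%d", 1:50), environment = "E1",
               trait = "FLAT", lsmean = rep(1, 50), se = 1))
  class(lsm) <- c("lsmeans_table", "data.frame")
  ct <- trait_yield_correlations(lsm, "E1")
  expect_equal(ct$r[ct$trait == "SAME"], 1)
  expect_equal(ct$r[ct$trait == "NEG"], -1)
  expect_identical(ct$stars[ct$trait == "SAME"], "***")
  expect_true(is.na(ct$r[ct$trait == "FLAT"]))
})

test_that("planted trait-yield correlation is recovered at panel size", {
  rs <- vapply(1:10, function(s) {
    cfg <- sim_config(n_lines = 242, n_markers = 300, n_envs = 1, n_qtl = 100,
                      missing_rate = 0, seed = s + 100)
    tr <- simulate_physiology(simulate_trial(simulate_markers(cfg), cfg), cfg)
    lgy <- compute_lsmeans(tr$plots, "GY")
    lsp <- compute_lsmeans(tr$plots, "SPAD")
    lsm <- rbind(lgy, lsp)
    class(lsm) <- class(lgy)
    trait_yield_correlations(lsm, "ENV_1")$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.38) , 0.2)
})
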