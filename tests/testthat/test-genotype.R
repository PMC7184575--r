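test_that("marker filtering applies the missingness and MAF rules", {
  m <- tiny_dosage(10, 4, seed = 2)
  m[, 1] <- c(rep(NA, 9), 2)            # 0.9 missing: removed
  m[, 2] <- rep(c(0, 2), 5)             # MAF 0.5, complete: retained
  m[, 3] <- c(2, rep(0, 9))             # MAF 0.10: retained
  m[, 4] <- rep(0, 10)                  # MAF 0: removed
  out <- filter_markers(m)
  expect_identical(colnames(out), c("M2", "M3"))
  qc <- attr(out, "qc")
  expect_equal(qc$n_removed_missing, 1)
  expect_equal(qc$n_removed_maf, 1)

  # boundary cases are retained: exactly 80% missing, MAF exactly 0.05
  mb <- matrix(rep(c(0, 2), each = 10), 20, 2,
               dimnames = list(sprintf("L%d", 1:20), c("A", "B")))
  mb[1:16, 1] <- NA                     # exactly 0.80 missing
  mb[17:20, 1] <- c(0, 2, 0, 2)         # observed calls stay polymorphic
  mb[, 2] <- c(2, rep(0, 19))           # MAF exactly 0.05
  expect_identical(colnames(filter_markers(mb)), c("A", "B"))

  expect_error(filter_markers(matrix(0, 5, 2)), "all markers removed")
})

test_that("imputation fills missing calls with column statistics", {
  m <- tiny_dosage(6, 5, seed = 3)
  expect_identical(impute_markers(m), m)   # complete input untouched

  m2 <- matrix(c(0, 2, 2, 2, NA), 5, 1, dimnames = list(NULL, "M1"))
  expect_equal(unname(impute_markers(m2, "column_mean")[5, 1]), 1.5)
  expect_equal(unname(impute_markers(m2, "major_allele")[5, 1]), 2)

  set.seed(9)
  m3 <- tiny_dosage(40, 30, seed = 4)
  mask <- matrix(runif(length(m3)) < 0.05, nrow(m3))
  m3m <- m3; m3m[mask] <- NA
  imp <- impute_markers(m3m, "column_mean")
  for (j in seq_len(ncol(m3))) {
    obs_mean <- mean(m3m[, j], na.rm = TRUE)
    expect_equal(unname(imp[is.na(m3m[, j]), j]),
                 rep(obs_mean, sum(is.na(m3m[, j]))))
  }

  m4 <- m3m; m4[, 2] <- NA
  expect_error(impute_markers(m4), "all calls missing")
})

test_that("allelic-independence filter keeps complementary loci and drops degenerate ones", {
  # 25 ref-fixed + 25 alt-fixed inbreds: perfectly dependent alleles
  m <- cbind(comp = c(rep(0, 25), rep(2, 25)),
             mono = rep(0, 50),
             good2 = c(rep(2, 25), rep(0, 25)))
  rownames(m) <- sprintf("L%d", 1:50)
  out <- fisher_allelic_filter(m)
  expect_identical(colnames(out), c("comp", "good2"))
  expect_equal(attr(out, "fisher")$n_removed_degenerate, 1)
  # oracle: exact hypergeometric two-sided P for the 2x2 [[0,25],[25,0]]
  p_exact <- 2 * dhyper(0, 25, 25, 25)
  expect_lt(p_exact, 0.001)
  expect_equal(fisher.test(matrix(c(0, 25, 25, 0), 2))$p.value, p_exact)
})

test_that("independent allele presences are retained at about the alpha rate", {
  # each allele present independently with probability 0.5; the four cells
  # map to dosage het / ref-only / alt-only / no-call
  set.seed(21)
  n <- 50; n_mark <- 2000
  cell <- matrix(sample(1:4, n * n_mark, replace = TRUE), n, n_mark)
  m <- matrix(NA_real_, n, n_mark,
              dimnames = list(sprintf("L%d", 1:n), sprintf("M%d", 1:n_mark)))
  m[cell == 1] <- 1; m[cell == 2] <- 0; m[cell == 3] <- 2
  kept <- tryCatch(ncol(fisher_allelic_filter(m)),
                   error = function(e) 0L)
  expect_lte(kept / n_mark, 0.01)        # Fisher's test is conservative
})

test_that("the genomic relationship matrix matches hand arithmetic and its identities", {
  m <- matrix(c(0, 2, 0, 2), 2, 2,
              dimnames = list(c("L1", "L2"), c("M1", "M2")))
  G <- compute_grm(m)
  expect_equal(unname(G), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  m2 <- tiny_dosage(20, 50, seed = 5)
  m2 <- impute_markers(filter_markers(m2, min_maf = 0.01))
  G2 <- compute_grm(m2)
  expect_equal(G2, t(G2))
  expect_equal(mean(diag(G2)), 1, tolerance = 1e-12)

  # duplicating every marker leaves G unchanged (the /n cancels)
  expect_equal(compute_grm(cbind(m2, m2)), G2, tolerance = 1e-12,
               ignore_attr = TRUE)

  # marker order permutation leaves G unchanged; line permutation conforms
  perm_m <- sample(ncol(m2)); perm_l <- sample(nrow(m2))
  expect_equal(compute_grm(m2[, perm_m]), G2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(compute_grm(m2[perm_l, ])),
               unname(G2[perm_l, perm_l]), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(compute_grm(cbind(m2, M99 = rep(1, nrow(m2)))),
               "zero-variance")
  expect_error(compute_grm(tiny_dosage() * NA), "imputed")
})

test_that("family structure shows up as elevated within-family relationships", {
  cfg <- sim_config(n_lines = 200, n_markers = 2000, n_families = 2,
                    fst = 0.3, missing_rate = 0, seed = 17)
  mk <- simulate_markers(cfg)
  G <- compute_grm(impute_markers(filter_markers(mk$dosage, min_maf = 0.01)))
  same <- outer(as.integer(mk$family), as.integer(mk$family), "==")
  diag(same) <- NA
  expect_gt(mean(G[which(same)]), mean(G[which(!same)]))
})

test_that("QC pipeline is deterministic and counts planted failures", {
  set.seed(31)
  n <- 40
  good <- matrix(sample(c(0, 2), n * 200, replace = TRUE, prob = c(0.6, 0.4)),
                 n, 200)
  low_maf <- matrix(rep(0, n * 30), n); low_maf[1, ] <- 2  # MAF 1/40 < 0.05
  over_miss <- matrix(sample(c(0, 2), n * 20, replace = TRUE), n, 20)
  over_miss[seq_len(ceiling(0.9 * n)), ] <- NA
  m <- cbind(good, low_maf, over_miss)
  colnames(m) <- sprintf("M%d", seq_len(ncol(m)))
  rownames(m) <- sprintf("L%d", seq_len(n))
  res1 <- genotype_qc(m)
  res2 <- genotype_qc(m)
  expect_identical(res1$G, res2$G)
  expect_equal(res1$report$filter$n_removed_maf, 30)
  expect_equal(res1$report$filter$n_removed_missing, 20)
})

test_that("VCF writer and reader round-trip dosages, rejecting multiallelic sites", {
  cfg <- sim_config(n_lines = 10, n_markers = 15, missing_rate = 0.2,
                    het_rate = 0.1, seed = 23)
  mk <- simulate_markers(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(mk$dosage, path)
  back <- read_vcf_dosage(path)
  expect_equal(back, mk$dosage)

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", sep = "\t"),
               paste("1", "10", "snp1", "A", "C,G", ".", "PASS", ".", "GT",
                     "0/1", sep = "\t")), bad)
  expect_error(read_vcf_dosage(bad), "multiallelic")
})
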