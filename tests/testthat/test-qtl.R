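test_that("GRM standardization gives unit diagonal mean and clone symmetry", {
  set.seed(41)
  gt <- random_gt(20, 100, seed = 41)
  # clone sample 1 into sample 2
  d <- gt$dosage; d[2, ] <- d[1, ]
  gt2 <- make_gt(d)
  g <- compute_grm(gt2)
  expect_equal(mean(diag(g)), 1, tolerance = 1e-8)
  expect_equal(g[1, 2], g[1, 1], tolerance = 1e-12)
  expect_equal(g, t(g))
})

test_that("GRM equals hand-computed XXt/M on a tiny example", {
  d <- matrix(c(0, 1, 2, 1,
                2, 0, 1, 1,
                0, 2, 2, 0), nrow = 4)
  gt <- make_gt(d)
  xc <- sweep(d, 2, colMeans(d))
  xs <- sweep(xc, 2, sqrt(colMeans(xc^2)), "/")
  expect_equal(unname(compute_grm(gt)), unname(tcrossprod(xs) / 3),
               tolerance = 1e-12)
})

test_that("OLS scan matches the lm() oracle on fuzzed instances", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(30:80, 1)
    gt <- random_gt(n, 12, seed = 42 + rep)
    C <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2")))
    y <- rnorm(n) + 0.5 * gt$dosage[, 6] + C %*% c(0.3, -0.2)
    pm <- make_pm(matrix(y, 1), tss = gt$variants$pos[6])
    rec <- cis_scan(gt, pm, covariate_matrix(C, validate = FALSE),
                    window_bp = 3000, maf_min = 0)
    for (k in seq_len(nrow(rec))) {
      ora <- lm_oracle(as.vector(y), gt$dosage[, rec$variant_id[k]], C)
      expect_equal(rec$beta[k], ora$beta, tolerance = 1e-8)
      expect_equal(rec$se[k], ora$se, tolerance = 1e-8)
      expect_equal(rec$p[k], ora$p, tolerance = 1e-8)
    }
  }
})

test_that("LMM with identity GRM reduces to OLS", {
  gt <- random_gt(50, 30, seed = 43)
  set.seed(43)
  y <- matrix(rnorm(3 * 50), 3, 50)
  y[1, ] <- y[1, ] + 0.8 * gt$dosage[, 10]
  pm <- make_pm(y, tss = gt$variants$pos[c(10, 15, 20)])
  C <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "c1"))
  cv <- covariate_matrix(C, validate = FALSE)
  ols <- cis_scan(gt, pm, cv, window_bp = 5000, maf_min = 0)
  lmm <- cis_scan(gt, pm, cv, window_bp = 5000, maf_min = 0,
                  model = "lmm", grm = diag(50))
  expect_equal(lmm$p, ols$p, tolerance = 1e-6)
  expect_equal(lmm$beta, ols$beta, tolerance = 1e-6)
})

test_that("noiseless phenotype recovers its generative slope with tiny p", {
  gt <- random_gt(40, 10, seed = 44)
  y <- 2 * gt$dosage[, 5]
  pm <- make_pm(matrix(y, 1), tss = gt$variants$pos[5])
  rec <- cis_scan(gt, pm, maf_min = 0)
  hit <- rec[rec$variant_id == gt$variants$id[5], ]
  expect_equal(hit$beta, 2, tolerance = 1e-12)
  expect_lt(hit$p, 1e-200)
})

test_that("missing dosages are mean-imputed and constants skipped", {
  gt <- random_gt(30, 6, seed = 45)
  d <- gt$dosage
  d[1:3, 2] <- NA         # missing: imputed
  d[, 4] <- 1             # constant: skipped
  gt2 <- make_gt(d)
  y <- rnorm(30)
  pm <- make_pm(matrix(y, 1), tss = 3000)
  rec <- cis_scan(gt2, pm, maf_min = 0)
  expect_false(gt2$variants$id[4] %in% rec$variant_id)
  expect_true(gt2$variants$id[2] %in% rec$variant_id)
})

test_that("hierarchical FDR reproduces the hand-worked BH example", {
  rec <- data.frame(
    feature_id = c("G1", "G1", "G1", "G2", "G2", "G3", "G3"),
    variant_id = c("s1", "s2", "s3", "s4", "s5", "s6", "s7"),
    p = c(0.0005, 0.04, 0.8, 0.3, 0.6, 0.004, 0.01))
  res <- hierarchical_fdr(rec, alpha = 0.05)
  expect_equal(res$features$min_P_prime, c(0.0015, 0.6, 0.008))
  expect_equal(res$features$P_double_prime, c(0.0045, 0.6, 0.012))
  expect_identical(res$features$significant, c(TRUE, FALSE, TRUE))
  expect_equal(res$snp_threshold, 0.008)
  expect_identical(res$records$variant_id[res$records$significant],
                   c("s1", "s6"))
})

test_that("hierarchical FDR degenerate inputs behave", {
  rec <- data.frame(feature_id = c("A", "B"), variant_id = c("x", "y"),
                    p = c(1, 1))
  res <- hierarchical_fdr(rec)
  expect_false(any(res$features$significant))
  expect_true(is.na(res$snp_threshold))
  one <- hierarchical_fdr(data.frame(feature_id = "A", variant_id = "x",
                                     p = 0.01))
  expect_equal(one$features$P_double_prime, 0.01)
  expect_true(one$features$significant)
  expect_equal(one$snp_threshold, 0.01)
  expect_true(one$records$significant)
  expect_error(hierarchical_fdr(NULL), "no association records")
})

test_that("P_prime dominates p and every significant feature has a significant SNP", {
  set.seed(46)
  gt <- random_gt(100, 200, seed = 46)
  y <- matrix(rnorm(20 * 100), 20, 100)
  y[1:5, ] <- y[1:5, ] + 1.0 * t(gt$dosage[, seq(10, 90, 20)])
  pm <- make_pm(y, tss = seq(10000, 200000, length.out = 20))
  res <- hierarchical_fdr(cis_scan(gt, pm))
  expect_true(all(res$records$P_prime >= res$records$p))
  expect_true(all(res$features$P_double_prime >= res$features$min_P_prime))
  sig_f <- res$features$feature_id[res$features$significant]
  sig_with_snp <- unique(res$records$feature_id[res$records$significant])
  expect_setequal(sig_f, sig_with_snp)
})

test_that("conditioning on the causal variant removes the signal", {
  gt <- random_gt(120, 60, seed = 47)
  set.seed(47)
  y <- 1.2 * gt$dosage[, 30] + rnorm(120)
  pm <- make_pm(matrix(y, 1), tss = gt$variants$pos[30])
  res0 <- hierarchical_fdr(cis_scan(gt, pm))
  expect_true(res0$features$significant[1])
  cond <- conditional_scan(gt, pm, conditioning =
                             list(G001 = gt$variants$id[30]),
                           original_threshold = res0$snp_threshold)
  expect_false(cond$flags$independent[1])
})

test_that("conditioning on an unlinked variant retains the signal", {
  gt <- random_gt(120, 120, seed = 48)
  set.seed(48)
  # G001 carries a strong signal; G002 a moderate one that sets the
  # threshold, leaving G001 ample margin after conditioning
  y <- rbind(1.5 * gt$dosage[, 20] + rnorm(120),
             0.7 * gt$dosage[, 80] + rnorm(120))
  pm <- make_pm(y, tss = gt$variants$pos[c(20, 80)])
  res0 <- hierarchical_fdr(cis_scan(gt, pm))
  expect_true(all(res0$features$significant))
  far <- gt$variants$id[110]  # unlinked (independent simulation)
  expect_warning(
    cond <- conditional_scan(gt, pm,
                             conditioning = list(G001 = c(far, "nope")),
                             original_threshold = res0$snp_threshold),
    "absent")
  expect_true(cond$flags$independent[cond$flags$feature_id == "G001"])
})

test_that("empty conditioning set reproduces the unconditioned scan", {
  gt <- random_gt(60, 40, seed = 49)
  set.seed(49)
  pm <- make_pm(matrix(rnorm(60), 1), tss = gt$variants$pos[20])
  rec0 <- cis_scan(gt, pm)
  cond <- conditional_scan(gt, pm, conditioning = list(),
                           original_threshold = 0.05)
  expect_equal(cond$records$p, rec0$p)
  expect_equal(cond$records$beta, rec0$beta)
})
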