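test_that("expression filter boundaries are strict where specified", {
  n <- 162
  counts <- rbind(g1 = c(rep(6, 19), rep(0, n - 19)),   # 19 < 20 individuals
                  g2 = c(rep(6, 20), rep(0, n - 20)),   # passes count rule
                  g3 = rep(6, n))
  tpm <- rbind(g1 = rep(2, n),
               g2 = rep(0.1, n),                        # mean exactly 0.1
               g3 = rep(0.2, n))
  kept <- filter_expression_features(counts, tpm)
  expect_false("g1" %in% kept)
  expect_false("g2" %in% kept)   # strict > on mean TPM
  expect_true("g3" %in% kept)
})

test_that("expression filter equals brute-force predicate evaluation", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 50; g <- 40
    counts <- matrix(rpois(g * n, 4), g, n,
                     dimnames = list(sprintf("g%02d", 1:g), NULL))
    tpm <- matrix(rexp(g * n, 5), g, n, dimnames = dimnames(counts))
    th <- filter_thresholds(expr_min_reads = 3, expr_min_individuals = 10,
                            expr_min_mean_tpm = 0.2)
    kept <- filter_expression_features(counts, tpm, th)
    brute <- rownames(counts)[vapply(1:g, function(i) {
      sum(counts[i, ] > 3) >= 10 && mean(tpm[i, ]) > 0.2
    }, logical(1))]
    expect_identical(kept, brute)
  }
})

test_that("splicing filter boundaries and brute-force agreement", {
  n <- 120
  # intron with exactly 6 zero-read individuals is excluded (max 5)
  counts <- rbind(i1 = c(rep(0, 6), rep(5, n - 6)),
                  i2 = rep(25, n),
                  i3 = rep(30, n))
  cl <- c("c1", "c1", "c2")
  th <- filter_thresholds(cluster_min_individuals = 100)
  kept <- filter_splicing_features(counts, cl, th)
  expect_false("i1" %in% kept)
  expect_true("i2" %in% kept)   # cluster c1 totals pass via i2+i1
  expect_true("i3" %in% kept)
  # cluster with >= 20 reads in only 99 individuals: all introns excluded
  counts2 <- rbind(j1 = c(rep(20, 99), rep(1, n - 99)),
                   j2 = rep(0.0, n))
  kept2 <- filter_splicing_features(counts2, c("c1", "c1"), th)
  expect_length(kept2, 0)
  expect_error(filter_splicing_features(counts, c("c1", NA, "c2"), th),
               "cluster")
  # fuzzed agreement with row-wise predicates
  set.seed(32)
  g <- 30
  cmat <- matrix(rpois(g * n, 8), g, n,
                 dimnames = list(sprintf("i%02d", 1:g), NULL))
  clmap <- rep(sprintf("c%d", 1:10), each = 3)
  th2 <- filter_thresholds(intron_max_zero_individuals = 2,
                           cluster_min_reads = 20,
                           cluster_min_individuals = 60,
                           cluster_max_zero_individuals = 4)
  kept3 <- filter_splicing_features(cmat, clmap, th2)
  brute <- rownames(cmat)[vapply(1:g, function(i) {
    tot <- colSums(cmat[clmap == clmap[i], , drop = FALSE])
    sum(cmat[i, ] == 0) <= 2 && sum(tot >= 20) >= 60 && sum(tot == 0) < 4
  }, logical(1))]
  expect_identical(kept3, brute)
})

test_that("stage-2 normalization maps ranks onto the fixed normal grid", {
  # Latin-square rank pattern: stage 1 is rank-preserving here, so the
  # stage-2 map of [5, 1, 9] is exactly the 3-point normal grid
  x <- rbind(c(5, 1, 9), c(1, 9, 5), c(9, 5, 1))
  pm <- make_pm(x, tss = c(100, 200, 300))
  qn <- two_stage_quantile_normalize(pm)
  expect_equal(unname(qn$values[1, ]), c(0, -0.9674216, 0.9674216),
               tolerance = 1e-6)
  # every feature's sorted values equal the same quantile vector
  grid <- qnorm((1:3 - 0.5) / 3)
  for (i in 1:3) expect_equal(sort(unname(qn$values[i, ])), grid,
                              tolerance = 1e-12)
  # per-feature means vanish on the symmetric grid
  expect_lt(max(abs(rowMeans(qn$values))), 1e-12)
})

test_that("quantile normalization is equivariant to sample permutation", {
  set.seed(33)
  x <- matrix(rnorm(80), 8, 10)
  pm <- make_pm(x, tss = seq(100, 800, 100))
  qn1 <- two_stage_quantile_normalize(pm)$values
  perm <- sample(10)
  pm2 <- make_pm(x[, perm], tss = seq(100, 800, 100))
  qn2 <- two_stage_quantile_normalize(pm2)$values
  expect_equal(qn2, qn1[, perm])
})

test_that("constant features are flagged and mapped to zero", {
  # feature 1 is the within-sample minimum everywhere, so it remains
  # constant through stage 1 and degenerates in stage 2
  x <- rbind(c(1, 1, 1, 1), c(4, 2, 3, 5))
  pm <- make_pm(x, tss = c(100, 200))
  qn <- two_stage_quantile_normalize(pm)
  expect_equal(unname(qn$values[1, ]), rep(0, 4))
  expect_true("G001" %in% attr(qn, "constant_features"))
})

test_that("hidden factors recover a rank-1 structure and are orthogonal", {
  set.seed(34)
  u <- rnorm(30); v <- rnorm(12)
  x <- outer(u, v)  # features x samples, rank 1
  pm <- make_pm(x, tss = seq_len(30) * 100)
  f1 <- infer_hidden_factors(pm, 1)
  expect_gt(abs(cor(f1$values[, 1], v)), 0.999)
  pm2 <- make_pm(x + matrix(rnorm(360, sd = 0.01), 30, 12),
                 tss = seq_len(30) * 100)
  fk <- infer_hidden_factors(pm2, 11)
  g <- crossprod(fk$values)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_error(infer_hidden_factors(pm, 0), "positive")
  expect_error(infer_hidden_factors(pm, 12), "min")
})

test_that("factor-count selection follows the tie and single-grid rules", {
  set.seed(35)
  gt <- random_gt(60, 150, seed = 35)
  cfg_like_vals <- matrix(rnorm(40 * 60), 40, 60)
  pm <- make_pm(cfg_like_vals, tss = seq(5000, 145000, length.out = 40))
  pm <- two_stage_quantile_normalize(pm)
  single <- select_factor_count(gt, pm, grid = 0)
  expect_equal(single$k, 0L)
  res <- select_factor_count(gt, pm, grid = c(0, 1, 2))
  # pure-noise phenotypes: all k give (near-)identical discovery counts;
  # ties must resolve to the smallest k with that count
  best <- max(res$discoveries)
  expect_equal(res$k,
               min(as.integer(names(res$discoveries)[res$discoveries == best])))
  expect_error(select_factor_count(gt, pm, grid = integer(0)), "empty")
})

test_that("a strong latent confounder makes k=1 at least as productive as k=0", {
  cfg <- sim_config(n_pops = 1, samples_per_pop = 120, n_variants = 400,
                    n_genes = 80, frac_causal = 0.5, effect_size_sd = 0.7,
                    n_latent_factors = 1, covariate_effect_sd = 1.5, seed = 36)
  sim <- simulate_genotypes(cfg)
  cv <- simulate_covariates(sim$genotypes, cfg)
  expr <- simulate_expression_phenotypes(sim$genotypes, cfg, covariates = cv)
  qn <- two_stage_quantile_normalize(expr$phenotypes)
  res <- select_factor_count(sim$genotypes, qn, grid = c(0, 1))
  expect_gte(res$discoveries[["1"]], res$discoveries[["0"]])
})
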