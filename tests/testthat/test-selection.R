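test_that("weighted locus scores reduce to hand dot products and bounds", {
  expect_equal(weighted_locus_score(c(0.5, 0.3, 0.2), c(0.6, 0.1, 0.2)), 0.37)
  expect_equal(weighted_locus_score(c(1, 0, 0), c(0.9, 0.1, 0.5)), 0.9)
  expect_equal(weighted_locus_score(rep(0.25, 4), c(1, 2, 3, 4)), 2.5)
  # missing statistics dropped with renormalization; bounds respected
  s <- weighted_locus_score(c(0.5, 0.3, 0.2), c(NA, 0.1, 0.4))
  expect_equal(s, (0.3 * 0.1 + 0.2 * 0.4) / 0.5)
  expect_error(weighted_locus_score(c(0.5, 0.5), c(NA, NA)), "missing")
  set.seed(71)
  for (i in 1:20) {
    pp <- causal_posteriors(rnorm(6)); st <- rnorm(6)
    w <- weighted_locus_score(pp, st)
    expect_gte(w, min(st)); expect_lte(w, max(st))
  }
})

test_that("locus permutation p equals exhaustive enumeration on small loci", {
  # point-mass PP on the maximal statistic of 5 distinct values: the
  # observed score is attained only when that statistic lands on the
  # point-mass position, i.e. in (k-1)! of k! permutations
  st <- c(0.1, 0.9, 0.3, 0.5, 0.7)
  pp <- c(0, 1, 0, 0, 0)
  res <- locus_permutation_test(pp, st, B = 5000, seed = 1)
  # exhaustive: P(null >= obs) = 1/5
  expect_equal(res$p, (1 + 5000 / 5) / 5001, tolerance = 0.2)
  # constant statistic: every permutation ties the observed score
  cres <- locus_permutation_test(c(0.7, 0.2, 0.1), rep(0.4, 3), B = 200,
                                 seed = 2)
  expect_equal(cres$p, 1)
  expect_error(locus_permutation_test(c(1), c(0.2), B = 10), ">= 2")
  expect_error(locus_permutation_test(c(0.5, 0.5), c(0.1, 0.2), B = 0),
               "positive")
})

test_that("permutation p matches the exact enumeration distribution", {
  # 4 variants, generic weights: enumerate all 24 permutations exactly
  pp <- c(0.4, 0.3, 0.2, 0.1)
  st <- c(2, -1, 0.5, 3)
  obs <- sum(pp * st)
  p4 <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p4 <- as.matrix(p4[apply(p4, 1, function(r) length(unique(r)) == 4), ])
  exact <- mean(apply(p4, 1, function(o) sum(pp * st[o]) >= obs))
  res <- locus_permutation_test(pp, st, B = 20000, seed = 3)
  expect_equal(mean(res$null >= res$observed), exact, tolerance = 0.02)
})

test_that("locus permutation p-values are uniform under exchangeable nulls", {
  set.seed(72)
  pvals <- vapply(1:200, function(i) {
    pp <- causal_posteriors(rnorm(15))
    st <- rnorm(15)
    locus_permutation_test(pp, st, B = 199)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("candidate calling applies both predicates", {
  set.seed(73)
  snp_fst <- rbeta(5000, 1, 10)
  thr <- quantile(snp_fst, 0.99, names = FALSE)
  wf <- c(thr + 0.1, thr + 0.1, thr - 0.01)
  ep <- c(0.005, 0.5, 0.005)
  flags <- call_candidates_global(wf, ep, snp_fst)
  expect_identical(flags, c(TRUE, FALSE, FALSE))
  # fuzzed agreement with brute-force predicates
  wf2 <- runif(50, 0, 0.6); ep2 <- runif(50)
  expect_identical(call_candidates_global(wf2, ep2, snp_fst),
                   wf2 > thr & ep2 < 0.01)
  snp_d <- rexp(5000); snp_pbs <- rnorm(5000, 0, 0.05)
  td <- quantile(snp_d, 0.995, names = FALSE)
  tp <- quantile(snp_pbs, 0.995, names = FALSE)
  wd <- c(td + 1, td + 1, td - 0.1)
  wp <- c(tp + 1, tp - 0.01, tp + 1)
  expect_identical(
    call_candidates_population(wd, wp, snp_d, snp_pbs),
    c(TRUE, FALSE, FALSE))
})

test_that("FST outlier enrichment: extreme and degenerate cases", {
  set.seed(74)
  m <- 600
  ids <- sprintf("v%03d", 1:m)
  fst <- setNames(c(sort(runif(m - 10, 0, 0.3)), runif(10, 0.8, 1)), ids)
  maf <- setNames(runif(m, 0.05, 0.5), ids)
  ld_sets <- setNames(as.list(ids), ids)  # LD sets of size 1: the lead only
  leads <- names(sort(fst, decreasing = TRUE))[1:5]  # top-FST variants
  res <- suppressWarnings(
    fst_outlier_enrichment(leads, ld_sets, fst, maf, B = 400, seed = 1))
  expect_equal(res$observed, 1)
  expect_equal(res$p, 1 / 401, tolerance = 1e-12)
  # LD sets of size 1: max-in-LD equals the lead's own FST
  expect_equal(res$threshold, quantile(fst, 0.99, names = FALSE))
})

test_that("FST outlier enrichment is calibrated under null lead placement", {
  set.seed(75)
  m <- 1500
  ids <- sprintf("v%04d", 1:m)
  fst <- setNames(rbeta(m, 1, 8), ids)
  maf <- setNames(runif(m, 0.05, 0.5), ids)
  sizes <- sample(0:12, m, TRUE)
  ld_sets <- setNames(lapply(1:m, function(i) {
    c(ids[i], sample(ids[-i], sizes[i]))
  }), ids)
  reps <- 40
  pvals <- vapply(1:reps, function(r) {
    leads <- sample(ids, 60)
    suppressWarnings(
      fst_outlier_enrichment(leads, ld_sets, fst, maf, B = 150,
                             seed = 100 + r))$p
  }, numeric(1))
  type1 <- mean(pvals < 0.05)
  expect_lte(type1, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(mean(pvals), 0.2)  # p distributed away from 0
})

test_that("annotation enrichment: identity background gives exactly zero", {
  set.seed(76)
  m <- 200
  info <- data.frame(id = sprintf("v%03d", 1:m), chrom = "chr1",
                     pos = seq(1000, by = 500, length.out = m),
                     maf = runif(m, 0.05, 0.5),
                     tss_distance = runif(m, 0, 5e4))
  ann <- list(enh = data.frame(chrom = "chr1", start = 1000, end = 20000))
  qtl <- info$id[1:40]
  res <- annotation_enrichment(qtl, info, ann, pool = qtl, B = 50, seed = 1)
  expect_true(all(res$scores == 0))
})

test_that("annotation enrichment detects constructed enrichment, not noise", {
  set.seed(77)
  m <- 1000
  info <- data.frame(id = sprintf("v%04d", 1:m), chrom = "chr1",
                     pos = sample(1:1e6, m), maf = runif(m, 0.05, 0.5),
                     tss_distance = runif(m, 0, 5e4))
  # category C covers a fixed set of positions; QTL set drawn 3x enriched
  inC <- info$pos <= 3e5
  qtl_pool_in <- info$id[inC]; qtl_pool_out <- info$id[!inC]
  hits <- 0
  for (r in 1:10) {
    qtl <- c(sample(qtl_pool_in, 60), sample(qtl_pool_out, 40))
    res <- annotation_enrichment(
      qtl, info, list(C = data.frame(chrom = "chr1", start = 1, end = 3e5)),
      B = 200, seed = r)
    if (res$p[["C"]] < 0.05 && res$mean_score[["C"]] > 0) hits <- hits + 1
  }
  expect_gte(hits, 8)
  # random annotation: mean score near 0
  res0 <- annotation_enrichment(
    sample(info$id, 100), info,
    list(R = data.frame(chrom = "chr1",
                        start = seq(1, 1e6, 2e4),
                        end = seq(1, 1e6, 2e4) + 1e4)),
    B = 300, seed = 99)
  expect_lt(abs(res0$mean_score[["R"]]), 0.25)
})
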