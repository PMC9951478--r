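#' Storey's pi1 (fraction of true positives)
#'
#' Estimates the null proportion `pi0(lambda) = #{p > lambda} / (m (1 -
#' lambda))` on a lambda grid. The smoother method fits a cubic smoothing
#' spline (df = 3) to `pi0(lambda)` and evaluates it at the largest lambda;
#' the fixed method reads `pi0` at `lambda = 0.5`. The estimate is clipped
#' to \[0, 1\] and `pi1 = 1 - pi0`.
#'
#' @param pvalues vector of replication p-values.
#' @param lambda_grid grid in (0, 1) (default `seq(0.05, 0.95, 0.05)`).
#' @param method `"smoother"` or `"fixed"`.
#' @return list of class `pi1_result`: `pi0`, `pi1`, `lambda`, `method`.
#' @export
estimate_pi1 <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05),
                         method = c("smoother", "fixed")) {
  method <- match.arg(method)
  pvalues <- pvalues[!is.na(pvalues)]
  m <- length(pvalues)
  if (m == 0) stop("empty p-value input")
  if (m < 100) warning("fewer than 100 p-values; pi1 estimate is unstable")
  pi0_l <- vapply(lambda_grid, function(l) sum(pvalues > l) / (m * (1 - l)),
                  numeric(1))
  pi0 <- if (method == "fixed") {
    pi0_l[which.min(abs(lambda_grid - 0.5))]
  } else {
    fit <- smooth.spline(lambda_grid, pi0_l, df = 3)
    predict(fit, x = max(lambda_grid))$y
  }
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi0 = pi0, pi1 = 1 - pi0, lambda = lambda_grid,
                 pi0_lambda = pi0_l, method = method),
            class = "pi1_result")
}

#' Exact two-sided binomial test
#'
#' Two-sided exact binomial p-value by the minimum-likelihood method: the
#' sum of P(X = x) over all outcomes at most as probable as the observed
#' count (the convention of [stats::binom.test]).
#'
#' @param k observed successes.
#' @param n trials (> 0).
#' @param p0 null success probability (default 0.5).
#' @return list with `p`, `k`, `n`, `p0`, `estimate` (k/n).
#' @export
exact_binomial_test <- function(k, n, p0 = 0.5) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  res <- binom.test(k, n, p = p0, alternative = "two.sided")
  list(p = res$p.value, k = k, n = n, p0 = p0, estimate = k / n)
}

#' One-sided Kolmogorov-Smirnov test
#'
#' One-sided sup-difference of empirical CDFs. With `alternative =
#' "greater"` the alternative is that `sample_b` is stochastically greater
#' than `sample_a` (its CDF lies below), `D = sup_x (F_a(x) - F_b(x))`;
#' `"less"` is the mirror image. The asymptotic p-value is
#' `exp(-2 D^2 m n / (m + n))`; a permutation p-value (useful at small n)
#' is available via `permutations`.
#'
#' @param sample_a,sample_b numeric samples.
#' @param alternative `"greater"` or `"less"` (direction of `sample_b`
#'   relative to `sample_a`).
#' @param permutations if > 0, also compute a permutation p-value.
#' @return list with `statistic` (D), `p`, and optionally `p_permutation`.
#' @export
one_sided_ks_test <- function(sample_a, sample_b,
                              alternative = c("greater", "less"),
                              permutations = 0) {
  alternative <- match.arg(alternative)
  if (!length(sample_a) || !length(sample_b)) stop("samples must be non-empty")
  d_stat <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    fa <- ecdf(a)(pts); fb <- ecdf(b)(pts)
    if (alternative == "greater") max(fa - fb) else max(fb - fa)
  }
  D <- d_stat(sample_a, sample_b)
  m <- length(sample_a); n <- length(sample_b)
  p <- exp(-2 * D^2 * m * n / (m + n))
  out <- list(statistic = D, p = min(1, p), alternative = alternative)
  if (permutations > 0) {
    pooled <- c(sample_a, sample_b)
    null <- replicate(permutations, {
      idx <- sample.int(m + n, m)
      d_stat(pooled[idx], pooled[-idx])
    })
    out$p_permutation <- (1 + sum(null >= D)) / (permutations + 1)
  }
  out
}

#' Cross-population LD-structure correlation
#'
#' Pearson correlation between two populations' r-squared vectors at a
#' locus, aligned on variants polymorphic (and hence present) in both.
#'
#' @param r2_pop1,r2_pop2 named r-squared vectors from [ld_r2_window].
#' @return Pearson rho, or NA if fewer than 3 shared variants or a vector
#'   is constant.
#' @export
ld_structure_correlation <- function(r2_pop1, r2_pop2) {
  shared <- intersect(names(r2_pop1), names(r2_pop2))
  if (length(shared) < 3) return(NA_real_)
  a <- r2_pop1[shared]; b <- r2_pop2[shared]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

# Alleles whose flip is indistinguishable from a strand swap.
.strand_ambiguous <- function(ref, alt) {
  paste(ref, alt) %in% c("A T", "T A", "C G", "G C")
}

#' Effect-size concordance between cohorts
#'
#' Aligns records of two cohorts on shared feature-variant pairs and the
#' same counted (ALT) allele: pairs whose ref/alt are swapped between
#' cohorts have the second cohort's effect sign flipped; strand-ambiguous
#' swaps (A/T, C/G) are dropped with a message. Returns the Pearson
#' correlation and least-squares slope of cohort-b effects on cohort-a
#' effects, overall and per optional group label.
#'
#' @param records_a,records_b data.frames with feature_id, variant_id, ref,
#'   alt, beta.
#' @param groups optional named vector (by `feature_id`) of group labels
#'   (e.g. "shared"/"independent").
#' @return list with `overall` (rho, slope, n) and `by_group` (data.frame),
#'   plus the aligned `pairs` data.frame.
#' @export
effect_size_concordance <- function(records_a, records_b, groups = NULL) {
  key_a <- paste(records_a$feature_id, records_a$variant_id)
  key_b <- paste(records_b$feature_id, records_b$variant_id)
  shared <- intersect(key_a, key_b)
  if (length(shared) < 3) stop("fewer than 3 shared feature-variant pairs")
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  same <- records_a$ref[ia] == records_b$ref[ib] &
    records_a$alt[ia] == records_b$alt[ib]
  flipped <- records_a$ref[ia] == records_b$alt[ib] &
    records_a$alt[ia] == records_b$ref[ib]
  ambiguous <- flipped & .strand_ambiguous(records_a$ref[ia], records_a$alt[ia])
  if (any(ambiguous)) {
    message(sum(ambiguous), " strand-ambiguous allele swap(s) dropped")
  }
  keep <- (same | flipped) & !ambiguous
  beta_a <- records_a$beta[ia][keep]
  beta_b <- ifelse(flipped[keep], -records_b$beta[ib][keep],
                   records_b$beta[ib][keep])
  pairs <- data.frame(feature_id = records_a$feature_id[ia][keep],
                      variant_id = records_a$variant_id[ia][keep],
                      beta_a = beta_a, beta_b = beta_b,
                      stringsAsFactors = FALSE)
  if (!is.null(groups)) pairs$group <- groups[pairs$feature_id]
  conc <- function(x, y) {
    if (length(x) < 3) return(c(rho = NA_real_, slope = NA_real_, n = length(x)))
    c(rho = cor(x, y), slope = coef(lm(y ~ x))[["x"]], n = length(x))
  }
  overall <- conc(pairs$beta_a, pairs$beta_b)
  by_group <- NULL
  if (!is.null(groups)) {
    gs <- split(pairs, pairs$group)
    by_group <- do.call(rbind, lapply(names(gs), function(g) {
      data.frame(group = g, t(conc(gs[[g]]$beta_a, gs[[g]]$beta_b)),
                 stringsAsFactors = FALSE)
    }))
  }
  list(overall = as.list(overall), by_group = by_group, pairs = pairs)
}

#' Classify features as shared or independent
#'
#' Joins conditional-scan flags onto feature ids: "independent" iff the
#' signal remains significant after conditioning, else "shared"; features
#' missing from the conditional output get NA.
#'
#' @param conditional_flags data.frame (`feature_id`, `independent`) from
#'   [conditional_scan].
#' @param feature_ids features to label (default: those in the flags).
#' @return named character vector of labels.
#' @export
classify_shared_independent <- function(conditional_flags,
                                        feature_ids = NULL) {
  if (is.null(feature_ids)) feature_ids <- conditional_flags$feature_id
  idx <- match(feature_ids, conditional_flags$feature_id)
  lab <- ifelse(is.na(idx), NA_character_,
                ifelse(conditional_flags$independent[idx],
                       "independent", "shared"))
  setNames(lab, feature_ids)
}
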