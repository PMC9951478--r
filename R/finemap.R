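#' Wakefield approximate Bayes factors
#'
#' For each variant, `z = beta/se` and `V = se^2` (summary mode) or, when
#' effect estimates are unavailable, `z = qnorm(1 - p/2)` with
#' `V = 1/(2 n f (1 - f))` for allele frequency `f` and sample size `n`
#' (p-value mode; z's sign is arbitrary and does not enter the Bayes
#' factor). With prior effect variance `W` and shrinkage `r = W/(V + W)`,
#' `log ABF = 0.5 * (log(1 - r) + z^2 * r)`. The default prior SD 0.15 is
#' appropriate for a phenotype standardized to unit variance.
#'
#' @param beta,se effect estimates and standard errors (summary mode).
#' @param p,maf,n two-sided p-values, allele frequencies, and sample size
#'   (p-value mode, used when `beta`/`se` are NULL).
#' @param W prior effect variance (default `0.15^2`).
#' @param max_z cap applied to z when `p` underflows to 0 (default 40).
#' @return numeric vector of log ABFs.
#' @export
approximate_bayes_factor <- function(beta = NULL, se = NULL, p = NULL,
                                     maf = NULL, n = NULL, W = 0.15^2,
                                     max_z = 40) {
  if (!is.null(beta) && !is.null(se)) {
    z <- beta / se
    V <- se^2
  } else if (!is.null(p) && !is.null(maf) && !is.null(n)) {
    if (any(maf <= 0 | maf >= 1)) stop("allele frequency must be in (0, 1)")
    z <- qnorm(1 - p / 2)
    z[p == 0 | z > max_z] <- max_z
    V <- 1 / (2 * n * maf * (1 - maf))
  } else {
    stop("provide either (beta, se) or (p, maf, n)")
  }
  r <- W / (V + W)
  0.5 * (log(1 - r) + z^2 * r)
}

#' Per-variant causal posterior probabilities
#'
#' Normalizes approximate Bayes factors within a feature into the posterior
#' probability that each variant is the causal one:
#' `PP_n = ABF_n / sum_p ABF_p`, computed stably in log space.
#'
#' @param log_abf vector of log ABFs for one feature's tested variants.
#' @return numeric vector of posteriors summing to 1.
#' @export
causal_posteriors <- function(log_abf) {
  if (length(log_abf) == 0) stop("need >= 1 variant")
  m <- max(log_abf)
  w <- exp(log_abf - m)
  w / sum(w)
}

#' Build a credible set
#'
#' Sorts variants by descending posterior probability (ties broken by
#' smaller p-value, then by variant id) and takes the minimal prefix whose
#' cumulative posterior mass strictly exceeds `mass`. The strict comparison
#' uses a 1e-9 absolute guard so that exactly-attained boundaries (e.g.
#' uniform posteriors summing to the threshold) do not flip on
#' floating-point round-off.
#'
#' @param pp posterior probabilities (normalized).
#' @param variant_id variant ids aligned with `pp`.
#' @param p optional raw p-values for tie-breaking.
#' @param mass posterior mass threshold (default 0.9).
#' @return list with `variants` (ordered ids in the set), `pp` (their
#'   posteriors), `cumulative` (mass of the set), `size`, and `mass`.
#' @export
build_credible_set <- function(pp, variant_id, p = NULL, mass = 0.9) {
  stopifnot(length(pp) == length(variant_id))
  if (is.null(p)) p <- rep(NA_real_, length(pp))
  o <- order(-pp, p, variant_id)
  cum <- cumsum(pp[o])
  size <- match(TRUE, cum > mass + 1e-9)
  if (is.na(size)) size <- length(pp)
  list(variants = variant_id[o][seq_len(size)],
       pp = pp[o][seq_len(size)],
       cumulative = cum[size], size = size, mass = mass)
}

#' Credible-set overlap between two analyses
#'
#' For each feature present in both lists, tests whether the two credible
#' sets share any variant id. An optional `min_pp` restricts each set to
#' variants with posterior at least that large before intersecting (e.g.
#' 0.1 to require a variant with >10% causal probability).
#'
#' @param cs_a,cs_b named lists of credible sets (as returned by
#'   [build_credible_set]), names = feature ids, over a shared variant space.
#' @param min_pp optional posterior floor applied to both sets.
#' @return list with `overlap` (data.frame feature_id, overlap) and
#'   `summary` (n_features, n_overlap, fraction).
#' @export
credible_set_overlap <- function(cs_a, cs_b, min_pp = NULL) {
  shared <- intersect(names(cs_a), names(cs_b))
  restrict <- function(cs) {
    v <- cs$variants
    if (!is.null(min_pp)) v <- v[cs$pp >= min_pp]
    v
  }
  ov <- vapply(shared, function(f) {
    length(intersect(restrict(cs_a[[f]]), restrict(cs_b[[f]]))) > 0
  }, logical(1))
  list(overlap = data.frame(feature_id = shared, overlap = as.vector(ov),
                            stringsAsFactors = FALSE),
       summary = list(n_features = length(shared), n_overlap = sum(ov),
                      fraction = if (length(shared)) mean(ov) else NA_real_))
}

#' Fine-map all significant features of a scan
#'
#' Convenience wrapper: for each requested feature, computes log ABFs from
#' the scan's effect estimates, normalizes to posteriors, and builds the
#' credible set.
#'
#' @param records association records (with beta, se, p) from [cis_scan].
#' @param feature_ids features to fine-map (default: all in `records`).
#' @param W prior effect variance.
#' @param mass credible-set mass threshold.
#' @return list with `posteriors` (data.frame feature_id, variant_id,
#'   log_abf, PP, in_credible_set) and `credible_sets` (named list).
#' @export
finemap_features <- function(records, feature_ids = NULL, W = 0.15^2,
                             mass = 0.9) {
  if (is.null(feature_ids)) feature_ids <- unique(records$feature_id)
  sets <- list()
  rows <- list()
  for (f in feature_ids) {
    r <- records[records$feature_id == f, , drop = FALSE]
    if (nrow(r) == 0) next
    la <- approximate_bayes_factor(beta = r$beta, se = r$se, W = W)
    pp <- causal_posteriors(la)
    cs <- build_credible_set(pp, r$variant_id, p = r$p, mass = mass)
    sets[[f]] <- cs
    rows[[f]] <- data.frame(feature_id = f, variant_id = r$variant_id,
                            log_abf = la, PP = pp,
                            in_credible_set = r$variant_id %in% cs$variants,
                            stringsAsFactors = FALSE)
  }
  list(posteriors = do.call(rbind, rows), credible_sets = sets)
}
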