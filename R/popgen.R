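#' Per-population allele frequencies and counts
#'
#' ALT-allele frequency `p = sum(dosage) / (2 * non-missing)` and allele
#' count `n = 2 * non-missing diploids`, per variant per population. A
#' population with zero non-missing samples at a variant gets `NA` there.
#'
#' @param genotypes a [genotype_dataset] with population labels.
#' @return list of class `population_frequencies` with matrices `p` and `n`
#'   (variants x populations) and `pops`.
#' @export
population_allele_frequencies <- function(genotypes) {
  pops <- unique(genotypes$populations)
  m <- ncol(genotypes$dosage)
  p <- matrix(NA_real_, m, length(pops),
              dimnames = list(genotypes$variants$id, pops))
  n <- matrix(0, m, length(pops), dimnames = dimnames(p))
  for (k in seq_along(pops)) {
    d <- genotypes$dosage[genotypes$populations == pops[k], , drop = FALSE]
    nm <- colSums(!is.na(d))
    n[, k] <- 2 * nm
    p[, k] <- ifelse(nm > 0, colSums(d, na.rm = TRUE) / (2 * nm), NA_real_)
  }
  structure(list(p = p, n = n, pops = pops), class = "population_frequencies")
}

#' Hudson's FST estimator
#'
#' Per-variant estimator with finite-sample correction:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`. Per-variant values may be negative; variants with
#' denominator 0 are `NA`. The multi-variant aggregate is the ratio of
#' averages `sum(num)/sum(den)`.
#'
#' @param p1,p2 ALT-allele frequencies in the two populations.
#' @param n1,n2 allele counts (2 x diploids), each >= 2.
#' @return list with `fst` (per variant), `numerator`, `denominator`, and
#'   `aggregate` (ratio of averages over variants with defined parts).
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  if (any(n1 < 2, na.rm = TRUE) || any(n2 < 2, na.rm = TRUE)) {
    stop("allele counts must be >= 2")
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(den == 0, NA_real_, num / den)
  ok <- !is.na(num) & !is.na(den) & den != 0
  list(fst = fst, numerator = num, denominator = den,
       aggregate = sum(num[ok]) / sum(den[ok]))
}

#' Genome-wide pairwise FST summaries
#'
#' Per-variant Hudson FST for every population pair, plus each pair's mean
#' and standard deviation across all variants with defined FST — the
#' standardization constants of the polarized d-statistic.
#'
#' @param freqs a `population_frequencies` object.
#' @return list of class `pairwise_fst_summary` with `fst` (variants x
#'   pairs matrix, columns named "A|B"), `mean`, `sd` (named vectors), and
#'   `pairs` (2-column matrix of pair members).
#' @export
pairwise_fst_summary <- function(freqs) {
  pops <- freqs$pops
  pr <- t(combn(pops, 2))
  nm <- paste(pr[, 1], pr[, 2], sep = "|")
  fst <- matrix(NA_real_, nrow(freqs$p), nrow(pr),
                dimnames = list(rownames(freqs$p), nm))
  for (i in seq_len(nrow(pr))) {
    a <- pr[i, 1]; b <- pr[i, 2]
    fst[, i] <- hudson_fst(freqs$p[, a], freqs$n[, a],
                           freqs$p[, b], freqs$n[, b])$fst
  }
  structure(list(fst = fst,
                 mean = apply(fst, 2, mean, na.rm = TRUE),
                 sd = apply(fst, 2, sd, na.rm = TRUE),
                 pairs = pr),
            class = "pairwise_fst_summary")
}

#' Population branch statistic
#'
#' Branch length `T = -log(1 - FST)` per pair; the focal population's branch
#' is `PBS = (T_focal_ref1 + T_focal_ref2 - T_ref1_ref2) / 2`. Negative
#' per-variant FST values are clamped to 0 before the log (a branch length
#' cannot be negative); FST = 1 gives an infinite branch with a warning.
#' Negative PBS values are preserved. Missing inputs give missing output.
#'
#' @param fst_focal_ref1,fst_focal_ref2 FST between the focal population and
#'   each reference.
#' @param fst_ref1_ref2 FST between the two references.
#' @return numeric vector of PBS values.
#' @export
pbs <- function(fst_focal_ref1, fst_focal_ref2, fst_ref1_ref2) {
  branch <- function(f) {
    f <- pmax(f, 0)
    if (any(f >= 1, na.rm = TRUE)) warning("FST >= 1: infinite branch length")
    -log(1 - pmin(f, 1))
  }
  (branch(fst_focal_ref1) + branch(fst_focal_ref2) -
      branch(fst_ref1_ref2)) / 2
}

#' Polarized d-statistic
#'
#' For focal population i, `d_i = | sum_{j != i} s_j (FST_ij - E[FST_ij]) /
#' sd[FST_ij] |` where `s_j = +1` if the focal allele frequency is at least
#' population j's and `-1` otherwise. The polarization prevents variants at
#' intermediate frequency in the focal population (but differentiated
#' elsewhere) from scoring highly: opposite-direction pairs cancel. Pairs
#' with missing frequency or FST are skipped per variant.
#'
#' @param freqs a `population_frequencies` object.
#' @param summary a [pairwise_fst_summary] over the same populations.
#' @param focal_pop focal population label.
#' @return numeric vector of d values per variant (>= 0).
#' @export
polarized_d <- function(freqs, summary, focal_pop) {
  others <- setdiff(freqs$pops, focal_pop)
  if (length(others) < 2) stop("need >= 2 non-focal populations")
  acc <- rep(0, nrow(freqs$p))
  for (j in others) {
    key <- if (paste(focal_pop, j, sep = "|") %in% colnames(summary$fst)) {
      paste(focal_pop, j, sep = "|")
    } else paste(j, focal_pop, sep = "|")
    if (summary$sd[key] == 0) stop("sd of FST is 0 for pair ", key)
    s <- ifelse(freqs$p[, focal_pop] >= freqs$p[, j], 1, -1)
    z <- (summary$fst[, key] - summary$mean[key]) / summary$sd[key]
    contrib <- s * z
    contrib[is.na(contrib)] <- 0
    acc <- acc + contrib
  }
  abs(acc)
}

#' LD r-squared in a window around a lead variant
#'
#' Squared Pearson correlation of dosages between the lead variant and every
#' variant within `window_bp`, computed on a sample subset (typically one
#' population) and restricted to variants polymorphic in that subset.
#'
#' @param genotypes a [genotype_dataset].
#' @param lead_variant variant id.
#' @param window_bp window half-width (default 100000).
#' @param samples optional sample ids defining the subset (default: all).
#' @return named numeric vector of r-squared values (includes the lead
#'   itself, r2 = 1).
#' @export
ld_r2_window <- function(genotypes, lead_variant, window_bp = 100000,
                         samples = NULL) {
  v <- genotypes$variants
  li <- match(lead_variant, v$id)
  if (is.na(li)) stop("lead variant not found: ", lead_variant)
  rows <- if (is.null(samples)) seq_len(nrow(genotypes$dosage)) else
    match(samples, genotypes$samples)
  lead <- genotypes$dosage[rows, li]
  if (sd(lead, na.rm = TRUE) == 0 || all(is.na(lead))) {
    stop("lead variant monomorphic in subset")
  }
  widx <- which(v$chrom == v$chrom[li] & abs(v$pos - v$pos[li]) <= window_bp)
  X <- genotypes$dosage[rows, widx, drop = FALSE]
  poly <- apply(X, 2, function(x) sd(x, na.rm = TRUE) > 0)
  poly[is.na(poly)] <- FALSE
  X <- X[, poly, drop = FALSE]
  r <- suppressWarnings(cor(lead, X, use = "pairwise.complete.obs"))
  setNames(as.vector(r)^2, colnames(X))
}
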