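#' Posterior-weighted locus score
#'
#' Weighted selection score for one feature: `sum_p PP_p * stat_p`, the
#' causal-posterior-weighted average of a per-variant statistic (FST, d, or
#' PBS) over the locus's tested variants. Variants with a missing statistic
#' are dropped and the posteriors renormalized.
#'
#' @param pp normalized posterior probabilities.
#' @param stat per-variant statistic aligned with `pp`.
#' @return scalar score (lies within the range of the used statistics).
#' @export
weighted_locus_score <- function(pp, stat) {
  stopifnot(length(pp) == length(stat))
  ok <- !is.na(stat)
  if (!any(ok)) stop("all per-variant statistics missing")
  pp <- pp[ok] / sum(pp[ok])
  sum(pp * stat[ok])
}

#' Locus permutation test for a weighted score
#'
#' Permutes the per-variant statistic across the locus's variants while
#' holding the posterior weights fixed, recomputing the weighted score each
#' time. The empirical p-value uses the add-one convention
#' `p = (1 + #{null >= observed}) / (B + 1)`, so p is always positive.
#'
#' @param pp normalized posteriors.
#' @param stat per-variant statistic.
#' @param B number of permutations (default 10000).
#' @param seed optional RNG seed.
#' @return list with `observed`, `null` (length-B vector), `p`.
#' @export
locus_permutation_test <- function(pp, stat, B = 10000, seed = NULL) {
  if (B <= 0) stop("B must be positive")
  if (length(pp) < 2) stop("need >= 2 variants at the locus")
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(stat)
  pp <- pp[ok] / sum(pp[ok])
  stat <- stat[ok]
  obs <- sum(pp * stat)
  null <- replicate(B, sum(pp * stat[sample.int(length(stat))]))
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (B + 1))
}

#' Call global selection candidates
#'
#' A feature is a candidate iff its weighted FST score exceeds the `pct`
#' quantile of the genome-wide per-SNP FST distribution AND its locus
#' permutation p-value is below `emp_alpha`.
#'
#' @param weighted_fst per-feature weighted FST scores.
#' @param empirical_p per-feature permutation p-values.
#' @param snp_fst genome-wide per-SNP FST values.
#' @param pct outlier percentile (default 0.99).
#' @param emp_alpha permutation significance level (default 0.01).
#' @return logical vector of candidate flags.
#' @export
call_candidates_global <- function(weighted_fst, empirical_p, snp_fst,
                                   pct = 0.99, emp_alpha = 0.01) {
  thr <- quantile(snp_fst, pct, na.rm = TRUE, names = FALSE)
  weighted_fst > thr & empirical_p < emp_alpha
}

#' Call population-specific selection candidates
#'
#' A feature is a candidate for a focal population iff its weighted d score
#' and weighted PBS score both exceed the `pct` quantile of the respective
#' genome-wide per-SNP distributions. Permutation p-values may optionally be
#' required in addition.
#'
#' @param weighted_d,weighted_pbs per-feature weighted scores.
#' @param snp_d,snp_pbs genome-wide per-SNP d and PBS values.
#' @param pct outlier percentile (default 0.995).
#' @param empirical_p,emp_alpha optional permutation p requirement.
#' @return logical vector of candidate flags.
#' @export
call_candidates_population <- function(weighted_d, weighted_pbs, snp_d,
                                       snp_pbs, pct = 0.995,
                                       empirical_p = NULL, emp_alpha = NULL) {
  flag <- weighted_d > quantile(snp_d, pct, na.rm = TRUE, names = FALSE) &
    weighted_pbs > quantile(snp_pbs, pct, na.rm = TRUE, names = FALSE)
  if (!is.null(empirical_p) && !is.null(emp_alpha)) {
    flag <- flag & empirical_p < emp_alpha
  }
  flag
}

# MAF bin index (width 0.05) and LD-count bin index
# ({0}, {1,2}, (2,5], (5,10], (10,20], (20,50], >50).
.maf_bin <- function(maf) pmin(floor(maf / 0.05), 9)
.ld_bin <- function(k) findInterval(k, c(0, 1, 3, 6, 11, 21, 51))

#' FST-outlier enrichment among lead QTL variants
#'
#' Observed statistic: the fraction of lead variants whose maximum FST over
#' their LD set (r2 > 0.8 companions, lead included) exceeds the outlier
#' threshold (by default the 99th percentile of all SNP FST values). Null:
#' each lead is matched with a random pool SNP from the same MAF bin (width
#' 0.05) and LD-count bin ({0}, {1,2}, (2,5], (5,10], (10,20], (20,50],
#' >50), the max-FST-in-LD-set of the matched SNPs is thresholded the same
#' way, and the null fraction recorded; `B` replicates give the empirical
#' p-value `(1 + #{null >= observed}) / (B + 1)`. Sampling is without
#' replacement within a replicate; lead variants are excluded from the pool.
#' An empty matching bin falls back to the nearest non-empty bin with a
#' warning.
#'
#' @param lead_variants character vector of lead variant ids.
#' @param ld_sets named list: variant id -> ids of variants in LD with it
#'   (including itself); must cover leads and pool.
#' @param snp_fst named per-SNP FST vector (genome-wide).
#' @param maf named per-SNP pooled MAF vector.
#' @param outlier_threshold FST outlier cutoff; default the `pct` quantile
#'   of `snp_fst`.
#' @param pct percentile used when `outlier_threshold` is NULL.
#' @param B replicates (default 10000).
#' @param seed optional RNG seed.
#' @return list with `observed` (outlier fraction), `null` (length-B),
#'   `p`, and `threshold`.
#' @export
fst_outlier_enrichment <- function(lead_variants, ld_sets, snp_fst, maf,
                                   outlier_threshold = NULL, pct = 0.99,
                                   B = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(outlier_threshold)) {
    outlier_threshold <- quantile(snp_fst, pct, na.rm = TRUE, names = FALSE)
  }
  max_fst <- vapply(ld_sets, function(v) {
    f <- snp_fst[v]
    if (all(is.na(f))) NA_real_ else max(f, na.rm = TRUE)
  }, numeric(1))
  obs <- mean(max_fst[lead_variants] > outlier_threshold, na.rm = TRUE)
  pool <- setdiff(names(ld_sets), lead_variants)
  ld_n <- lengths(ld_sets) - 1L
  key <- paste(.maf_bin(maf[names(ld_sets)]), .ld_bin(ld_n), sep = ":")
  names(key) <- names(ld_sets)
  pool_by_bin <- split(pool, key[pool])
  # assign each lead a donor bin, falling back to the nearest non-empty bin
  lead_bin <- key[lead_variants]
  donor_bin <- lead_bin
  empty <- !(lead_bin %in% names(pool_by_bin))
  if (any(empty)) {
    warning(sum(empty), " lead(s) with empty matching bin; nearest non-empty bin used")
    avail <- do.call(rbind, strsplit(names(pool_by_bin), ":"))
    av_m <- as.numeric(avail[, 1]); av_l <- as.numeric(avail[, 2])
    for (i in which(empty)) {
      want <- as.numeric(strsplit(lead_bin[i], ":")[[1]])
      dist <- abs(av_m - want[1]) + abs(av_l - want[2])
      donor_bin[i] <- names(pool_by_bin)[which.min(dist)]
    }
  }
  groups <- split(seq_along(lead_variants), donor_bin)
  null <- numeric(B)
  for (b in seq_len(B)) {
    picked <- character(length(lead_variants))
    for (g in names(groups)) {
      cand <- pool_by_bin[[g]]
      idx <- groups[[g]]
      if (length(cand) >= length(idx)) {
        picked[idx] <- sample(cand, length(idx))
      } else {
        picked[idx] <- sample(cand, length(idx), replace = TRUE)
      }
    }
    null[b] <- mean(max_fst[picked] > outlier_threshold, na.rm = TRUE)
  }
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (B + 1),
       threshold = outlier_threshold)
}

# Membership of positions in a category's interval set (1-based closed).
.interval_membership <- function(chrom, pos, intervals) {
  hit <- logical(length(pos))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    on <- chrom == ch
    if (!any(on)) next
    q <- IRanges::IRanges(start = pos[on], width = 1L)
    s <- IRanges::IRanges(start = iv$start, end = iv$end)
    hit[on] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Matched-background annotation enrichment
#'
#' For each of `B` replicates, every QTL variant is matched with one random
#' background variant from the same MAF bin (width 0.05) and TSS-distance
#' decile (computed on the pool), sampled without replacement within the
#' replicate; QTL variants are excluded from the pool. Per functional
#' category the enrichment score is
#' `log((#QTL in category + 1) / (#background in category + 1))`
#' (pseudocount 1 guards zero counts). Returns the replicate score
#' distribution and an empirical two-sided p per category (add-one
#' convention on the smaller tail, doubled and capped at 1).
#'
#' @param qtl_variants character vector of QTL variant ids.
#' @param variant_info data.frame over pool and QTL variants: `id`, `chrom`,
#'   `pos`, `maf`, `tss_distance`.
#' @param annotations named list of interval data.frames (`chrom`, `start`,
#'   `end`; 1-based closed), one per category.
#' @param pool optional character vector of eligible background ids
#'   (default: all of `variant_info` minus the QTL set).
#' @param B replicates (default 10000).
#' @param seed optional RNG seed.
#' @return list with `scores` (B x categories matrix), `mean_score`, and
#'   `p` (named per category; NA where the category never overlaps).
#' @export
annotation_enrichment <- function(qtl_variants, variant_info, annotations,
                                  pool = NULL, B = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  info <- variant_info
  rownames(info) <- info$id
  if (is.null(pool)) pool <- setdiff(info$id, qtl_variants)
  membership <- vapply(annotations, function(iv) {
    .interval_membership(info$chrom, info$pos, iv)
  }, logical(nrow(info)))
  rownames(membership) <- info$id
  dist_breaks <- unique(quantile(info[pool, "tss_distance"],
                                 probs = seq(0, 1, 0.1), na.rm = TRUE))
  dbin <- function(d) findInterval(d, dist_breaks, all.inside = TRUE)
  key <- paste(.maf_bin(info$maf), dbin(info$tss_distance), sep = ":")
  names(key) <- info$id
  pool_by_bin <- split(pool, key[pool])
  qtl_bin <- key[qtl_variants]
  donor_bin <- qtl_bin
  empty <- !(qtl_bin %in% names(pool_by_bin))
  if (any(empty)) {
    warning(sum(empty), " QTL variant(s) with empty matching bin; nearest used")
    avail <- do.call(rbind, strsplit(names(pool_by_bin), ":"))
    av <- apply(avail, 2, as.numeric)
    if (is.null(dim(av))) av <- matrix(av, nrow = 1)
    for (i in which(empty)) {
      want <- as.numeric(strsplit(qtl_bin[i], ":")[[1]])
      dist <- abs(av[, 1] - want[1]) + abs(av[, 2] - want[2])
      donor_bin[i] <- names(pool_by_bin)[which.min(dist)]
    }
  }
  groups <- split(seq_along(qtl_variants), donor_bin)
  q_counts <- colSums(membership[qtl_variants, , drop = FALSE])
  scores <- matrix(NA_real_, B, length(annotations),
                   dimnames = list(NULL, names(annotations)))
  for (b in seq_len(B)) {
    picked <- character(length(qtl_variants))
    for (g in names(groups)) {
      cand <- pool_by_bin[[g]]
      idx <- groups[[g]]
      if (length(cand) >= length(idx)) picked[idx] <- sample(cand, length(idx))
      else picked[idx] <- sample(cand, length(idx), replace = TRUE)
    }
    b_counts <- colSums(membership[picked, , drop = FALSE])
    scores[b, ] <- log((q_counts + 1) / (b_counts + 1))
  }
  never <- q_counts == 0 & colSums(abs(scores)) == 0 &
    colSums(membership[pool, , drop = FALSE]) == 0
  pvals <- apply(scores, 2, function(s) {
    lo <- (1 + sum(s <= 0)) / (B + 1)
    hi <- (1 + sum(s >= 0)) / (B + 1)
    min(1, 2 * min(lo, hi))
  })
  pvals[never] <- NA_real_
  list(scores = scores, mean_score = colMeans(scores), p = pvals)
}
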