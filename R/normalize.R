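#' Feature-filtering thresholds
#'
#' Defaults follow whole-blood QTL practice: genes need more than
#' `expr_min_reads` reads in at least `expr_min_individuals` individuals and
#' mean TPM strictly above `expr_min_mean_tpm`; introns may have at most
#' `intron_max_zero_individuals` zero-read individuals, and their cluster
#' must reach `cluster_min_reads` reads in at least `cluster_min_individuals`
#' individuals with strictly fewer than `cluster_max_zero_individuals`
#' zero-read individuals.
#'
#' @param expr_min_reads strict read threshold per individual (default 5).
#' @param expr_min_individuals individuals required above it (default 20).
#' @param expr_min_mean_tpm strict mean-TPM threshold (default 0.1).
#' @param intron_max_zero_individuals inclusive bound (default 5).
#' @param cluster_min_reads inclusive per-individual cluster reads (default 20).
#' @param cluster_min_individuals inclusive individual count (default 100).
#' @param cluster_max_zero_individuals strict bound (default 10).
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(expr_min_reads = 5, expr_min_individuals = 20,
                              expr_min_mean_tpm = 0.1,
                              intron_max_zero_individuals = 5,
                              cluster_min_reads = 20,
                              cluster_min_individuals = 100,
                              cluster_max_zero_individuals = 10) {
  th <- as.list(environment())
  if (any(unlist(th) < 0)) stop("thresholds must be non-negative")
  structure(th, class = "filter_thresholds")
}

#' Filter expression features
#'
#' Keeps a gene iff it has reads strictly greater than `expr_min_reads` in at
#' least `expr_min_individuals` samples and mean TPM strictly greater than
#' `expr_min_mean_tpm`. An optional biotype vector restricts to lncRNA and
#' protein-coding genes.
#'
#' @param counts genes x samples read-count matrix.
#' @param tpm genes x samples TPM matrix with identical dimnames.
#' @param thresholds a [filter_thresholds].
#' @param biotype optional character vector per gene; when supplied only
#'   `"protein_coding"` and `"lncRNA"` genes are eligible.
#' @return character vector of kept feature ids.
#' @export
filter_expression_features <- function(counts, tpm,
                                       thresholds = filter_thresholds(),
                                       biotype = NULL) {
  if (!identical(dim(counts), dim(tpm)) ||
      !identical(rownames(counts), rownames(tpm))) {
    stop("counts and TPM matrices must share features and samples")
  }
  n_expr <- rowSums(counts > thresholds$expr_min_reads)
  keep <- n_expr >= thresholds$expr_min_individuals &
    rowMeans(tpm) > thresholds$expr_min_mean_tpm
  if (!is.null(biotype)) {
    keep <- keep & biotype %in% c("protein_coding", "lncRNA")
  }
  rownames(counts)[keep]
}

#' Filter splicing features
#'
#' Keeps an intron iff it has at most `intron_max_zero_individuals` samples
#' with zero reads, and its cluster has at least `cluster_min_reads` reads in
#' at least `cluster_min_individuals` samples and strictly fewer than
#' `cluster_max_zero_individuals` zero-read samples.
#'
#' @param junction_counts introns x samples read counts.
#' @param cluster_map character vector of cluster ids per intron.
#' @param thresholds a [filter_thresholds].
#' @return character vector of kept intron ids.
#' @export
filter_splicing_features <- function(junction_counts, cluster_map,
                                     thresholds = filter_thresholds()) {
  if (length(cluster_map) != nrow(junction_counts)) {
    stop("every intron needs a cluster id")
  }
  if (anyNA(cluster_map)) stop("intron without cluster")
  cl <- rowsum(junction_counts, cluster_map)
  cl_ok <- rowSums(cl >= thresholds$cluster_min_reads) >=
    thresholds$cluster_min_individuals &
    rowSums(cl == 0) < thresholds$cluster_max_zero_individuals
  intron_ok <- rowSums(junction_counts == 0) <=
    thresholds$intron_max_zero_individuals
  keep <- intron_ok & cl_ok[match(cluster_map, rownames(cl))]
  rownames(junction_counts)[keep]
}

# Map x onto target order statistics; ties share the average target value.
.qn_to_target <- function(x, target) {
  o <- order(x)
  xs <- x[o]
  grp <- cumsum(!duplicated(xs))
  out <- numeric(length(x))
  out[o] <- ave(target, grp)
  out
}

#' Two-stage quantile normalization
#'
#' Stage 1 maps each sample's value distribution onto the across-sample
#' average order statistics (ties share the average of their target values),
#' removing sample-level distributional differences. Stage 2 rank-transforms
#' each feature to the standard normal via `qnorm((rank - offset)/(n - 2*offset + 1))`
#' with average ranks for ties; the default offset 0.5 gives the grid
#' `(rank - 0.5)/n`, and `offset = 3/8` gives Blom scores. A feature constant
#' across samples maps to all zeros and is flagged in the returned object's
#' `constant_features` attribute.
#'
#' @param pm a [phenotype_matrix] (state `"raw"`); rows with any `NA` are
#'   normalized over their non-missing samples.
#' @param offset rank offset for stage 2.
#' @return A [phenotype_matrix] with state `"qn"`.
#' @export
two_stage_quantile_normalize <- function(pm, offset = 0.5) {
  x <- pm$values
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 features and >= 2 samples")
  # stage 1: quantile-normalize samples to the mean distribution
  complete <- !apply(x, 1, anyNA)
  if (any(complete)) {
    xc <- x[complete, , drop = FALSE]
    target <- rowMeans(apply(xc, 2, sort))
    for (j in seq_len(ncol(x))) {
      x[complete, j] <- .qn_to_target(xc[, j], target)
    }
  }
  # stage 2: rank-based inverse normal transform per feature
  n_all <- ncol(x)
  out <- x
  const <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    ok <- !is.na(x[i, ])
    v <- x[i, ok]
    n <- length(v)
    if (n == 0 || length(unique(v)) == 1) {
      out[i, ok] <- 0
      const[i] <- TRUE
      next
    }
    r <- rank(v, ties.method = "average")
    out[i, ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  }
  res <- phenotype_matrix(out, pm$features, "qn")
  attr(res, "constant_features") <- pm$features$id[const]
  res
}

#' Infer hidden factors by principal components
#'
#' Latent covariates standing in for hidden technical and cell-composition
#' variation: the top-k sample scores of the feature-centered phenotype
#' matrix, ordered by variance explained, with a deterministic sign
#' convention (the largest-magnitude feature loading of each component is
#' made positive).
#'
#' @param pm a quantile-normalized [phenotype_matrix].
#' @param k number of factors, `0 < k < min(samples, features)`.
#' @return A [covariate_matrix] with columns `Factor1..Factork`.
#' @export
infer_hidden_factors <- function(pm, k) {
  if (k <= 0) stop("k must be positive")
  x <- pm$values
  x <- x[!apply(x, 1, anyNA), , drop = FALSE]
  if (k >= min(dim(x))) stop("k must be < min(samples, features)")
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(pc$rotation[which.max(abs(pc$rotation[, j])), j])
    if (s < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- sprintf("Factor%d", seq_len(k))
  rownames(scores) <- colnames(pm$values)
  covariate_matrix(scores, validate = FALSE)
}

#' Select the hidden-factor count maximizing discoveries
#'
#' Re-runs the cis scan and hierarchical FDR for each candidate number of
#' hidden factors and returns the count yielding the most FDR-significant
#' features (ties broken toward the smallest k). Standard grids are
#' `c(0:5, 10, 15, 20, 25, 30)` for expression and `0:10` for splicing.
#'
#' @param genotypes a [genotype_dataset].
#' @param pm a quantile-normalized [phenotype_matrix].
#' @param base_covariates [covariate_matrix] of known covariates (or NULL).
#' @param grid integer vector of candidate factor counts.
#' @param alpha feature-level FDR (default 0.05).
#' @param ... passed to [cis_scan] (window, MAF, model, grm).
#' @return list with `k` (chosen count) and `discoveries` (named vector of
#'   significant-feature counts per grid value).
#' @export
select_factor_count <- function(genotypes, pm, base_covariates = NULL,
                                grid, alpha = 0.05, ...) {
  if (length(grid) == 0) stop("empty grid")
  grid <- sort(unique(as.integer(grid)))
  if (length(grid) == 1) {
    return(list(k = grid, discoveries = setNames(NA_integer_, grid)))
  }
  kmax <- max(grid)
  factors <- if (kmax > 0) infer_hidden_factors(pm, kmax) else NULL
  counts <- setNames(integer(length(grid)), grid)
  for (i in seq_along(grid)) {
    k <- grid[i]
    cov_k <- base_covariates$values
    if (k > 0) {
      cov_k <- cbind(cov_k, factors$values[, seq_len(k), drop = FALSE])
    }
    cv <- if (is.null(cov_k)) NULL else covariate_matrix(cov_k, validate = FALSE)
    rec <- cis_scan(genotypes, pm, cv, ...)
    fdr <- hierarchical_fdr(rec, alpha = alpha)
    counts[i] <- sum(fdr$features$significant)
  }
  list(k = grid[which.max(counts)], discoveries = counts)
}
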