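#' Genetic relatedness matrix
#'
#' GRM from all polymorphic biallelic variants: dosages are mean-imputed,
#' columns standardized to mean 0 and variance 1 (monomorphic variants
#' skipped), and `GRM = X Xt / M` over the M variants used, so the diagonal
#' averages 1.
#'
#' @param genotypes a [genotype_dataset].
#' @return samples x samples symmetric matrix.
#' @export
compute_grm <- function(genotypes) {
  x <- genotypes$dosage
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  # population-variance standardization keeps the diagonal mean exactly 1
  ss <- sqrt(colMeans(xc^2))
  use <- which(ss > 0)
  if (length(use) < 2) stop("need >= 2 polymorphic variants")
  xs <- sweep(xc[, use, drop = FALSE], 2, ss[use], "/")
  g <- tcrossprod(xs) / length(use)
  dimnames(g) <- list(genotypes$samples, genotypes$samples)
  g
}

# Full-rank design with intercept from an optional covariate matrix.
.design_matrix <- function(covariates, n) {
  C <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cv <- if (inherits(covariates, "covariate_matrix")) covariates$values else covariates
    C <- cbind(C, cv)
  }
  q <- qr(C)
  if (q$rank < ncol(C)) C <- C[, q$pivot[seq_len(q$rank)], drop = FALSE]
  C
}

# Mean-impute missing dosages; returns matrix plus indices of variants that
# are constant afterwards (to be skipped).
.impute_dosages <- function(x) {
  imputed <- FALSE
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      x[miss, j] <- mean(x[, j], na.rm = TRUE)
      imputed <- TRUE
    }
  }
  list(x = x, constant = which(apply(x, 2, function(v) max(v) == min(v))),
       imputed = imputed)
}

# Cis-window variant indices for one feature row (1-based positions;
# distance 0 inside an intron interval).
.cis_window_idx <- function(feature, variants, window_bp) {
  on_chrom <- variants$chrom == feature$chrom
  if (feature$kind == "gene") {
    which(on_chrom & abs(variants$pos - feature$tss) <= window_bp)
  } else {
    d <- pmax(0, pmax(feature$start - variants$pos,
                      variants$pos - feature$end))
    which(on_chrom & d <= window_bp)
  }
}

# REML estimate of the variance ratio delta = ve/vg for y ~ C under the
# eigendecomposed GRM (lambda = eigenvalues; inputs already rotated).
.reml_delta <- function(yt, Ct, lambda) {
  n <- length(yt); p <- ncol(Ct)
  neg_loglik <- function(log_delta) {
    w <- 1 / (lambda + exp(log_delta))
    Cw <- Ct * sqrt(w); yw <- yt * sqrt(w)
    fit <- qr(Cw)
    rss <- sum(qr.resid(fit, yw)^2)
    R <- qr.R(fit)
    (n - p) * log(rss) + sum(log(lambda + exp(log_delta))) +
      2 * sum(log(abs(diag(R))))
  }
  opt <- optimize(neg_loglik, c(-10, 10))
  exp(opt$minimum)
}

#' Cis-window association scan
#'
#' Tests every variant with pooled MAF strictly above `maf_min` lying within
#' `window_bp` of each feature (gene TSS, or intron interval with distance 0
#' inside) against the feature's phenotype, adjusting for covariates.
#' `model = "ols"` regresses phenotype on dosage plus covariates and reports
#' a two-sided t test on the dosage coefficient. `model = "lmm"` fits a
#' single-variance-component mixed model via eigendecomposition of the GRM:
#' the variance ratio is estimated once per feature by REML on the
#' covariates-only model, then each variant is tested by generalized least
#' squares. Missing dosages are mean-imputed inside the scan; variants
#' constant after imputation are skipped, and features with empty windows are
#' skipped with a message.
#'
#' @param genotypes a [genotype_dataset].
#' @param phenotypes a [phenotype_matrix] with samples in genotype order.
#' @param covariates optional [covariate_matrix].
#' @param window_bp cis window half-width (default 100000).
#' @param maf_min pooled MAF threshold, strict (default 0.05).
#' @param model `"ols"` or `"lmm"`.
#' @param grm GRM matrix for `model = "lmm"` (see [compute_grm]).
#' @return data.frame of association records: feature_id, variant_id, chrom,
#'   pos, ref, alt, maf, beta, se, p.
#' @export
cis_scan <- function(genotypes, phenotypes, covariates = NULL,
                     window_bp = 100000, maf_min = 0.05,
                     model = c("ols", "lmm"), grm = NULL) {
  model <- match.arg(model)
  if (window_bp <= 0 || maf_min < 0) stop("window and MAF thresholds invalid")
  y_all <- phenotypes$values
  if (ncol(y_all) != nrow(genotypes$dosage)) {
    stop("phenotype samples do not match genotype samples")
  }
  n <- nrow(genotypes$dosage)
  v <- genotypes$variants
  cand <- which(v$maf > maf_min & !is.na(v$maf))
  imp <- .impute_dosages(genotypes$dosage[, cand, drop = FALSE])
  if (length(imp$constant)) cand_keep <- setdiff(seq_along(cand), imp$constant)
  else cand_keep <- seq_along(cand)
  X <- imp$x[, cand_keep, drop = FALSE]
  cand <- cand[cand_keep]
  vc <- v[cand, , drop = FALSE]
  C <- .design_matrix(covariates, n)
  p_cov <- ncol(C)
  if (model == "lmm") {
    if (is.null(grm)) stop("model = 'lmm' requires a GRM")
    eg <- eigen(grm, symmetric = TRUE)
    U <- eg$vectors
    lambda <- pmax(eg$values, 0)
    Xt_all <- crossprod(U, X)
    Ct <- crossprod(U, C)
  } else {
    qrC <- qr(C)
    Xr_all <- qr.resid(qrC, X)
  }
  out <- vector("list", nrow(y_all))
  feats <- phenotypes$features
  for (i in seq_len(nrow(y_all))) {
    widx_variant <- .cis_window_idx(feats[i, ], vc, window_bp)
    if (length(widx_variant) == 0) {
      message("feature ", feats$id[i], " has no testable cis variants; skipped")
      next
    }
    y <- y_all[i, ]
    ok <- !is.na(y)
    if (sum(ok) < p_cov + 2) next
    if (model == "ols") {
      if (all(ok)) {
        yr <- qr.resid(qrC, y)
        Xr <- Xr_all[, widx_variant, drop = FALSE]
        df <- n - p_cov - 1
      } else {
        qrC_ok <- qr(C[ok, , drop = FALSE])
        yr <- qr.resid(qrC_ok, y[ok])
        Xr <- qr.resid(qrC_ok, X[ok, widx_variant, drop = FALSE])
        df <- sum(ok) - p_cov - 1
      }
      sxx <- colSums(Xr^2)
      sxy <- as.vector(crossprod(Xr, yr))
      beta <- sxy / sxx
      rss <- sum(yr^2) - beta^2 * sxx
      se <- sqrt(pmax(rss, 0) / df / sxx)
    } else {
      yt <- as.vector(crossprod(U, ifelse(ok, y, mean(y, na.rm = TRUE))))
      delta <- .reml_delta(yt, Ct, lambda)
      w <- 1 / (lambda + delta)
      sw <- sqrt(w)
      Cw <- Ct * sw
      qrCw <- qr(Cw)
      yr <- qr.resid(qrCw, yt * sw)
      Xr <- qr.resid(qrCw, Xt_all[, widx_variant, drop = FALSE] * sw)
      df <- n - p_cov - 1
      sxx <- colSums(Xr^2)
      sxy <- as.vector(crossprod(Xr, yr))
      beta <- sxy / sxx
      rss <- sum(yr^2) - beta^2 * sxx
      se <- sqrt(pmax(rss, 0) / df / sxx)
    }
    tval <- beta / se
    out[[i]] <- data.frame(
      feature_id = feats$id[i],
      variant_id = vc$id[widx_variant],
      chrom = vc$chrom[widx_variant], pos = vc$pos[widx_variant],
      ref = vc$ref[widx_variant], alt = vc$alt[widx_variant],
      maf = vc$maf[widx_variant],
      beta = beta, se = se, p = 2 * pt(-abs(tval), df),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Hierarchical Benjamini-Hochberg FDR
#'
#' Two-level FDR control: raw p-values are BH-adjusted within each feature
#' (single-corrected `P_prime`); the minimum `P_prime` per feature is
#' BH-adjusted across features (double-corrected `P_double_prime`). Features
#' with `P_double_prime < alpha` are significant. The SNP-level threshold is
#' the minimum `P_prime` of the significant feature with the largest
#' `P_double_prime`; variants of significant features with
#' `P_prime <= threshold` are flagged significant.
#'
#' @param records association records from [cis_scan].
#' @param alpha feature-level FDR (default 0.05).
#' @return list with `records` (input plus `P_prime`, `significant`),
#'   `features` (feature_id, min_P_prime, P_double_prime, significant,
#'   snp_threshold), and `snp_threshold`.
#' @export
hierarchical_fdr <- function(records, alpha = 0.05) {
  if (is.null(records) || nrow(records) == 0) stop("no association records")
  fid <- factor(records$feature_id, levels = unique(records$feature_id))
  records$P_prime <- ave(records$p, fid,
                         FUN = function(x) p.adjust(x, method = "BH"))
  min_pp <- tapply(records$P_prime, fid, min)
  features <- data.frame(feature_id = names(min_pp),
                         min_P_prime = as.vector(min_pp),
                         stringsAsFactors = FALSE)
  features$P_double_prime <- p.adjust(features$min_P_prime, method = "BH")
  features$significant <- features$P_double_prime < alpha
  if (any(features$significant)) {
    sig <- features[features$significant, ]
    threshold <- sig$min_P_prime[which.max(sig$P_double_prime)]
  } else {
    threshold <- NA_real_
  }
  features$snp_threshold <- threshold
  sig_features <- features$feature_id[features$significant]
  records$significant <- !is.na(threshold) &
    records$feature_id %in% sig_features &
    records$P_prime <= threshold
  list(records = records, features = features, snp_threshold = threshold)
}

#' Conditional independence scan
#'
#' Residualizes each feature's normalized phenotype on the dosages of its
#' conditioning variants (plus covariates), re-runs the cis scan on the
#' residuals, and flags the feature as carrying an independent signal iff
#' any variant's within-feature BH-adjusted p-value still passes the
#' original SNP threshold.
#'
#' @param genotypes a [genotype_dataset].
#' @param phenotypes a [phenotype_matrix].
#' @param covariates optional [covariate_matrix].
#' @param conditioning data.frame (`feature_id`, `variant_id`) or named list
#'   of variant-id vectors; variants absent from the genotypes are dropped
#'   with a warning, as are variants collinear with the covariates.
#' @param original_threshold SNP threshold from the unconditioned
#'   [hierarchical_fdr].
#' @param ... passed to [cis_scan].
#' @return list with `flags` (feature_id, independent) and `records`
#'   (conditional scan records with `P_prime`).
#' @export
conditional_scan <- function(genotypes, phenotypes, covariates = NULL,
                             conditioning, original_threshold, ...) {
  if (is.data.frame(conditioning)) {
    conditioning <- split(conditioning$variant_id, conditioning$feature_id)
  }
  absent <- setdiff(unlist(conditioning), genotypes$variants$id)
  if (length(absent)) {
    warning("conditioning variant(s) absent from genotypes dropped: ",
            paste(absent, collapse = ", "))
    conditioning <- lapply(conditioning, setdiff, y = absent)
  }
  y_all <- phenotypes$values
  n <- ncol(y_all)
  C <- .design_matrix(covariates, n)
  for (fid in names(conditioning)) {
    vids <- conditioning[[fid]]
    if (length(vids) == 0 || !(fid %in% rownames(y_all))) next
    G <- genotypes$dosage[, vids, drop = FALSE]
    G <- .impute_dosages(G)$x
    D <- cbind(C, G)
    qD <- qr(D)
    if (qD$rank < ncol(D)) {
      warning("collinear conditioning dosage(s) dropped for ", fid)
    }
    y <- y_all[fid, ]
    ok <- !is.na(y)
    y_all[fid, ok] <- qr.resid(qr(D[ok, qD$pivot[seq_len(qD$rank)],
                                    drop = FALSE]), y[ok])
  }
  pm_res <- phenotype_matrix(y_all, phenotypes$features, phenotypes$state)
  rec <- cis_scan(genotypes, pm_res, covariates, ...)
  fid <- factor(rec$feature_id, levels = unique(rec$feature_id))
  rec$P_prime <- ave(rec$p, fid, FUN = function(x) p.adjust(x, "BH"))
  ind <- tapply(rec$P_prime <= original_threshold, fid, any)
  list(flags = data.frame(feature_id = names(ind),
                          independent = as.vector(ind),
                          stringsAsFactors = FALSE),
       records = rec)
}
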