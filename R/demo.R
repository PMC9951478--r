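#' Run the full pipeline end-to-end on synthetic data
#'
#' Simulates a multi-population cohort with known truth, then runs every
#' stage: feature filtering (on pseudo-counts derived from the simulated
#' phenotypes), two-stage quantile normalization, hidden-factor inference,
#' cis scan, hierarchical FDR, fine-mapping into 90% credible sets,
#' selection scans (weighted FST with locus permutations, polarized d and
#' PBS with the first population focal and the last two as references), and
#' a split-sample replication analysis (discovery on half the cohort,
#' replication p-values and pi1 plus effect-size concordance on the other
#' half). Fully deterministic under a fixed seed.
#'
#' @param seed integer seed driving all randomness.
#' @param n_genes number of simulated genes (default 120).
#' @param samples_per_pop individuals per population (default 54; 3
#'   populations gives a 162-sample cohort).
#' @param frac_causal fraction of causal genes (default 0.4).
#' @param n_factors hidden factors included in the scan covariates.
#' @param B permutations for the selection scan (default 500; raise for
#'   production use).
#' @param model association model, `"ols"` (default) or `"lmm"`.
#' @return list with the simulation inputs, scan results, FDR tables,
#'   credible sets, selection scores, replication statistics, and a
#'   `summary` list of headline numbers.
#' @export
run_demo <- function(seed = 1, n_genes = 120, samples_per_pop = 54,
                     frac_causal = 0.4, n_factors = 2, B = 500,
                     model = "ols") {
  cfg <- sim_config(n_pops = 3, samples_per_pop = samples_per_pop,
                    n_variants = 2000, n_genes = n_genes,
                    fst_targets = c(0.05, 0.05, 0.15),
                    effect_size_sd = 1, frac_causal = frac_causal,
                    seed = seed)
  sim <- simulate_genotypes(cfg)
  gt <- sim$genotypes
  cov <- simulate_covariates(gt, cfg)
  expr <- simulate_expression_phenotypes(gt, cfg, covariates = cov,
                                         pop_freqs = sim$pop_freqs)
  # pseudo-counts on a TPM-like scale to exercise the expression filters
  tpm <- 2^expr$phenotypes$values
  counts <- round(tpm * 30)
  dimnames(counts) <- dimnames(tpm)
  kept <- filter_expression_features(counts, tpm,
                                     filter_thresholds(expr_min_individuals =
                                                         min(20, samples_per_pop)))
  keep_idx <- expr$phenotypes$features$id %in% kept
  pm_raw <- phenotype_matrix(expr$phenotypes$values[keep_idx, , drop = FALSE],
                             expr$phenotypes$features[keep_idx, , drop = FALSE])
  pm_qn <- two_stage_quantile_normalize(pm_raw)
  factors <- if (n_factors > 0) infer_hidden_factors(pm_qn, n_factors) else NULL
  cov_all <- if (is.null(factors)) cov else
    covariate_matrix(cbind(cov$values, factors$values), validate = FALSE)
  grm <- if (model == "lmm") compute_grm(gt) else NULL

  rec <- cis_scan(gt, pm_qn, cov_all, model = model, grm = grm)
  fdr <- hierarchical_fdr(rec, alpha = 0.05)
  sig_features <- fdr$features$feature_id[fdr$features$significant]
  fm <- finemap_features(rec, feature_ids = sig_features)

  # selection: FST between the drifted population (POP3) and the others
  freqs <- population_allele_frequencies(gt)
  fst_sum <- pairwise_fst_summary(freqs)
  snp_fst <- hudson_fst(freqs$p[, "POP1"], freqs$n[, "POP1"],
                        freqs$p[, "POP3"], freqs$n[, "POP3"])$fst
  names(snp_fst) <- gt$variants$id
  snp_d <- polarized_d(freqs, fst_sum, focal_pop = "POP3")
  snp_pbs <- pbs(fst_sum$fst[, "POP1|POP3"], fst_sum$fst[, "POP2|POP3"],
                 fst_sum$fst[, "POP1|POP2"])
  names(snp_d) <- names(snp_pbs) <- gt$variants$id
  sel <- do.call(rbind, lapply(sig_features, function(f) {
    pr <- fm$posteriors[fm$posteriors$feature_id == f, ]
    perm <- locus_permutation_test(pr$PP, snp_fst[pr$variant_id], B = B)
    data.frame(feature_id = f,
               weighted_fst = weighted_locus_score(pr$PP, snp_fst[pr$variant_id]),
               weighted_d = weighted_locus_score(pr$PP, snp_d[pr$variant_id]),
               weighted_pbs = weighted_locus_score(pr$PP, snp_pbs[pr$variant_id]),
               empirical_p = perm$p, stringsAsFactors = FALSE)
  }))
  if (!is.null(sel) && nrow(sel)) {
    sel$candidate_global <- call_candidates_global(sel$weighted_fst,
                                                   sel$empirical_p, snp_fst)
    sel$candidate_pop <- call_candidates_population(sel$weighted_d,
                                                    sel$weighted_pbs,
                                                    snp_d, snp_pbs)
  }

  # split-sample replication: discovery on half A, replication on half B
  set.seed(seed + 10L)
  half_a <- as.vector(vapply(split(seq_along(gt$populations), gt$populations),
                             function(i) sample(i, length(i) %/% 2),
                             integer(samples_per_pop %/% 2)))
  half_b <- setdiff(seq_along(gt$populations), half_a)
  subset_gt <- function(idx) {
    genotype_dataset(gt$dosage[idx, , drop = FALSE], gt$variants[, 1:5],
                     gt$populations[idx])
  }
  subset_pm <- function(idx) {
    phenotype_matrix(pm_qn$values[, idx, drop = FALSE], pm_qn$features, "qn")
  }
  subset_cov <- function(idx) {
    covariate_matrix(cov_all$values[idx, , drop = FALSE], validate = FALSE)
  }
  rec_a <- cis_scan(subset_gt(half_a), subset_pm(half_a), subset_cov(half_a))
  fdr_a <- hierarchical_fdr(rec_a)
  sig_a <- fdr_a$records[fdr_a$records$significant, ]
  rec_b <- cis_scan(subset_gt(half_b), subset_pm(half_b), subset_cov(half_b))
  key_b <- paste(rec_b$feature_id, rec_b$variant_id)
  rep_p <- rec_b$p[match(paste(sig_a$feature_id, sig_a$variant_id), key_b)]
  pi1 <- if (sum(!is.na(rep_p)) >= 10) {
    suppressWarnings(estimate_pi1(rep_p[!is.na(rep_p)]))
  } else NULL
  conc <- if (nrow(sig_a) >= 3) effect_size_concordance(sig_a, rec_b) else NULL

  truth <- expr$truth[expr$truth$feature_id %in% pm_qn$features$id, ]
  tab <- table(causal = factor(truth$causal, levels = c(FALSE, TRUE)),
               significant = factor(truth$feature_id %in% sig_features,
                                    levels = c(FALSE, TRUE)))
  fisher <- fisher.test(tab)
  list(config = cfg, genotypes = gt, phenotypes = pm_qn, covariates = cov_all,
       truth = expr$truth, records = rec, fdr = fdr, finemap = fm,
       selection = sel, snp_fst = snp_fst, snp_d = snp_d, snp_pbs = snp_pbs,
       replication = list(pi1 = pi1, concordance = conc,
                          replication_p = rep_p),
       summary = list(
         n_features_tested = length(unique(rec$feature_id)),
         n_significant_features = length(sig_features),
         snp_threshold = fdr$snp_threshold,
         n_candidates_global = if (is.null(sel)) 0L else sum(sel$candidate_global),
         truth_enrichment_or = unname(fisher$estimate),
         pi1_split_replication = if (is.null(pi1)) NA_real_ else pi1$pi1))
}
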