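#' Simulation configuration
#'
#' Defines the structure of a synthetic multi-population cohort: population
#' count and sizes, Balding-Nichols drift targets, variant density, gene and
#' intron-cluster counts, cis-effect distribution, and nuisance covariates.
#' The defaults emulate a whole-blood cohort of 162 individuals drawn from
#' several differentiated populations, with variants spaced evenly on one
#' synthetic chromosome so every 100 kb cis window holds a predictable number
#' of variants.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop diploid individuals per population (>= 2).
#' @param n_variants biallelic variants on the synthetic chromosome.
#' @param n_genes genes with a TSS on the chromosome.
#' @param n_clusters intron clusters.
#' @param introns_per_cluster junctions per cluster (>= 2).
#' @param fst_targets per-population Balding-Nichols drift parameter F in
#'   \[0, 1); scalar recycled to `n_pops`.
#' @param ancestral_freq_range interval within (0, 1) for ancestral allele
#'   frequencies; the default (0.05, 0.95) limits monomorphic draws.
#' @param variant_spacing_bp distance between adjacent variants.
#' @param cis_window_bp cis window half-width in bp.
#' @param effect_size_sd SD of true per-allele effects on the normalized
#'   phenotype scale for causal features.
#' @param frac_causal fraction of features given one causal cis variant.
#' @param noise_sd residual SD of phenotypes.
#' @param n_latent_factors latent confounding factors in the covariates.
#' @param covariate_effect_sd SD of covariate loadings on phenotypes.
#' @param cluster_read_mean Poisson mean of per-sample intron-cluster totals.
#' @param overdispersion Dirichlet-multinomial overdispersion for junction
#'   counts; 0 (default) = plain multinomial, larger values concentrate less.
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pops = 3, samples_per_pop = 54, n_variants = 2000,
                       n_genes = 200, n_clusters = 40, introns_per_cluster = 3,
                       fst_targets = 0.02,
                       ancestral_freq_range = c(0.05, 0.95),
                       variant_spacing_bp = 1000L, cis_window_bp = 100000L,
                       effect_size_sd = 0.8, frac_causal = 0.3, noise_sd = 1,
                       n_latent_factors = 2, covariate_effect_sd = 0.5,
                       cluster_read_mean = 50, overdispersion = 0, seed = 1L) {
  fst_targets <- rep_len(fst_targets, n_pops)
  cfg <- list(n_pops = as.integer(n_pops),
              samples_per_pop = as.integer(samples_per_pop),
              n_variants = as.integer(n_variants),
              n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              introns_per_cluster = as.integer(introns_per_cluster),
              fst_targets = fst_targets,
              ancestral_freq_range = ancestral_freq_range,
              variant_spacing_bp = as.integer(variant_spacing_bp),
              cis_window_bp = as.integer(cis_window_bp),
              effect_size_sd = effect_size_sd, frac_causal = frac_causal,
              noise_sd = noise_sd,
              n_latent_factors = as.integer(n_latent_factors),
              covariate_effect_sd = covariate_effect_sd,
              cluster_read_mean = cluster_read_mean,
              overdispersion = overdispersion,
              seed = as.integer(seed))
  counts <- c(cfg$n_pops, cfg$samples_per_pop, cfg$n_variants, cfg$n_genes,
              cfg$n_clusters, cfg$introns_per_cluster, cfg$variant_spacing_bp,
              cfg$cis_window_bp)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (cfg$samples_per_pop < 2) {
    stop("samples_per_pop must be >= 2 (frequency estimation impossible)")
  }
  if (any(fst_targets < 0 | fst_targets >= 1)) {
    stop("fst_targets must lie in [0, 1); F = 1 is rejected")
  }
  if (cfg$introns_per_cluster < 2) stop("clusters need >= 2 junctions")
  if (frac_causal < 0 || frac_causal > 1) stop("frac_causal must be in [0, 1]")
  r <- ancestral_freq_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] >= r[2]) {
    stop("ancestral_freq_range must be an interval within (0, 1)")
  }
  structure(cfg, class = "sim_config")
}

#' Load a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [sim_config] arguments.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Simulate multi-population genotypes under the Balding-Nichols model
#'
#' Ancestral frequencies are drawn uniformly on `ancestral_freq_range`; each
#' population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral p (equal to p when F = 0), and diploid dosages are binomial
#' draws. Variants occupy evenly spaced 1-based positions on one synthetic
#' chromosome, so the expected pairwise Hudson FST between two populations
#' with drift F each is close to F.
#'
#' @param config a [sim_config].
#' @return list with `genotypes` (a [genotype_dataset]; variants monomorphic
#'   across all samples are flagged in `genotypes$variants$monomorphic`) and
#'   `pop_freqs` (true alt-allele frequency matrix, variants x populations).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_variants
  pops <- sprintf("POP%d", seq_len(config$n_pops))
  p_anc <- runif(m, config$ancestral_freq_range[1], config$ancestral_freq_range[2])
  pop_freqs <- matrix(NA_real_, m, config$n_pops,
                      dimnames = list(NULL, pops))
  for (k in seq_len(config$n_pops)) {
    f <- config$fst_targets[k]
    if (f == 0) {
      pop_freqs[, k] <- p_anc
    } else {
      pop_freqs[, k] <- rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
  }
  n <- config$n_pops * config$samples_per_pop
  dosage <- matrix(NA_real_, n, m)
  populations <- rep(pops, each = config$samples_per_pop)
  for (k in seq_len(config$n_pops)) {
    rows <- which(populations == pops[k])
    dosage[rows, ] <- matrix(
      rbinom(length(rows) * m, 2, rep(pop_freqs[, k], each = length(rows))),
      nrow = length(rows))
  }
  rownames(dosage) <- sprintf("%s_S%03d", populations,
                              rep(seq_len(config$samples_per_pop), config$n_pops))
  variants <- data.frame(
    chrom = "chr1",
    pos = config$variant_spacing_bp * seq_len(m),
    id = sprintf("var%05d", seq_len(m)),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  gt <- genotype_dataset(dosage, variants, populations)
  cm <- colMeans(gt$dosage, na.rm = TRUE)
  gt$variants$monomorphic <- cm == 0 | cm == 2
  list(genotypes = gt, pop_freqs = pop_freqs)
}

# Assign evenly spread feature anchor positions inside the variant span.
.anchor_positions <- function(config, n_features) {
  span <- config$variant_spacing_bp * config$n_variants
  as.integer(round(seq(config$cis_window_bp / 2,
                       span - config$cis_window_bp / 2,
                       length.out = n_features)))
}

# Draw causal assignments for features given their cis variant index lists.
.draw_truth <- function(ids, cis_lists, config) {
  n <- length(ids)
  causal <- runif(n) < config$frac_causal
  causal_variant <- rep(NA_character_, n)
  effect <- rep(0, n)
  for (i in which(causal)) {
    if (length(cis_lists[[i]]) == 0) {
      causal[i] <- FALSE  # empty cis window: feature flagged non-causal
      next
    }
    causal_variant[i] <- sample(cis_lists[[i]], 1)
    effect[i] <- rnorm(1, 0, config$effect_size_sd)
  }
  data.frame(feature_id = ids, causal = causal,
             causal_variant_id = causal_variant, true_effect = effect,
             stringsAsFactors = FALSE)
}

# Append per-population alt frequencies of each causal variant.
.truth_with_freqs <- function(truth, genotypes, pop_freqs) {
  idx <- match(truth$causal_variant_id, genotypes$variants$id)
  for (k in colnames(pop_freqs)) {
    truth[[paste0("freq_", k)]] <- ifelse(is.na(idx), NA_real_,
                                          pop_freqs[idx, k])
  }
  truth
}

#' Simulate cis-regulated expression phenotypes
#'
#' Each gene receives a TSS on the synthetic chromosome. A fraction
#' `frac_causal` of genes get one causal variant drawn uniformly from the
#' gene's cis window and an effect drawn N(0, `effect_size_sd`); the
#' phenotype is `effect * dosage + covariate loadings + N(0, noise_sd)` on
#' the normalized scale. Non-causal genes receive covariate contributions
#' and noise only.
#'
#' @param genotypes `genotypes` element of [simulate_genotypes] output.
#' @param config the same [sim_config].
#' @param covariates optional [covariate_matrix] from [simulate_covariates];
#'   when supplied, every column loads on every gene with weights drawn
#'   N(0, `covariate_effect_sd`).
#' @param pop_freqs optional true frequency matrix, recorded in the truth.
#' @return list with `phenotypes` (a [phenotype_matrix], state `"raw"`) and
#'   `truth` (feature_id, causal flag, causal_variant_id, true_effect,
#'   per-population causal-variant frequencies).
#' @export
simulate_expression_phenotypes <- function(genotypes, config,
                                           covariates = NULL,
                                           pop_freqs = NULL) {
  stopifnot(inherits(genotypes, "genotype_dataset"))
  set.seed(config$seed + 1L)
  n <- nrow(genotypes$dosage)
  ng <- config$n_genes
  tss <- .anchor_positions(config, ng)
  ids <- sprintf("GENE%04d", seq_len(ng))
  pos <- genotypes$variants$pos
  cis_lists <- lapply(tss, function(t) {
    genotypes$variants$id[abs(pos - t) <= config$cis_window_bp]
  })
  truth <- .draw_truth(ids, cis_lists, config)
  vals <- matrix(rnorm(ng * n, 0, config$noise_sd), ng, n,
                 dimnames = list(ids, genotypes$samples))
  if (!is.null(covariates)) {
    C <- covariates$values
    # latent factors load with the configured SD; the measured sex/age
    # analogues get modest fixed loadings
    load_sd <- ifelse(colnames(C) %in% c("sex", "age"), 0.3,
                      config$covariate_effect_sd)
    load <- matrix(rnorm(ng * ncol(C)), ng, ncol(C))
    load <- sweep(load, 2, load_sd, "*")
    vals <- vals + load %*% t(C)
  }
  ci <- which(truth$causal)
  if (length(ci)) {
    dos <- genotypes$dosage[, truth$causal_variant_id[ci], drop = FALSE]
    vals[ci, ] <- vals[ci, , drop = FALSE] +
      truth$true_effect[ci] * t(dos)
  }
  features <- data.frame(id = ids, kind = "gene", chrom = "chr1", tss = tss,
                         start = NA_integer_, end = NA_integer_,
                         cluster = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(pop_freqs)) truth <- .truth_with_freqs(truth, genotypes, pop_freqs)
  list(phenotypes = phenotype_matrix(vals, features, "raw"), truth = truth)
}

#' Simulate intron-junction splicing phenotypes
#'
#' Introns are grouped into clusters sharing a genomic anchor. Per sample and
#' cluster, a Poisson total read count is split multinomially across
#' junctions with cluster-specific baseline proportions. For a causal
#' cluster, the logit of one junction's proportion is shifted by
#' `true_effect * dosage` of a cis variant; the remaining junctions are
#' rescaled so proportions stay on the simplex. The phenotype is the
#' junction proportion per cluster (JPC = junction count / cluster total).
#'
#' @inheritParams simulate_expression_phenotypes
#' @return list with `phenotypes` (JPC values; `NA` where the cluster total
#'   is 0), `truth`, `junction_counts` (features x samples integer matrix),
#'   and `cluster_totals` (clusters x samples).
#' @export
simulate_splicing_phenotypes <- function(genotypes, config, covariates = NULL,
                                         pop_freqs = NULL) {
  stopifnot(inherits(genotypes, "genotype_dataset"))
  set.seed(config$seed + 2L)
  n <- nrow(genotypes$dosage)
  nc <- config$n_clusters
  k <- config$introns_per_cluster
  anchors <- .anchor_positions(config, nc)
  pos <- genotypes$variants$pos
  intron_ids <- as.vector(t(outer(seq_len(nc), seq_len(k), function(c, j)
    sprintf("clu%d:intron%d", c, j))))
  # causal status drawn per cluster; the affected junction is the first
  cluster_cis <- lapply(anchors, function(a) {
    genotypes$variants$id[abs(pos - a) <= config$cis_window_bp]
  })
  cl_truth <- .draw_truth(sprintf("clu%d", seq_len(nc)), cluster_cis, config)
  base_prop <- matrix(rgamma(nc * k, shape = 2), nc, k)
  base_prop <- base_prop / rowSums(base_prop)
  counts <- matrix(0L, nc * k, n,
                   dimnames = list(intron_ids, genotypes$samples))
  totals <- matrix(rpois(nc * n, config$cluster_read_mean), nc, n,
                   dimnames = list(sprintf("clu%d", seq_len(nc)),
                                   genotypes$samples))
  for (c in seq_len(nc)) {
    q0 <- base_prop[c, ]
    shift <- rep(0, n)
    if (cl_truth$causal[c]) {
      d <- genotypes$dosage[, cl_truth$causal_variant_id[c]]
      shift <- cl_truth$true_effect[c] * d
    }
    q_focal <- plogis(qlogis(q0[1]) + shift)
    for (s in seq_len(n)) {
      q <- c(q_focal[s], q0[-1] * (1 - q_focal[s]) / (1 - q0[1]))
      if (config$overdispersion > 0) {
        g <- rgamma(k, shape = q / config$overdispersion)
        q <- g / sum(g)
      }
      if (totals[c, s] > 0) {
        counts[(c - 1) * k + seq_len(k), s] <- rmultinom(1, totals[c, s], q)
      }
    }
  }
  jpc <- sweep(counts, 2, rep(1, n), "*")
  for (c in seq_len(nc)) {
    rows <- (c - 1) * k + seq_len(k)
    tot <- totals[c, ]
    jpc[rows, ] <- sweep(counts[rows, , drop = FALSE], 2,
                         ifelse(tot == 0, NA_real_, tot), "/")
  }
  width <- max(50L, config$variant_spacing_bp)
  features <- data.frame(
    id = intron_ids, kind = "intron", chrom = "chr1", tss = NA_integer_,
    start = rep(anchors, each = k) + width * (rep(seq_len(k), nc) - 1L),
    end = rep(anchors, each = k) + width * rep(seq_len(k), nc) - 1L,
    cluster = rep(sprintf("clu%d", seq_len(nc)), each = k),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    feature_id = intron_ids,
    causal = rep(cl_truth$causal, each = k) & rep(seq_len(k), nc) == 1,
    causal_variant_id = ifelse(rep(seq_len(k), nc) == 1,
                               rep(cl_truth$causal_variant_id, each = k),
                               NA_character_),
    true_effect = ifelse(rep(seq_len(k), nc) == 1,
                         rep(cl_truth$true_effect, each = k), 0),
    stringsAsFactors = FALSE)
  truth$causal_variant_id[!truth$causal] <- NA_character_
  truth$true_effect[!truth$causal] <- 0
  if (!is.null(pop_freqs)) truth <- .truth_with_freqs(truth, genotypes, pop_freqs)
  list(phenotypes = phenotype_matrix(jpc, features, "raw"), truth = truth,
       junction_counts = counts, cluster_totals = totals)
}

#' Simulate nuisance covariates
#'
#' One binary covariate (sex analogue), one continuous covariate (age
#' analogue, standardized), and `n_latent_factors` standard-normal latent
#' factors that stand in for hidden technical/cell-composition variation.
#'
#' @param genotypes `genotypes` element of [simulate_genotypes] output
#'   (provides the sample roster).
#' @param config a [sim_config].
#' @return A [covariate_matrix] with rownames = sample ids.
#' @export
simulate_covariates <- function(genotypes, config) {
  set.seed(config$seed + 3L)
  n <- nrow(genotypes$dosage)
  k <- config$n_latent_factors
  m <- cbind(sex = rbinom(n, 1, 0.5),
             age = as.numeric(scale(runif(n, 20, 70))))
  if (k > 0) {
    lat <- matrix(rnorm(n * k), n, k,
                  dimnames = list(NULL, sprintf("latent%d", seq_len(k))))
    m <- cbind(m, lat)
  }
  rownames(m) <- genotypes$samples
  covariate_matrix(m)
}

#' Write a simulated dataset to disk
#'
#' Writes genotypes as VCF v4.2 (GT field, hard calls), phenotypes as
#' BED-like files (0-based half-open intervals, header naming samples in
#' genotype order), covariates and truth as TSV, plus a sample-population
#' map. Files round-trip exactly through the package readers.
#'
#' @param genotypes a [genotype_dataset] (integer dosages).
#' @param phenotypes a [phenotype_matrix] or named list of them.
#' @param covariates a [covariate_matrix] or NULL.
#' @param truth truth data.frame(s) or NULL.
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_dataset <- function(genotypes, phenotypes, covariates = NULL,
                          truth = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"))
  .write_vcf(genotypes, paths[["vcf"]])
  if (inherits(phenotypes, "phenotype_matrix")) {
    phenotypes <- list(phenotypes = phenotypes)
  }
  for (nm in names(phenotypes)) {
    p <- file.path(out_dir, paste0(nm, ".bed"))
    .write_phenotype_bed(phenotypes[[nm]], p)
    paths[[paste0("bed_", nm)]] <- p
  }
  if (!is.null(covariates)) {
    p <- file.path(out_dir, "covariates.tsv")
    df <- data.frame(sample = rownames(covariates$values),
                     covariates$values, check.names = FALSE)
    write_table_tsv(df, p)
    paths[["covariates"]] <- p
  }
  if (!is.null(truth)) {
    if (is.data.frame(truth)) truth <- list(truth = truth)
    for (nm in names(truth)) {
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      write_table_tsv(truth[[nm]], p)
      paths[[paste0("truth_", nm)]] <- p
    }
  }
  pm <- file.path(out_dir, "populations.tsv")
  write_table_tsv(data.frame(sample = genotypes$samples,
                             population = genotypes$populations), pm)
  paths[["populations"]] <- pm
  paths
}

.write_vcf <- function(gt, path) {
  d <- gt$dosage
  if (any(is.na(d) | d != round(d))) {
    stop("VCF writer requires complete integer dosages")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gt$samples), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  v <- gt$variants
  for (j in seq_len(ncol(d))) {
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt_code[d[, j] + 1]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

.write_phenotype_bed <- function(pm, path) {
  f <- pm$features
  start0 <- ifelse(f$kind == "gene", f$tss - 1L, f$start - 1L)
  end0 <- ifelse(f$kind == "gene", f$tss, f$end)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#chr", "start", "end", "id", colnames(pm$values)),
                   collapse = "\t"), con)
  vals <- matrix(sprintf("%.17g", pm$values), nrow = nrow(pm$values))
  body <- cbind(f$chrom, start0, end0, f$id, vals)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
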