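# Small in-code fixtures shared across test files.

# Genotype dataset from an explicit dosage matrix (samples x variants),
# variants evenly spaced `spacing` bp apart on chr1.
make_gt <- function(dosage, populations = rep("POP1", nrow(dosage)),
                    spacing = 1000L) {
  m <- ncol(dosage)
  variants <- data.frame(chrom = "chr1", pos = spacing * seq_len(m),
                         id = sprintf("var%05d", seq_len(m)),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("S%03d", seq_len(nrow(dosage)))
  genotype_dataset(dosage, variants, populations)
}

# Gene phenotype matrix (features x samples) with TSS positions.
make_pm <- function(values, tss, state = "raw") {
  ids <- sprintf("G%03d", seq_len(nrow(values)))
  rownames(values) <- ids
  features <- data.frame(id = ids, kind = "gene", chrom = "chr1", tss = tss,
                         start = NA_integer_, end = NA_integer_,
                         cluster = NA_character_, stringsAsFactors = FALSE)
  phenotype_matrix(values, features, state)
}

# Random genotypes: n samples, m variants, frequencies in (0.2, 0.8).
random_gt <- function(n, m, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  make_gt(dos)
}

# Reference OLS scan for one phenotype/variant pair via lm(): the oracle
# the fast scan must reproduce.
lm_oracle <- function(y, x, C = NULL) {
  df <- if (is.null(C)) data.frame(y = y, x = x) else
    data.frame(y = y, x = x, C)
  fit <- summary(lm(y ~ ., data = df))
  co <- fit$coefficients["x", ]
  list(beta = co[["Estimate"]], se = co[["Std. Error"]], p = co[["Pr(>|t|)"]])
}
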