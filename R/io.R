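#' Genotype dataset container
#'
#' Bundles a sample-by-variant ALT-allele dosage matrix with variant records,
#' pooled minor-allele frequencies, and per-sample population labels. Dosages
#' are counts of the ALT allele in \[0, 2\] (fractional allowed for imputed
#' data); missing values are `NA`. Internal coordinates are 1-based.
#'
#' @param dosage numeric matrix, samples x variants; rownames are sample ids,
#'   colnames variant ids.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, one row per column of `dosage`.
#' @param populations character vector of population labels, one per sample.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `dosage`, `variants` (with an added `maf` column), `samples`,
#'   `populations`.
#' @export
genotype_dataset <- function(dosage, variants, populations) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (length(populations) != nrow(dosage)) {
    stop("one population label per sample required")
  }
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  colnames(dosage) <- variants$id
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  alt_freq <- colMeans(dosage, na.rm = TRUE) / 2
  variants$maf <- pmin(alt_freq, 1 - alt_freq)
  structure(
    list(dosage = dosage, variants = variants,
         samples = rownames(dosage),
         populations = as.character(populations)),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d variants, %d population(s)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$populations))))
  invisible(x)
}

#' Phenotype matrix container
#'
#' Feature-by-sample phenotype values (expression or intron junction
#' proportions) with per-feature genomic annotation. Gene features carry a
#' 1-based TSS position; intron features carry a 1-based closed interval and
#' a cluster id.
#'
#' @param values numeric matrix, features x samples; rownames feature ids.
#' @param features data.frame with columns `id`, `kind` ("gene" or "intron"),
#'   `chrom`, `tss` (genes; NA for introns), `start`, `end` (introns; NA for
#'   genes), `cluster` (introns; NA for genes).
#' @param state normalization state tag, `"raw"` or `"qn"`.
#' @return Object of class `phenotype_matrix`.
#' @export
phenotype_matrix <- function(values, features, state = c("raw", "qn")) {
  state <- match.arg(state)
  stopifnot(is.matrix(values), nrow(features) == nrow(values))
  if (anyDuplicated(features$id)) stop("feature ids must be unique")
  rownames(values) <- features$id
  structure(list(values = values, features = features, state = state),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("phenotype_matrix [%s]: %d features x %d samples (%s)\n",
              x$state, nrow(x$values), ncol(x$values),
              paste(unique(x$features$kind), collapse = "+")))
  invisible(x)
}

#' Covariate matrix container
#'
#' @param values numeric matrix, samples x named covariates.
#' @param validate reject constant columns (default TRUE).
#' @return Object of class `covariate_matrix`.
#' @export
covariate_matrix <- function(values, validate = TRUE) {
  stopifnot(is.matrix(values))
  if (is.null(colnames(values))) stop("covariates must be named")
  if (!is.numeric(values)) stop("covariates must be numeric")
  if (validate && ncol(values) > 0) {
    const <- apply(values, 2, function(v) sd(v, na.rm = TRUE) == 0 || all(is.na(v)))
    if (any(const)) {
      stop("constant covariate column(s): ",
           paste(colnames(values)[const], collapse = ", "))
    }
  }
  structure(list(values = values), class = "covariate_matrix")
}

# Parse a vector of VCF GT strings into ALT dosages 0/1/2 (NA for missing).
.gt_to_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    if (any(a %in% c(".", ""))) return(NA_real_)
    sum(as.numeric(a) != 0)
  }, numeric(1))
}

#' Read genotypes from a VCF file
#'
#' Reads a VCF (v4.x) with per-sample GT calls, counting dosages on the ALT
#' allele (0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA). Multi-allelic records
#' are skipped with a warning. Pooled MAF is computed over non-missing
#' samples.
#'
#' @param path VCF file (plain or gzipped).
#' @param population_map named character vector or two-column data.frame
#'   (`sample`, `population`) assigning every VCF sample to a population.
#' @return A [genotype_dataset].
#' @export
read_genotypes_vcf <- function(path, population_map) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.data.frame(population_map)) {
    population_map <- setNames(as.character(population_map$population),
                               population_map$sample)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records")
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- which(!multi)
  samples <- colnames(gt)
  missing_samples <- setdiff(samples, names(population_map))
  if (length(missing_samples)) {
    stop("sample(s) absent from population_map: ",
         paste(missing_samples, collapse = ", "))
  }
  dos <- matrix(NA_real_, nrow = length(samples), ncol = length(keep),
                dimnames = list(samples, fix$ID[keep]))
  for (j in seq_along(keep)) {
    dos[, j] <- .gt_to_dosage(gt[keep[j], ])
  }
  variants <- data.frame(
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    id = fix$ID[keep], ref = fix$REF[keep], alt = fix$ALT[keep],
    stringsAsFactors = FALSE)
  genotype_dataset(dos, variants, population_map[samples])
}

#' Read a BED-like phenotype file
#'
#' Expects a header line `#chr start end id <sample...>` and tab-separated
#' rows. Intervals are 0-based half-open on disk. Features whose id contains
#' a `clu<k>:` prefix are treated as introns (interval stored 1-based closed,
#' cluster id from the prefix); all other rows are genes whose TSS is the
#' interval start converted to a 1-based position.
#'
#' @param path file path.
#' @return A [phenotype_matrix] with state `"raw"`.
#' @export
read_phenotype_bed <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#")) stop("phenotype BED must start with a #header line")
  cols <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  tab <- read.delim(path, header = FALSE, skip = 1, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) != length(cols)) stop("row width does not match header")
  names(tab) <- cols
  ids <- as.character(tab[[4]])
  if (anyDuplicated(ids)) stop("duplicate feature id(s) in phenotype BED")
  start0 <- as.integer(tab[[2]]); end0 <- as.integer(tab[[3]])
  if (any(start0 >= end0)) stop("interval with start >= end in phenotype BED")
  is_intron <- grepl("^clu[0-9]+:", ids)
  features <- data.frame(
    id = ids,
    kind = ifelse(is_intron, "intron", "gene"),
    chrom = as.character(tab[[1]]),
    tss = ifelse(is_intron, NA_integer_, start0 + 1L),
    start = ifelse(is_intron, start0 + 1L, NA_integer_),
    end = ifelse(is_intron, end0, NA_integer_),
    cluster = ifelse(is_intron, sub(":.*", "", ids), NA_character_),
    stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -(1:4), drop = FALSE])
  mode(vals) <- "numeric"
  colnames(vals) <- cols[-(1:4)]
  phenotype_matrix(vals, features, state = "raw")
}

#' Read a tab-separated table with header
#'
#' @param path file path.
#' @param numeric coerce all non-id columns to numeric, failing loudly.
#' @return data.frame (possibly zero rows).
#' @export
read_table_tsv <- function(path, numeric = FALSE) {
  first <- readLines(path, n = 1)
  if (!length(first) || first == "") stop("missing header in ", path)
  widths <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(widths)) > 1) stop("ragged rows in ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (numeric) {
    for (j in seq_along(tab)) {
      if (is.character(tab[[j]])) {
        conv <- suppressWarnings(as.numeric(tab[[j]]))
        if (anyNA(conv) && !all(is.na(tab[[j]]))) {
          stop("non-numeric value in column '", names(tab)[j], "'")
        }
        tab[[j]] <- conv
      }
    }
  }
  tab
}

#' Write a table as TSV with header, full float precision
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read covariates from TSV
#'
#' First column is the sample id; remaining columns must be numeric and
#' non-constant.
#'
#' @param path TSV with header.
#' @return A [covariate_matrix] with sample ids as rownames.
#' @export
read_covariates_tsv <- function(path) {
  tab <- read_table_tsv(path)
  ids <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    conv <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(conv) && !all(is.na(vals[[j]]))) {
      stop("non-numeric covariate cell(s) in column '", names(vals)[j], "'")
    }
    vals[[j]] <- conv
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  covariate_matrix(m)
}
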