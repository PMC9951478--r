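Package: tqtl
Title: Cis-QTL Mapping, Fine-Mapping, and Selection Scans for
    Multi-Population Transcriptomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps expression and splicing quantitative trait loci (eQTLs and
    sQTLs) in cis with covariate and relatedness correction, controls
    discovery with a hierarchical Benjamini-Hochberg procedure, fine-maps
    associations into 90% credible sets via Wakefield approximate Bayes
    factors, and tests fine-mapped loci for population differentiation using
    Hudson's FST, the population branch statistic, and a polarized
    d-statistic with permutation and matched-background nulls. Includes
    replication statistics (Storey's pi1, one-sided Kolmogorov-Smirnov tests,
    effect-size concordance, conditional independence classification) and a
    multi-population synthetic-data generator (Balding-Nichols genotypes,
    cis-regulated expression and intron-junction phenotypes) with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
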