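---
title: "Methods: cis-QTL mapping, fine-mapping, and selection scans in tqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-QTL mapping, fine-mapping, and selection scans in tqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tqtl)
```

`tqtl` implements a complete desk-scale pipeline for mapping transcriptomic
quantitative trait loci (tQTLs — expression and splicing QTLs) in cohorts
drawn from several differentiated populations, fine-mapping the resulting
associations into credible sets, and asking whether the fine-mapped loci
show evidence of local adaptation. This vignette explains each model, its
assumptions, the tunable parameters, and the numerical choices made where a
convention had to be picked.

## The association model

For each feature (a gene's normalized expression, or an intron's junction
proportion within its cluster), every variant with pooled minor allele
frequency above 0.05 and within 100 kb of the feature (gene TSS, or intron
interval with distance zero inside the interval) is tested under an
additive dosage model

$$ y = \mu + \beta g + C\gamma + \varepsilon, $$

where $g$ counts ALT alleles (0–2, mean-imputed where missing) and $C$
holds the covariates (measured covariates plus inferred hidden factors).
The default engine is ordinary least squares with a two-sided Wald $t$ test
on $\beta$, computed through covariate residualization (Frisch–Waugh), so
it is algebraically identical to the full regression. A linear mixed model
with one genetic variance component is available (`model = "lmm"`): the
genetic relatedness matrix (GRM) is eigendecomposed once, the variance
ratio $\delta = \sigma^2_e/\sigma^2_g$ is estimated by REML on the
covariates-only model once per feature, and each variant is then tested by
generalized least squares in the rotated basis. Estimating $\delta$ once
per feature rather than per variant is the standard speed/accuracy
trade-off; with an identity GRM the mixed model reduces exactly to OLS,
which the test suite checks to 1e-6. The Wald test was chosen over LRT or
score tests as the conventional default for single-variant scans.

The GRM is built from all polymorphic biallelic variants, columns
standardized with the population variance (denominator $n$) so the diagonal
averages exactly 1, and $G = XX^\top/M$.

## Normalization and hidden factors

Raw phenotypes pass two filters before normalization. Genes need more than
5 reads in at least 20 individuals and mean TPM strictly above 0.1; introns
may have at most 5 individuals with zero reads, and their cluster must have
at least 20 reads in at least 100 individuals and strictly fewer than 10
zero-read individuals. Filtering happens before normalization; whether the
sample-level normalization should precede filtering is a genuinely open
ordering question, and filtering first was chosen because the filters are
defined on raw counts.

Normalization is two-stage. Stage 1 quantile-normalizes each sample's value
distribution onto the across-sample average order statistics, removing
sample-level distributional differences; tied values share the average of
their target values. Stage 2 maps each feature onto the standard normal via
$\Phi^{-1}((r - 0.5)/n)$ with average ranks for ties; Blom's offset (3/8)
is available via the `offset` argument. Neither offset convention is
canonical; $(r-0.5)/n$ was chosen as the symmetric midpoint rule. A feature
that is constant across samples cannot be rank-normalized and is mapped to
zero and flagged.

Hidden covariates are inferred as principal components of the
feature-centered normalized matrix. Variational factor models (PEER-style)
serve the same role in many published pipelines; principal components are
used here because what the pipeline actually consumes is a set of
latent-variance surrogates, and the selection rule — rerunning the scan
across a grid of factor counts and keeping the count that maximizes
FDR-significant discoveries, ties going to the smallest count — is
preserved, which is what matters downstream. Components get a
deterministic sign (largest-magnitude loading positive) so results are
reproducible across platforms.

## Hierarchical FDR

Discovery control is two-level Benjamini–Hochberg: BH across each feature's
variants gives single-corrected $P'$; BH across the per-feature minima
gives double-corrected $P''$; features with $P'' < 0.05$ are significant.
The variant-level threshold is the minimum $P'$ of the significant feature
with the largest $P''$, and variants of significant features with $P' \le$
threshold are flagged. Two conventions were fixed deliberately: the
comparison is $\le$ rather than strictly below, so the borderline feature's
own lead variant is always included; and flagging is restricted to
significant features, since a variant inside a non-significant feature has
no discovery to attach to.

## Fine-mapping

Per variant, the Wakefield approximate Bayes factor is computed from the
scan summary statistics: $z = \beta/\mathrm{se}$, $V = \mathrm{se}^2$,
shrinkage $r = W/(V+W)$, $\log \mathrm{ABF} = \tfrac12(\log(1-r) + z^2 r)$.
When effect estimates are unavailable the p-value form is used, with
$z = \Phi^{-1}(1-p/2)$ and $V = 1/(2nf(1-f))$. The prior effect variance
defaults to $W = 0.15^2$, the conventional prior SD for a phenotype
standardized to unit variance — which stage-2 normalization guarantees
here; it is configurable for other scales. Underflowing p-values cap $z$
at 40.

Posteriors are the ABFs normalized within the feature (computed in log
space), and the 90% credible set is the minimal prefix of
descending-posterior variants whose cumulative mass strictly exceeds 0.9.
The strict comparison carries a 1e-9 absolute guard: exactly uniform
posteriors over ten variants must give a ten-variant set, and without the
guard floating-point cumulative sums can cross the boundary spuriously.
Ties in posterior break by smaller p-value, then variant id. Only
single-causal-variant fine-mapping is implemented; multi-signal loci are
handled operationally by the conditional scan.

## Conditional analysis and replication statistics

The conditional scan residualizes each feature's normalized phenotype on
its conditioning dosages (plus covariates), reruns the identical scan, and
calls the feature independent iff any variant's within-feature $P'$ still
passes the original threshold. Features are then labeled "independent" or
"shared" for the replication comparisons.

Replication strength is summarized by Storey's $\pi_1 = 1 - \pi_0$:
$\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on the grid 0.05–0.95,
smoothed with a cubic spline (df = 3) and read off at $\lambda = 0.95$; a
fixed-$\lambda$ (0.5) estimator is available. Frequency and LD-structure
differences between shared and independent QTLs are compared with one-sided
Kolmogorov–Smirnov tests using the asymptotic tail bound
$\exp(-2D^2mn/(m+n))$ (a permutation p-value is available for small
samples). Effect-size concordance aligns cohorts on the ALT allele,
flipping signs at swapped ref/alt pairs and dropping strand-ambiguous (A/T,
C/G) swaps. Credible-set size comparisons use the exact two-sided binomial
test via the minimum-likelihood convention of `stats::binom.test`.

## Selection scans

Differentiation statistics are built from per-population ALT-allele
frequencies, with allele counts $n = 2 \times$ non-missing diploids (a
definition that had to be fixed; missingness-aware counting is the natural
choice). Hudson's FST uses the finite-sample-corrected numerator and is
aggregated over variant sets as a ratio of averages. Per-variant FST can be
negative; negative values are retained for the d-statistic and enrichment
analyses but clamped to zero inside the PBS branch length
$T = -\log(1 - F_{ST})$, where a negative argument would flip the sign
semantics of the log. The polarized d-statistic standardizes each pairwise
FST by its genome-wide mean and SD (computed once per pair over all
variants with defined FST) and signs each term by whether the focal
frequency exceeds the other population's, so intermediate-frequency focal
variants cancel rather than score.

Gene-level scores weight each per-variant statistic by the fine-mapping
posterior: $\bar F_{ST} = \sum_p PP_p F_{ST}^p$, and likewise for d and
PBS. Significance comes from locus permutations (statistic shuffled across
the locus's variants, posteriors fixed) with the add-one convention
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(B+1)$, so empirical
p-values are never zero. Global candidates must exceed the 99th percentile
of genome-wide per-SNP FST and have permutation $p < 0.01$;
population-specific candidates must exceed the 99.5th percentile of both
the genome-wide d and PBS distributions, with the permutation requirement
optional for these (the global scan is where the permutation null is
essential, because posterior-weighted averages of locally elevated FST are
otherwise confounded by background selection). Percentile thresholds are
always computed from the supplied genome-wide vectors, never hard-coded.

Enrichment of FST outliers among lead QTL variants compares the max-FST
over each lead's LD set (r² > 0.8 companions, lead included) against
matched null SNPs drawn from the same MAF bin (width 0.05) and LD-count bin
({0}, {1,2}, (2,5], (5,10], (10,20], (20,50], >50); annotation enrichment
matches on MAF and TSS-distance decile and scores
$\log((\#\mathrm{QTL}+1)/(\#\mathrm{background}+1))$ per category, the
pseudocount guarding empty cells. Null draws are without replacement within
a replicate, with replacement across replicates, QTL variants excluded from
the pool; an empty matching bin falls back to the nearest non-empty bin
with a warning.

## The synthetic-data generator

The generator exists so that every stage above can be validated against
known truth. Populations follow the Balding–Nichols model: ancestral
frequencies uniform on (0.05, 0.95) (limiting monomorphic draws),
per-population frequencies Beta-distributed around them with drift
parameter $F$, diploid dosages binomial. This gives each population pair a
tunable expected FST, which the Hudson estimator must recover — the
generator's most important calibration property. Variants sit at evenly
spaced positions on one synthetic chromosome so every cis window holds a
predictable number of variants. Expression phenotypes are Gaussian with an
additive effect of one causal cis variant for a configurable fraction of
genes; splicing phenotypes are junction proportions from
Poisson-multinomial cluster counts, the causal effect shifting one
junction's logit proportion (Dirichlet-multinomial overdispersion is
available behind a flag, off by default). Covariates comprise a binary
sex analogue, a continuous age analogue, and standard-normal latent factors
whose loadings dominate the measured covariates, emulating the hidden
technical and cell-composition variation that factor inference is meant to
absorb.

What the generator deliberately does not emulate: linkage disequilibrium
from recombination (variants are independent given population
frequencies), admixed individuals, heritability spectra matched to any real
tissue, or sequence-level artifacts. Passing tests therefore demonstrate
the statistical machinery is correct and calibrated under the stated
model, not that real whole-blood data would yield any particular discovery
count. In particular, credible-set coverage on LD-free simulations is
higher than on real data, where LD spreads posterior mass across tagging
variants. Effect-size and noise defaults (`effect_size_sd = 0.8`,
`noise_sd = 1`) are placeholders exposed in `sim_config`, since cohort
heritability is not something the pipeline can assume.

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the statistical properties are
sharp: drift recovery on 5,000 variants and 100 diploids per population;
FDR calibration on 20–50 null cohorts of 300 features by 162 samples with
about 200 cis variants per feature; credible-set coverage on 250
strong-effect genes; $\pi_1$ recovery at 20,000 p-values; permutation
calibration over 200 loci at $B = 199$. All randomness flows from a single
integer seed; identical seeds give byte-identical datasets and results.
The package is driven from R: exported functions per stage plus
`run_demo()`, which chains simulate → filter → normalize → scan → FDR →
fine-map → selection → split-sample replication and returns every
intermediate object.

## Known limitations

- Single-causal-variant fine-mapping only; credible sets at multi-signal
  loci are interpretable only after conditioning.
- The mixed model assumes one variance component; environment or batch
  kinship beyond the GRM is not modeled.
- The splicing generator ties the causal effect to the first junction of a
  cluster and does not simulate annotation-dependent junction structure.
- FST-based scans inherit the usual caveat that high differentiation is
  evidence of selection only relative to an appropriate genome-wide null;
  the matched-background machinery mitigates, but cannot eliminate,
  confounding by background selection and admixture.
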