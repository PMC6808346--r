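---
title: "Candidate-gene polygenic profiles for language and psychosocial outcomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene polygenic profiles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyprofile)
```

## The scientific question

Children with poor language tend to have worse psychosocial outcomes than
their peers. One candidate explanation is developmental (poor language makes
social interaction harder); another is biological (the same common variants
influence both domains). Polygenic profile scores offer a way to probe the
second: estimate per-SNP effects on a language measure in one half of a
cohort, collapse them into a single weighted score, and ask whether that
score predicts language *and* psychosocial outcomes in the other,
independent half. `polyprofile` implements that full design — cohort
simulation, genotype QC, per-SNP association, LD clumping, p-value-
thresholded profile scores, best-fit threshold scans, and family-wise
false-discovery control — as composable, tested functions.

Because the cohort data this design is typically applied to are
managed-access, the package ships a synthetic-cohort generator as a
first-class module. Every downstream stage can therefore be exercised, end
to end, on data whose generating truth is known.

## The statistical pipeline

### Per-SNP association

For each SNP $j$ and quantitative trait $y$, an ordinary least-squares
model with intercept is fitted on complete cases:

$$y_i = \alpha + \beta_j g_{ij} + \varepsilon_i,$$

where $g_{ij} \in \{0, 1, 2\}$ counts the effect allele. Two-sided
p-values come from the $t$ distribution with $n - 2$ degrees of freedom.
Monomorphic SNPs yield a flagged degenerate row with $p = 1$ rather than
an error, so downstream thresholding is total. No covariates are included
by default; ordinal instruments are treated as quantitative.

### LD clumping

SNPs with $p \le$ `p_ceiling` are visited in order of ascending p (ties
broken by position, then identifier). Each round retains the best
remaining SNP as an index and removes all unassigned SNPs on the same
chromosome within `window_kb` whose squared dosage correlation with the
index exceeds `r2_threshold`. Defaults are `r2_threshold = 0.1`,
`window_kb = 250`, `p_ceiling = 1`, the conventional settings of
threshold-scan PRS tools. LD is measured as the composite (genotype) $r^2$
— the squared Pearson correlation of dosages over complete pairs — since
no phase information is modelled; this is a deliberate, documented
surrogate for haplotype $r^2$. LD is always computed in the cohort that
supplied the p-values (the discovery half).

### Profile scores and the threshold scan

At threshold $T$, the score of individual $i$ is the weighted average

$$s_i(T) = \frac{1}{|S(T)|} \sum_{j \in S(T)} \hat\beta_j\, g_{ij},$$

over the clumped SNPs with discovery $p_j \le T$. Averaging (rather than
summing) keeps scores comparable across thresholds with different
$|S(T)|$; since $R^2$ and the regression p-value are invariant to affine
rescaling of the score, this choice does not affect any reported
statistic. Missing dosages are imputed at twice the effect-allele
frequency of the scored cohort. Weights whose effect allele is the scored
dataset's other allele have their sign flipped, which makes scores exactly
invariant to allele-label flips with negated effects.

The grid runs from .01 to .50 in steps of .01 (50 thresholds). Zero is
excluded because an empty score is undefined; .50 is included because
best fits do occur at the grid's upper end. The sets $S(T)$ are nested,
so the scan accumulates contributions incrementally rather than rebuilding
each score.

Two best-fit modes are provided, because both framings are common:

* `scan_in_target` (default): thresholds are scanned in the evaluation
  (replication) cohort and the maximal-$R^2$ row is reported — the style
  of best-fit summary tables.
* `fixed_from_discovery`: the threshold is maximized in the discovery
  cohort and fitted once in replication — the style appropriate when the
  replication fit must itself be a single pre-registered test.

Neither mode is asserted to be "the" correct one; ties at equal $R^2$
break toward the smaller threshold (fewer SNPs).

### Test families and multiple testing

The replication fits form two families: *consistency* (each base trait
predicting itself, $m = 8$) and *cross-trait* (one base trait's weights
predicting DLD status and the five SDQ subscales, $m = 6$).
Benjamini–Hochberg step-up adjustment is applied within each family
separately — adjusted values printed for such tables are recoverable only
under this split — and rows with adjusted $p \le .05$ are flagged. DLD
status (a 0/1 caseness) is fitted by a linear probability model by
default so that all targets run through identical machinery; a logistic
alternative is available via `dld_link = "logistic"`.

## The synthetic cohort generator

### Genotypes

Six candidate gene loci (ATP2C2, CMIP, CNTNAP2, DCDC2, FOXP2, KIAA0319 at
their hg38 coordinates) carry 1,229 SNPs in total, allocated to genes in
proportion to genomic span by largest-remainder rounding — gene size, not
a per-gene quota, determines SNP counts. Within a block, genotypes follow
a latent-Gaussian threshold model: each of the two haplotypes is an
indicator that a latent AR(1) Gaussian (autocorrelation `ld_rho`, default
0.8) falls below the frequency quantile. This gives one LD parameter per
block, block-diagonal LD as in real gene loci, Hardy–Weinberg genotype
proportions, and mutually independent blocks. Effect-allele frequencies
are uniform on (0.05, 0.5); genotype calls go missing completely at
random at rate 0.01, consistent with post-QC data. The default cohort
size is 5,435, splitting 2,718/2,717.

### Phenotypes

Each trait has an architecture (causal SNP set, effect sizes, $h^2$). The
latent trait is

$$y^* = \sqrt{h^2}\,\tilde g + \sqrt{1 - h^2}\,\varepsilon,\qquad
\tilde g = \mathrm{scale}\Big(\sum_j \beta_j z_{ij}\Big),$$

with $z_{ij}$ the standardized dosage, so the additive component explains
exactly $h^2$ of latent variance. The latent score is standardized and
mapped affinely onto each instrument — midpoint plus $z \cdot
\mathrm{span}/6$, rounded to integers and clipped to the printed bounds
(e.g. 0–268 and 0–246 vocabulary inventories, 0–10 expressive naming,
86–162 pragmatic checklist, 0–10 SDQ subscales). Mapping by midpoint/span
preserves rank correlations while honouring instrument ranges; $\pm 3$ SD
spans the instrument, so clipping is rare.

The default architecture is deliberately weak, matching what candidate-
gene panels can plausibly carry: the expressive-language trait has 65
causal SNPs whose component explains 1% of variance; the peer-problems
trait has 65 causal SNPs of which 27 are shared with expressive language
with identical effect sizes (controlled pleiotropy); the remaining
language traits carry 40-SNP architectures at $h^2 = 0.005$, the other
problem subscales $h^2 = 0.002$, and prosociality none.

### Caseness and flags

DLD caseness uses a two-of-four criterion rule: pragmatic language,
nonword repetition, or receptive language more than 1 SD below the
standardized sample mean, or a positive speech/language-therapy report.
The therapy flag is generated as a noisy logistic indicator of low latent
language, $\Pr(\text{therapy}) = \mathrm{logit}^{-1}(-3 - 1.5\bar z)$,
because no deterministic rule exists for it; the intercept gives a
baseline rate of about 5%. ASD-like (1.2%) and hearing-like (2%) flags
exclude a child from both the affected and comparison groups. Under the
defaults this yields a caseness prevalence around 7–8%, within the range
of community prevalence estimates for DLD; the cutoff and the criterion
subset are configurable, and prevalence is monotone in the cutoff.

### What the generator does not emulate

Phenotypic correlation between instruments arises only through shared
genetics, so the strong instrument intercorrelations of real longitudinal
measures (and their shared method variance) are absent. Recruitment,
attrition, multiple births, ethnicity structure, genotyping batch
effects, and imputation artefacts are all out of scope. Passing tests on
this cohort therefore demonstrate the *pipeline's* correctness and
calibration, not that any particular real-world effect exists.

## Numerical and design choices

* **Seeds.** One master seed; every stochastic stage derives a child seed
  via a deterministic string hash (`derive_seed`), so stages are
  individually reproducible and mutually independent.
* **QC order.** Individuals with missingness above 3% are removed before
  SNP statistics are computed, then SNPs failing MAF < 1%, call rate
  < 95%, or HWE exact $p < 5 \times 10^{-7}$ are dropped; ordering
  matters because individual removal changes marginal SNP statistics.
  Heterozygosity and relatedness screens are accepted as upstream flags
  rather than recomputed, since they need cohort-scale context the
  package does not model.
* **HWE exact test.** Classic (non mid-p) exact conditional test,
  evaluated by log-gamma closed form over same-parity heterozygote
  counts, with probabilities no larger than the observed configuration's
  (within a $1 + 10^{-10}$ tolerance factor) summed.
* **Coordinates.** 1-based positions; gene-region membership uses closed
  intervals.
* **Degenerate inputs.** Monomorphic SNPs, constant phenotypes, empty
  score sets, and empty clump inputs are flagged results, not errors;
  irreconcilable alleles and missing traits are errors naming the
  offenders.
* **Rounding.** Report tables display three decimals; all computation and
  stored output keep full precision.

## Problem sizes in the test suite

The suite favours exact oracles at small sizes (closed-form OLS,
brute-force greedy clumping on 15-SNP instances, enumeration HWE) and
simulation checks at the design's own scale where the property demands
it: the null calibration of the fixed-threshold replication test uses 500
replicates of a 60-SNP, 5,435-individual cohort, and the
parameter-recovery check runs the full 1,229-SNP, 65-causal-SNP
architecture at the study split with 40 replicates, comparing the causal
arm's median best-fit replication $R^2$ against the 95th percentile of a
matched null arm (same genotypes, no causal SNPs).

A design note on that recovery check: with a causal component of ~1% of
variance spread over 65 SNPs, the expected increment in best-fit
replication $R^2$ over the null is of the same order as the spread of the
null's max-over-thresholds distribution, so a median-versus-null-95th-
percentile comparison sits near the boundary of what this architecture
can support. The check is kept at these conditions because they are the
design's stated regime; the paired causal-minus-null shift is the
quantity the architecture actually controls. The shared-fraction
pleiotropy check uses common genotypes and common environmental noise
across the shared fractions $f \in \{0, .5, 1\}$ so that the comparison
is paired rather than between independent simulations.

## Known limitations

* Haplotype-phase LD is not modelled; composite $r^2$ is used throughout.
* Logistic cross-trait fits report McFadden's pseudo-$R^2$, which is not
  comparable to the linear $R^2$ of the other rows.
* Best-fit threshold scans maximize over 50 correlated tests; nominal
  p-values of best-fit rows are optimistic by construction, which is why
  family-wise BH flags — and, for stricter use, the
  `fixed_from_discovery` mode — are provided.
* The generator's instrument correlations understate real-data
  correlations (see above), so the phenotype correlation matrix it
  produces is structurally sparser than a real cohort's.
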