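---
title: "Methods: Boolean implication networks for a multi-omics prognostic signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Boolean implication networks for a multi-omics prognostic signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implinet)
```

`implinet` implements an integrated analysis pipeline for a seven-gene
non-small cell lung cancer (NSCLC) prognostic signature (*ABCC4*, *CCL19*,
*SLC39A8*, *CD27*, *FUT7*, *DAG1*, *ZNF71*): three-level discretization of
expression and copy-number profiles, Boolean implication network inference by
prediction-logic statistics, cross-cohort replication, multi-omics network
assembly, proliferation-gene calling from CRISPR/RNAi dependency screens,
proportional-hazards risk stratification, drug-response categorization, and
construction of up/down gene lists for connectivity-map (CMap) queries. This
vignette documents the models, the tunable parameters and the design
decisions, and states precisely what the synthetic-data validation does and
does not demonstrate.

## Expression discretization

Gene expression is reduced to calls in $\{-1, 0, 1\}$ (under-expressed /
unchanged / over-expressed) per gene $g$ with row mean $m_g$ and standard
deviation $s_g$:

$$\mathrm{call}(x) = \begin{cases} 1 & x > m_g + n\, s_g \\ -1 & x < m_g - n\, s_g \\ 0 & \text{otherwise.} \end{cases}$$

The multiplier $n$ is calibrated on a panel of 27 housekeeping genes
(`housekeeping_genes()`): for each housekeeping gene, `solve_threshold_n()`
finds the $n$ at which the number of flagged samples (over- plus
under-expressed) equals a target fraction of the cohort, 30% by default.
Because the flagged count is a non-increasing step function of $n$ that
changes only at the standardized absolute deviations $|x - m_g|/s_g$, the
equation is solved by exact breakpoint search, not iteratively. Two
numerical choices matter:

* **Ties.** On discrete data the target count may be unattainable; the
  solver then returns the $n$ whose count is closest, preferring the smaller
  count, and among equal counts the smallest $n$. This makes the result
  deterministic and order-independent.
* **Boundary arithmetic.** `discretize_expression()` compares on the
  standardized scale $(x - m_g)/s_g$ so that a threshold returned by the
  solver behaves identically at its defining breakpoint in floating point.

The per-gene solutions are averaged over the 27 housekeeping genes
(`average_housekeeping_n()`) and that single cohort-level $n$ is applied to
every gene. The calibration is per gene *before* averaging (each
housekeeping gene uses its own mean and standard deviation); we read the
calibration contract that way because the equation is solved "for each
gene", and the per-gene construction is also the only one under which the
30%-per-gene property is testable. On continuous data with $0.3N$ integral
this flags exactly 30% of samples per housekeeping gene; on real, tied data
it is approximate.

Copy-number input is categorized by `categorize_cnv()` to amplification
(+1), normal (0) and deletion (−1). Upstream segmentation pipelines differ,
so the thresholds are explicit configuration, never inferred: defaults
$(0.3, -0.3)$ suit log2-ratio input, and $(0.5, -0.5)$ passes already
three-level matrices through unchanged. CNV thresholds are inclusive;
expression thresholds are strict (matching the inequalities of the
calibration equation).

## Prediction-logic implication rules

For an ordered pair of discretized variables $(A, B)$, four implication
rules are scored, each with a single "error" corner of the $3\times3$
contingency table: $A{=}1 \Rightarrow B \neq -1$ (error cell $(1,-1)$),
$A{=}1 \Rightarrow B \neq 1$, $A{=}-1 \Rightarrow B \neq -1$, and
$A{=}-1 \Rightarrow B \neq 1$. With $N$ samples, error count $e$, premise
row marginal $r$ and error-column marginal $c$:

$$e_{obs} = e/N, \qquad e_{exp} = \frac{r}{N}\cdot\frac{c}{N}, \qquad
U = e_{exp}, \qquad \nabla = 1 - \frac{e_{obs}}{e_{exp}}, \qquad
z = \frac{(e_{exp} - e_{obs})\sqrt{N}}{\sqrt{e_{exp}(1 - e_{exp})}}.$$

$U$ (scope) is the rule's expected error mass under independence and
$\nabla$ (precision) the proportional error reduction relative to
independence. A rule is significant when $z > z_{crit}$ (1.64 by default,
one-tailed $\alpha = 0.05$) with positive scope and precision. Samples with
a 0 call in the premise variable can never count as errors — they only
dilute the marginals — because error cells are corner cells by
construction.

Design decisions:

* Each $A \to B$ rule coincides with its $B \to A$ contrapositive (same
  error cell, same marginal product), so scoring the four $A \to B$ rules
  covers both directions; equivalence-like relations appear as the pair of
  reciprocal significant rules rather than as separate rule types.
* `best_rule()` resolves a pair to its single highest-precision significant
  rule, breaking ties by larger scope and then by a fixed rule-type order —
  fully deterministic.
* `infer_network()` defaults to the best-rule-per-pair convention but can
  return all significant rules (`keep = "significant"`); for symmetric
  planted relations the best rule alternates by sampling noise between the
  two reciprocal corners, so replication analyses that intersect cohorts by
  rule type should use the all-significant-rules mode.
* `intersect_cohorts()` keeps a rule only if it is significant **with the
  same rule type** in every cohort: a regulatory direction must replicate.

**The variance convention and its consequences.** The $z$ above divides by
$e_{exp}(1-e_{exp})$, treating the expected error rate as a fixed binomial
proportion. Conditionally on the observed marginals, however, the error
count is hypergeometric, with variance smaller by roughly the factor
$(1-r/N)(1-c/N)/(1-e_{exp})$. The statistic is therefore conservative
relative to the exact conditional null: at typical discretized marginals
(15% per tail) its realized per-rule type-I error is nearer 0.02 than the
nominal 0.05, and it disagrees with a permutation test at $\alpha = 0.05$
on a few percent of random tables. `permutation_null()` implements the
exact conditional reference (by label permutation; the closed form is
hypergeometric) and the test suite quantifies the gap rather than hiding
it. We keep the one-proportion form because it is the stated contract of
the method being implemented; the conditional test is available as the
oracle, and the conservatism only costs power, never validity.

## Multi-omics network assembly

`seed_filter()` builds the network around the seven signature genes
(seeds): a non-seed gene enters only if its cross-cohort-replicated edges
connect it to at least `min_seed_degree = 2` *distinct* seed genes — a gene
linked twice to one seed through different layers (co-expression and
CNV-mediated expression) counts once. Seeds are always retained and edges
with an excluded endpoint are dropped; the filter is idempotent.
Cross-layer pairs (CNV of one gene against expression of another) are
scored by exactly the same rule machinery; both cis and trans CNV-to-
expression pairs are supported and simply depend on which pairs the caller
requests. For cross-cohort membership we require the same layer pair in
every cohort (the layers are part of the edge identity), the stricter of
the two defensible readings.

`differential_expression_groups()` reproduces the radiotherapy contrast:
stage III/IV patients who received radiotherapy, split into short
(< 20 months) and long (> 58 months) survival, compared per gene by Welch
two-sample t-tests (the unequal-variance form is the safer default when
only "two-sample t-tests" is specified; a pooled flag is provided).

## Dependency screens and proliferation genes

The CRISPR and RNAi screen processing implements the published *output
standardization contracts*, not the underlying deconvolution models (which
consume raw guide/hairpin data we never see). For CRISPR, each cell line is
mapped affinely so the median non-essential-control effect is exactly 0 and
the median essential-control effect exactly −1. For RNAi, genes are first
averaged across cell lines and the same two-point map is applied on the
averages (positive controls to −1, negative to 0); the per-line matrix is
rescaled by the same map so per-line thresholding stays on the standardized
scale. Both maps are affine and hence rank-preserving per line.

A knockout/knockdown effect below −0.5 (strict) is a significant
dependency. Proliferation genes are called two ways, matching the two uses
of the notion: the **majority rule** (significant in ≥ 50% of the lines in
which the gene was actually tested — per-gene tested counts, not the panel
size, form the denominator, and the bound is inclusive) and the **count
rule** (significant in strictly more than 10 lines). The two readings
("in 50% of the tested" inclusive, "more than 10" strict) are literal.

## Survival analysis

`fit_risk_model()` is a standard multivariate Cox partial-likelihood fit
(via the `survival` package) on the seven gene covariates. The risk score
is the *uncentered* linear predictor $\sum_g \beta_g x_g$: no baseline
term, no mean-centering. This convention is stated explicitly because the
stratification cutoff (−0.74 by default) is a transferred constant — a
cutoff learned on a training set is only meaningful on a testing set if
both use the same uncentered convention. Patients score `low` strictly
below the cutoff and `high` at or above it. `km_logrank()` pairs the
two-sided log-rank p-value with the hazard ratio (high vs low) and its 95%
Wald interval from a one-covariate Cox fit on the stratum indicator — the
standard construction when a p-value and an HR are reported together.
Display truncation at 120 months is cosmetic and never alters the tests.

## Drug response and expression correlates

A cell line is *resistant* when its IC50/EC50 exceeds the maximum assayed
dose and *sensitive* below the minimum (default window 0.0006–10 µM, the
eight-dose screen range). For values inside the window the upstream method
is not printed, so the in-window trichotomy is this package's own explicit
rule: log10-scale tertiles of the window, inclusive at the bounds (an IC50
exactly at the maximum dose is in-window and falls in the upper tertile,
hence resistant). The rule is isolated in `categorize_response()` and
recorded in run metadata, so replacing it changes one function.

`de_by_response()` contrasts sensitive against resistant lines only
(partial responders are excluded — the strict reading) with Welch t-tests
and a linear-scale fold change `mean(sensitive)/mean(resistant)`; a gene is
reported when $p < 0.05$ and FC < 0.5 or > 2. Logged matrices must be
flagged (`log_input`) so fold changes are computed on de-logged means while
the t-test stays on the logged scale. `mrna_protein_correlation()` computes
per-gene Pearson correlations, emitting one row per protein quantification
(a gene with two quantifications yields two rows), and
`proportion_test()` compares significant-correlation proportions by the
pooled two-proportion z-test. Both one- and two-tailed p-values are
supported; the default is two-tailed, and the package documents that the
one-tailed variant exists because the two conventions appear side by side
in practice.

## Query signatures

`build_isoform_signature()` turns a seed gene's (or isoform's) significant
co-expression partners, restricted to proliferation genes, into an up/down
CMap query: under an up-regulated seed, positively related partners are up
and inversely related partners are down; under a down-regulated seed the
partition swaps. Three isoform seeds times two directions yield the six
proliferation-network signatures. `build_mechanism_signature()` applies
fixed set algebra to five components (11 epithelial markers up, drug-
sensitive genes up, 3 mesenchymal markers down, count-rule proliferation
genes down, CD27/CD274 down), with proliferation genes excluded from the
up list and epithelial markers excluded from the proliferation term. A
drug-sensitive *gene* is one reported higher-in-sensitive for at least one
drug and never higher-in-resistant in any screen. Up/down overlap in an
exported signature is a hard error, and CMap submission itself is out of
scope — the package exports GRP/GMT query files.

## Synthetic data: what it emulates and what it does not

Every input the pipeline consumes has a seeded generator that also emits
its ground truth:

* `gen_expression_cohort()` — housekeeping genes as unit-variance
  Gaussians; planted pairs share a latent factor with loading equal to the
  strength parameter. The latent-factor construction (rather than, say, a
  copula) is chosen because it produces exactly the corner-cell depletion
  implication rules detect, and strength maps monotonically to precision.
  Two cohorts with the same truth and different seeds exercise replication
  realistically.
* `gen_cnv_with_dosage()` — iid three-level CNV states (default
  frequencies 0.2/0.6/0.2) shifting target-gene expression by one
  strength-unit of its standard deviation per copy-number level.
* `gen_survival()` — exponential event times with hazard multiplier
  $\exp(\sum \beta x)$, baseline median 36 months, and independent uniform
  censoring whose upper bound is calibrated by root-finding to the target
  censoring fraction (realized within about ±3%).
* `gen_dependency_screen()` — true effects (essential −1, non-essential 0,
  planted genes −0.9 in a configured fraction of lines) distorted per line
  by a random affine map, so normalization has real work to undo, plus a
  missing mask.
* `gen_drug_activity()` — IC50/EC50 placed below/inside/above the dose
  window by planted category, with planted DE genes at means 10 vs 4
  (fold change 2.5) and unit within-group standard deviation.

The generators are deliberately Gaussian: the discretization step consumes
only relative position within a gene's distribution, so count-level noise
models (e.g. negative binomial RNA-seq noise) would be discretized away.
Consequently, passing tests demonstrate correctness of the statistics,
thresholds and set logic under the stated sampling models — they do not
demonstrate robustness to array batch effects, normalization artifacts,
probe-to-gene mapping or non-proportional hazards, all of which are
assumed handled upstream (or out of scope) in real data.

## Problem sizes and reproducibility

The validation suite runs at deliberately modest sizes chosen to make its
statistical assertions sharp but quick: 1000 random instances for the
threshold-solver equivalence, 250 random contingency tables against a
$10^4$-permutation null, two 200-sample cohorts with ten planted edges for
replication recovery, 2000 null pairs for the type-I estimate, $n = 1000$
for coefficient recovery and 500 replicates for HR interval coverage. All
randomness is seeded; `run_pipeline()` re-run with the same configuration
reproduces byte-identical artifact digests, and every threshold it uses is
taken from `implinet_config()` and serialized into the run manifest.

## Known limitations

* The implication z-test's variance convention is conservative (see
  above); borderline rules near $z_{crit}$ are under-called relative to
  the exact conditional test.
* No multiplicity control across the rule family is applied by default
  (per-test $\alpha$, as in the method's own usage); genome-scale scans
  should interpret edge counts accordingly.
* The −0.74 risk cutoff is a transferred constant, not re-derived; its
  optimality is out of scope.
* The in-window drug-response trichotomy is a package convention; analyses
  sensitive to it should vary the rule.
* GCT parsing targets version 1.2; probe-level formats and array
  normalization are out of scope.
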