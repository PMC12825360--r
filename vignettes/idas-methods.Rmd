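---
title: "Classifying differential-abundance gene signatures by nested ANOVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying differential-abundance gene signatures by nested ANOVA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Differential-abundance (DA) tools (Milo, DA-seq, Scissor, ...) identify the
cell neighborhoods whose frequency shifts with a phenotype — for example,
melanoma cells enriched in patients who respond to immunotherapy. They say
*where* in cell-state space the change happens, but not *which genes* drive
it, or whether a gene's behavior reflects the cell state, the phenotype, or
a combination of both. This package takes the DA-selected cells (consumed
as a per-cell flag, so any upstream method plugs in) and classifies every
gene into an interpretable effect category, then extracts per-category
differential-expression signatures.

## Pseudobulk first

All modeling happens on pseudobulk observations: the mean expression of a
gene over the cells of one sample in one cell state (optionally at one
timepoint), transformed as `log2(mean + pseudocount)`. Testing cells
directly treats thousands of correlated cells as independent replicates and
inflates false discovery; collapsing to per-sample group means restores
approximately independent, approximately Gaussian observations, which is
what the linear-model machinery assumes.

Two conventions are deliberate and configurable rather than hidden:

* the mean is computed on the input value scale and log-transformed
  afterwards (`log2(mean(x) + 1)` by default). A pseudocount of 1 keeps
  all-zero genes at exactly 0 and avoids `-Inf`;
* `min_cells` (default 1) drops groups aggregated from fewer cells, since
  tiny groups carry inflated sampling variance into the pseudobulk matrix.
  Dropped groups are reported, never silently imputed.

The phenotype is a sample-level attribute: cells of one sample that
disagree on the phenotype are an error, not a vote.

## The classification models

For a two-way design (factor `f1` with $I \ge 2$ levels, typically cell
state; factor `f2` with $J \ge 2$ levels, typically phenotype) each gene's
pseudobulk profile $y_{ijm}$ is summarized by one of five fixed-effect
ANOVA models: the full interaction model
$\mu + \alpha_i + \beta_j + (\alpha\beta)_{ij}$, the additive model, the
two single-factor models, and the intercept-only model. For a three-way
design (adding `f3`, typically pre/on treatment, and a subject grouping,
typically patient) there are ten candidates, from the full model with all
two-way interactions and the three-way interaction down to the null model,
each including a per-subject random intercept $u_n$ to absorb repeated
measures from the same patient.

Genes are classified by a staged sequence of nested-model comparisons, with
Benjamini–Hochberg adjustment computed *within each stage across exactly
the genes entering that stage* (mixing stages would mix null
distributions):

1. **No-effect test** (null vs full): genes not selected are `non-sig`.
   The threshold is either a fixed level on (adjusted) p-values or a
   quantile rule that keeps the `level * m` smallest — the quantile option
   exists only at this stage; later stages use a fixed level (default
   0.05, on BH-adjusted p-values by default).
2. **Interaction test** (additive vs full): significant genes are
   interaction genes.
3. **Main-effect tests** on the remainder. In the two-way design a gene is
   `F1` when dropping $\alpha$ hurts the additive fit but dropping
   $\beta$ does not (and symmetrically `F2`). In the three-way design a
   gene is `F1` when the f1-only model is *not* contradicted by the
   additive model while the f2-only and f3-only models *are*; a gene for
   which several single-factor models survive contradicts none of them
   uniquely and is routed to `additive` (reason `ambiguous-main`).
4. **Additive**: everything significant that no earlier stage claimed.
   (The remaining-set reading is used; a literal intersection of the
   earlier, mutually disjoint categories would be empty.)
5. **Three-way interaction test** (all-two-way vs full) splits interaction
   genes into `F1xF2xF3` vs two-way.
6. **Two-way attribution**: dropping each two-way interaction in turn from
   the all-two-way model; exactly one significant drop gives `F1xF2`,
   `F2xF3` or `F1xF3`, anything else is `two-way-combine`.

The categories partition the gene set by construction, and the partition is
asserted on every run. Zero-variance genes are `non-sig` with all stage
p-values set to 1 (an F-statistic of 0/0 carries no signal); genes that
become untestable at some stage (degrees of freedom collapse under missing
factor-level combinations, or a mixed fit fails) are routed to `non-sig`
with a reason code rather than dropped.

## Choice of test statistic

Two-way comparisons use the exact F-test on residual sums of squares;
factor coding is treatment coding, which is immaterial because nested RSS
comparisons are coding-invariant.

Three-way comparisons involve the random intercept. Likelihoods are only
comparable across fixed-effect structures under ML (not REML), and the
package exposes exactly that ML likelihood-ratio chi-square path
(`fit_mixed()`, `lrt_nested()`, `classify_three_way(test = "lrt")`).
However, at realistic cohort sizes — eight patients, 80 pseudobulk
observations — the asymptotic $\chi^2$ reference is anticonservative,
rejecting true nulls at a multiple of the nominal level: the ML variance
estimate is biased low when the fixed-parameter count is an appreciable
fraction of the observation count, and between-subject comparisons have
far fewer effective replicates than the asymptotics assume. The classifier
therefore defaults to the equivalent hypothesis tested as an F-statistic on
the dropped coefficient block of the full model, with
Satterthwaite-approximated denominator degrees of freedom (per-gene REML
fits via `lmerTest`) — the same nested-model hypothesis with a reference
distribution that respects the small number of subjects. The calibration
the default achieves under the global null is exercised directly by the
test suite's benchmark recovery of `non-sig` genes. The degrees of
freedom of the chi-square path count fixed-effect parameters only: the
random-intercept variance is present in both models of every pair, so no
boundary correction applies.

Non-convergent mixed fits are reported per gene and routed to `non-sig`
with a reason; they never abort a run.

## Post-hoc differential expression

Per-category interpretation uses moderated t-statistics with an
empirical-Bayes variance prior estimated from the gene ensemble: a scaled
inverse-chi-square prior $(d_0, s_0^2)$ fit by method of moments on the log
residual variances (inverse-trigamma solve), giving the shrunken variance
$\tilde{s}^2_g = (d_0 s_0^2 + d_g s^2_g) / (d_0 + d_g)$ and $d_0$ extra
degrees of freedom. $d_0 = 0$ recovers the ordinary t-test exactly;
$d_0 = \infty$ (returned when the log-variance dispersion is at or below
its sampling-theory expectation) pools all genes to a common variance. The
implementation is self-contained and is cross-checked in the test suite
against the established empirical-Bayes implementation on shared fixtures.

Three signature extractors share one contrast engine (cell-means OLS per
gene plus a linear contrast of group means):

* **cell-state markers** (`F1` genes): one-vs-rest per state, BH within
  each state, positive markers flagged as `log2FC > 0`;
* **phenotype signatures** (`F2` genes): level-vs-level across all
  observations, labeled up/down using raw `p < 0.001` and
  `|log2FC| > log2(1.5)` by default (both configurable; a stricter
  adjusted-p threshold of 0.01 and a feature-selection cutoff of
  `log2(1.3)` are conventional alternatives);
* **interaction markers**: the top 10 (configurable) one-vs-rest markers
  per state within the interaction gene set — ranked by p, ties by
  decreasing `|log2FC|`, then gene id — are re-contrasted between the two
  phenotypes *within* that state's observations; triples passing the
  thresholds are the cell-state-specific phenotype markers. States whose
  observations cover a single phenotype are skipped with a warning.

When a gene subset is too small to support prior estimation (fewer than 10
usable variances) the engine falls back to ordinary t-tests with a warning
rather than fabricating a prior.

## Spatial front end

For spatially resolved expression the per-sample, per-gene feature is the
nearest-neighbor correlation: each cell is paired with its single closest
other cell by Euclidean distance (ties to the smallest cell index; k = 1,
with directed pairs $(i, nn(i))$ so there is one value per cell), and the
Pearson correlation between own and neighbor expression is computed over
those pairs. A gene with coherent spatial structure in a sample scores
high; salt-and-pepper expression scores near zero. Zero-variance genes are
explicitly undefined (`NA`), never zeroed. The genes x samples feature
matrix then feeds the two-way classifier with sample-level factors; genes
undefined in 20% or more of samples are excluded with a log record, and
remaining undefined entries drop that observation for that gene only.

## The synthetic-data generator

The generator defines the package's study conditions; it is first-class,
tested code. Effects are planted per category from that category's own
generative model. Offset vectors are drawn from centered normals,
recentered to sum to zero within every margin (doubly centered interaction
tables, triply centered three-way arrays) and rescaled to root-mean-square
`effect_sd`. The recentering makes categories identifiable (a main effect
cannot leak into an interaction); the rescaling makes "effect size" mean
the same thing for every gene, factor and term — without it, a two-level
factor would carry a near-zero effect for an appreciable fraction of
planted genes and the planted label would be unverifiable even in
principle.

Benchmark conditions used by the test suite and the acceptance script:

* two-way: $I = 5$, $J = 2$, $m = 6$ replicates, `effect_sd = 2`,
  `noise_sd = 0.5` (effect/noise = 4), 200 genes per category;
* three-way: $K = 2$, 8 subjects split evenly over the two `f2` levels
  (the between-subject factor, as in a patient cohort), one observation
  per subject x state x timepoint, `sigma_u = 0.5`;
* global-null calibration: 2000 intercept-only genes per seed on a
  3 x 2 x 4 design;
* spatial: cells laid out as tight pairs on a jittered grid so each cell's
  nearest neighbor is its pair mate, pair expression bivariate normal with
  the planted correlation — the realized nnCorrelation converges to the
  planted value as the grid grows.

The single-cell generator uses lognormal noise scaled to preserve the
planted group mean. This is simpler than a count model; the classifier
consumes pseudobulk means, which are insensitive to that choice at the
tested depths. What the simulations consequently do *not* probe: library
size and dropout structure, batch effects, non-Gaussian pseudobulk
residuals, unbalanced designs with confounded factors. Passing the
recovery benchmarks shows the staged decision logic and its calibration
are correct under the stated model, not that any real dataset satisfies
that model.

## Numerical conventions

* Nested fixed-effect comparisons with equal RSS give p = 1; an exact full
  fit against an imperfect reduced fit gives p = 0; deviances and RSS
  differences are clipped at 0 against roundoff.
* Rank-deficient designs drop inestimable columns via pivoted QR and
  reduce the parameter count; a stage whose df difference collapses marks
  the gene untestable there.
* Quantile selection breaks boundary ties by lexicographic gene id so runs
  are byte-reproducible.
* All randomness flows from a single seed; identical inputs, policy and
  seed give byte-identical classification tables.

## Known limitations

At most three factors and a single random intercept (no random slopes, no
non-Gaussian responses, no permutation alternatives). The staged procedure
inherits the usual caveat of sequential testing: category boundaries near
the significance threshold are unstable under resampling, which is why the
benchmarks plant effects well above noise. The additive category is a
remainder set and therefore absorbs genes whose main-effect pattern is
ambiguous. nnCorrelation uses a single neighbor; a k-neighbor mean variant
exists behind the `nearest_neighbor`/`nn_correlation` building blocks but
single-nearest is the default and the tested contract.
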