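# idas

Interpretable classification of differential-abundance gene signatures by
nested ANOVA model comparison.

## What problem this solves

Differential-abundance (DA) analysis of single-cell data (Milo, DA-seq,
Scissor, ...) finds the cell neighborhoods whose frequency changes with a
phenotype — say, tumor cells enriched in immunotherapy responders. It does
not say which genes drive the change, nor whether a gene tracks the cell
state, the phenotype, or specifically their combination. `idas` takes the
DA-selected cells (any upstream tool, consumed as a per-cell flag),
aggregates them into per-sample per-cell-state log2 pseudobulk
observations, and assigns every gene to one effect category by a staged
sequence of nested ANOVA model comparisons:

* **two-way designs** (cell state x phenotype): categories `F1`, `F2`,
  `F1xF2`, `F1+F2`, `non-sig`, decided by exact F-tests between the five
  candidate fixed-effect models
  (`mu + alpha_i + beta_j + (alpha beta)_ij` down to intercept-only);
* **three-way designs** (cell state x phenotype x pre/on-treatment, with a
  per-patient random intercept `u_n`): ten categories up to `F1xF2xF3`,
  decided between the ten candidate mixed models — by default with
  Satterthwaite-approximated F-tests on the dropped coefficient block
  (calibrated at small patient counts), optionally by ML likelihood-ratio
  chi-square tests.

Stage p-values are Benjamini–Hochberg-adjusted within each stage; the
stage-1 threshold can be a fixed level or a top-quantile rule. Each
category is then interpreted by empirical-Bayes moderated-t differential
expression (cell-state markers, phenotype signatures, and top-k
cell-state-specific phenotype markers from the interaction set). A spatial
front end computes per-sample nearest-neighbor correlations
(nnCorrelation) from spatially resolved expression and feeds the same
classifier, and a synthetic-data module generates pseudobulk, single-cell
and spatial datasets with known per-gene ground truth.

See `vignettes/idas-methods.Rmd` for the models, assumptions, parameter
defaults and design decisions.

## Worked example

Simulate a two-way benchmark with planted categories, classify, score the
recovery, and pull the phenotype signature:

```r
library(idas)

sim <- simulate_two_way(n_per_category = 50, I = 3, J = 2, m = 4, seed = 7)
gc  <- classify_two_way(sim$pseudobulk, threshold_policy("alpha", 0.05))
print(gc)
#> GeneClassification (two_way design, 250 genes)
#>   threshold: alpha 0.05 on BH-adjusted p
#>
#>      F1      F2   F1xF2   F1+F2 non-sig
#>      46      45      55      55      49

round(recovery_metrics(sim$truth, gc)$recall, 2)
#>      F1      F2   F1xF2   F1+F2 non-sig
#>    0.90    0.90    1.00    1.00    0.98

sig <- phenotype_signature(sim$pseudobulk,
                           genes = gc$gene_id[gc$category == "F2"])
table(sig$label)
#> up-in-p1 up-in-p2
#>       20       25
```

Reading the output: 250 genes were planted, 50 per category. The
classifier recovered 90–100% of each category at the BH-adjusted 0.05
threshold (the 55s in `F1xF2` / `F1+F2` include a handful of misrouted
borderline genes; `recovery_metrics` quantifies exactly which). The 45
recovered phenotype genes split into 20 up-regulated in phenotype `p1` and
25 in `p2` at the default `p < 0.001`, `|log2FC| > log2(1.5)` thresholds.

The same workflow runs from the shell via the thin wrapper in
`inst/cli/idas.R`:

```sh
Rscript inst/cli/idas.R simulate two-way --seed 7 -o out/sim
Rscript inst/cli/idas.R classify --pseudobulk out/sim.pb.tsv \
    --design out/sim.design.tsv -o out/classification.tsv
Rscript inst/cli/idas.R de --pseudobulk out/sim.pb.tsv \
    --design out/sim.design.tsv --classification out/classification.tsv \
    --category F1 -o out/markers.tsv
```

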