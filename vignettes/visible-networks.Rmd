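---
title: "Visible neural networks for multi-omics phenotype prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visible neural networks for multi-omics phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnnomics)
```

## The model

A *visible* neural network restricts its connectivity to edges that have a
biological meaning, so that every neuron corresponds to an entity a
biologist can name. `vnnomics` builds such networks for two omics measured
on the same blood samples:

* **Methylation**: each CpG site (beta value in $[0,1]$) connects to
  exactly one gene — the gene whose transcription start site is nearest in
  base pairs on the same chromosome. The CpGs of a gene converge on a
  *methylation gene node*.
* **Expression**: each gene's (filtered, log-transformed) expression value
  enters as a single input.
* **Combined gene representation**: per gene, one node merges the
  methylation gene node and the expression input through one scalar edge
  each. These two edges are tagged by omic, which is what later allows
  per-gene omic decomposition and omic-specific penalties.
* **Output**: a single neuron; combined gene nodes connect to it directly,
  or through a three-level pathway hierarchy (genes grouped into local
  pathways, locals into mid-level groups, mids into a handful of global
  categories — the KEGG functional hierarchy has 321/44/6 such nodes).
  Genes without any pathway annotation keep a *skip connection* straight
  to the output, so every gene remains connected.

Only the gene universe shared by both omics is used: the sorted
intersection of the CpG-annotated genes and the expressed genes is the
canonical gene order for every mask, weight vector and report.

Classification networks end in a sigmoid output trained with weighted
binary cross-entropy (class weights inverse to prevalence,
$w_1 = n/2n_1$, $w_0 = n/2n_0$); regression networks use ReLU activations
throughout, trained with mean squared error. The output neuron's bias is
initialized to the training-set outcome mean.

## Interpretation by weight-path products

For every path from an input to the output, the product of the absolute
edge weights along the path is computed; an input's raw score is the sum
of these products over all its output-reaching paths, and the final score
is the proportion of the total over all inputs. Hidden-node scores
propagate the input proportions forward along absolute weights and
renormalize within a layer. The per-gene omic split partitions the
path-product mass arriving at a combined gene node by the omic tag of the
incoming edge. All of this is computed by dynamic programming over the
layer DAG — mathematically identical to explicit path enumeration, which
the test suite verifies on small random networks. Biases are ignored
(scores describe weights); multiplying any single downstream layer by a
constant cancels in the normalization.

Because trained weights depend on the random initialization, contribution
reports are computed per replicate seed and aggregated as mean and
standard deviation across seeds; the replicate seeds are
`base_seed + 0..n_seeds-1` and are recorded in every artifact.

## Evaluation protocol

`cohort_cv()` implements leave-one-cohort-out cross-validation: one cohort
is the held-out test set; the pooled remaining cohorts are split 75/25
into training and validation (seeded, one split per fold); the
hyperparameter grid (learning rates 0.01, 0.001, 0.005, 0.0001 crossed
with L1 strengths 0.01, 0.001, 0.0001) is searched on the validation set;
the best combination is retrained with ten seeds and each replicate is
evaluated on the test cohort. Grid combinations whose validation metric
ties the best within a small tolerance (0.005 AUC / 1% RMSE by default)
are resolved towards the stronger L1 penalty and then the earlier best
epoch — the one-standard-error rule familiar from penalized regression;
under cohort shift the shorter-trained, more regularized model of a
validation tie transfers better. Fold means are summarized with a
normal-approximation 95% interval, mean $\pm 1.96\,sd/\sqrt{k}$.
Classification models are selected and reported by AUC, regression models
by RMSE together with explained variance
($1 - \mathrm{Var}(y-\hat y)/\mathrm{Var}(y)$).

## Numerical and design choices

**Hidden activation.** Descriptions of this architecture family
sometimes specify an inverse hyperbolic tangent (arctanh) hidden
activation. Taken literally,
$\mathrm{atanh}$ has domain $(-1,1)$: unbounded pre-activations must be
clipped (we clip to $\pm(1 - 10^{-5})$, configurable), the clipped
function is flat outside its domain (zero gradient — saturated units die),
and inside it is *expansive*, with derivative $\ge 1$ growing without
bound near $\pm 1$. In our experiments networks with this activation
plateau near chance at realistic sizes while identical runs with `tanh`
train well; regularized linear models on the same features confirm the
signal is learnable. The package therefore defaults to `tanh` for hidden
layers in classification (ReLU in regression, as stated for that task)
and keeps `arctanh` available via the builders' `hidden` argument,
implemented exactly as defined — clipped forward value, and for training a
capped pseudo-derivative ($\min(1/(1-z^2), 10)$ inside the domain, 10
outside) so saturated units retain a bounded, finite gradient.

**Input scaling.** Expression is `log1p`-transformed and z-scored per
gene; methylation betas are z-scored per CpG. Both use training-set
statistics only, so no information leaks across splits. Zero-mean,
unit-scale inputs keep the bounded hidden activations in their responsive
range; with raw betas (mean ≈ 0.5, small variance) training is markedly
slower and less accurate. Both transforms are switches
(`scale_expression`, `scale_methylation`, `log_expression`) on
`prepare_inputs()` and `cohort_cv()`.

**Initialization.** Glorot-uniform restricted to mask edges, with fan
terms computed from the mask's mean in/out degree rather than the full
layer dimensions — for very sparse masks the full-dimension fan would
collapse the weight scale. Fully seeded.

**Optimizer and penalties.** Adam (configurable learning rate, batch size
64, at most 100 epochs by default) with early stopping on validation loss
(patience 10) and restoration of the best-validation-epoch weights. L1
penalties enter as subgradients $\lambda\,\mathrm{sign}(w)$: the base
penalty on the combined gene layer (sparsifying the per-gene merge edges
performs gene selection; penalizing the CpG aggregation layer as well
starves the methylation representation and, measured on held-out
cohorts, costs both accuracy and replicate stability; the placement is
a builder option, and the ME-only architecture keeps the penalty on its
methylation gene layer), plus
an optional omic-specific penalty on the combined-layer edges carrying
one omic's tag (`omic_l1 = list(tag = "ge", lambda = 0.01)`), which
probes whether the penalized omic carries information the other omic
cannot supply. An optional low-learning-rate settle phase
(`finetune_epochs`) is available but off by default.

**Degenerate inputs.** Single-class training labels, empty gene
intersections, all-zero weight interpretations and constant activations
(undefined PCA) are errors with specific messages rather than silent
results. Nearest-gene ties break deterministically toward the smaller TSS
coordinate, then the lexicographically smaller gene id. CpGs on
chromosomes without genes, or mapping to genes outside the omics
intersection, are dropped and counted.

## The synthetic-data generator

Real multi-omics consortium data is access-controlled, so the package
ships a generator (`simulate_omics()`, `simulate_classification()`) that
emulates the *structure* of a multi-cohort methylation + expression
study: four cohorts of 250 samples by default; 500 genes with on average
5 CpGs each (Poisson, minimum 1); methylation betas from a
logistic-transformed Gaussian with a per-gene latent factor shared by the
gene's CpGs; log-normal expression passing a 1-CPM-average filter by
construction; a binary covariate ("sex") shifting a designated gene block
in both omics; per-cohort phenotype shifts emulating the age
heterogeneity between population cohorts; and 5 causal genes whose
standardized gene-level methylation summary and log-expression enter the
phenotype linearly, with Gaussian noise (regression) or through a
logistic link with controlled prevalence (classification). The logistic
scale is set so the generator's Bayes-optimal AUC — the empirical AUC of
the true linear score — is at least 0.95. CpG positions are laid out
(10 kb gene spacing, CpGs within ±2 kb of their TSS) so the nearest-TSS
rule reproduces the planted CpG→gene map exactly.

Two switches matter for the omic analyses. `omic_specificity` makes a
fraction of causal genes single-omic (alternating methylation-only /
expression-only). `shared_latent = TRUE` makes each causal gene's
expression mirror its methylation latent, so the causal signal is
genuinely redundant between the omics; without it the two arms carry
independent information and a well-trained network will — correctly —
refuse to abandon a penalized omic.

What the generator does **not** emulate: array probe chemistry, batch
effects, cell-type composition, realistic linkage/co-methylation
structure, or non-linear gene-gene interactions. Passing the package's
experiments therefore demonstrates that the machinery recovers planted
linear-at-gene-level signal across cohort shifts — not that any
biological claim about real cohorts is reproduced.

## Study conditions used in the validation experiments

These problem sizes are the package's chosen desk-scale study conditions
(they also bound the runtime of the test suite):

* **Planted-gene recovery**: the generator defaults (4 × 250 samples,
  500 genes, 5 causal), ME+GE network, full grid search, 10 replicate
  seeds per fold, with a training budget of 60 epochs per fit. Under
  cohort shift, longer budgets overfit the pooled-cohort validation set
  and degrade cross-cohort transfer — qualitatively the same
  validation/test divergence the deeper architectures show — so the
  experiment caps the budget below the package-wide default. Checked:
  mean held-out-cohort AUC, and recovery of the causal genes among the
  top-5 mean contributions.
* **Omic-specific penalty probe**: 4 × 150 samples, 200 genes, 8 causal,
  low CpG noise (`me_noise_sd = 0.1`); one fold (first cohort held out),
  learning rate 0.005, base L1 $10^{-3}$, expression penalty
  $\lambda = 0.01$, 300 epochs with patience 30, two replicate seeds per
  arm. Arms: redundant (`shared_latent = TRUE`) with and without the
  penalty, and omic-exclusive (`omic_specificity = 1`) with the penalty.
  The redundant arm should abandon expression at no AUC cost; the
  exclusive arm should retain it. Eight causal genes (rather than the
  recovery experiment's five) give the surviving methylation path enough
  weight mass that the contribution shares resolve cleanly against the
  optimizer's small-weight noise floor.
* **Activation-pattern PCA**: 2 × 150 samples, 100 genes, a 15-gene sex
  block with a 2-SD feature shift; silhouette of the two covariate groups
  on the first principal component of the combined-gene activations.

## Known limitations

* The training engine is plain R on sparse matrix algebra; it is sized
  for annotation-driven networks with up to a few thousand inputs, not
  for the full 450k array at interactive speed.
* Subgradient L1 under Adam leaves small oscillating weights rather than
  exact zeros; contribution shares of irrelevant inputs therefore have a
  noise floor proportional to the learning rate.
* Contribution scores quantify what the trained network uses, which is
  predictive, not causal; different seeds can distribute mass differently
  across correlated inputs, which is why reports aggregate over seeds.
* The cohort-wise protocol fixes one seeded 75/25 split per fold; it does
  not re-split per hyperparameter combination.
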