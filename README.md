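# logrankclust

Survival-guided clustering for R: train neural networks to partition
subjects into prognostically distinct groups by directly maximising the
heterogeneity of their survival curves, instead of clustering on feature
similarity and hoping the clusters matter for outcome.

## Who this is for

Biostatisticians and computational oncologists who have right-censored
time-to-event data (e.g. laboratory panels or imaging with overall-survival
follow-up) and want *decision-boundary-style* risk groups — the shape of
output a staging system provides — discovered directly from the data,
without pre-labelled risk categories.

## The statistic at the core

For `k` groups and unique event times `t_j`, the classical multivariate
logrank test compares observed group events `O_{g,j}` with their
expectation under the null,

    E_{g,j} = d_j * R_g(t_j) / |R(t_j)| ,

accumulates the score vector `Z_g = sum_j (O_{g,j} - E_{g,j})`, and refers

    L = Z' V^- Z

to a chi-square distribution on `k - 1` degrees of freedom, where `V` is
the hypergeometric variance–covariance of the event allocation.

`logrankclust` replaces the hard group labels by per-subject probability
vectors `p_i` (a softmax network output).  Observed events and at-risk
masses become probability-weighted sums ("partial" events and risk sets),
which makes `L` a smooth function of the network parameters.  Because the
unconstrained maximiser of `L` is a degenerate partition, the training loss
subtracts an asymmetric barrier on the mean assignment proportions,

    loss = -L + lambda * P(p_bar),
    P(p) = (1/k) * sum_g 1 / (p_g^a - p_g^{2a}) - 4,   a = log(1/2)/log(1/k),

which is exactly zero at balanced proportions and diverges as any
proportion approaches 0 or 1.  Gradients of the full objective — through
the risk sets, the covariance and the barrier — are computed analytically
and verified against finite differences in the test suite.

The package ships an MLP (tabular) and a CNN (image) trained with AdamW
under event-stratified 5-fold cross-validation, seeded synthetic cohort
generators with planted prognostic classes, and evaluation tools:
cluster-to-truth matching, per-class AUROC/AUPRC, Harrell's concordance
with bootstrap confidence intervals, Kaplan–Meier summaries and paired
bootstrap model comparison.

## Worked example

Two planted prognostic classes (hazards 2 vs 0.3 per time unit, feature
means four standard deviations apart, 30% censoring), recovered without
ever showing the model a label:

```r
library(logrankclust)

spec <- synthetic_spec(n_subjects = 600, k_classes = 2,
                       class_weights = c(0.5, 0.5),
                       class_separation = 4, hazards = c(2, 0.3), seed = 42)
sim  <- simulate_tabular_cohort(spec)

cfg <- train_config("mlp", epochs = 30, seed = 42)
cv  <- cross_validate(sim$cohort, sim$features,
                      mlp_spec(10, k_outputs = 2), cfg)

report <- evaluate_clustering(cv, sim$cohort, true_labels = sim$labels,
                              n_boot = 1000, seed = 42)
report
```

which prints (exact output of the code above):

```
Evaluation: k = 2, c-index 0.701 (0.681-0.721), logrank p = 4.57e-61
matched AUROC: 0.996 0.996 | AUPRC: 0.996 0.997
```

Reading the numbers: the held-out clustering separates survival strongly
(the logrank p-value is descriptive here, since the grouping was optimised
for separation), the cluster risk ranking orders individual event times
with concordance about 0.70, and the matched per-class AUROC/AUPRC
measure how well the unsupervised clusters recover the planted classes
after the optimal cluster-to-truth permutation — here almost perfectly.
Recovery of three or more classes under weaker separation is harder; the
methods vignette discusses the limits in detail.

A `survival_cohort` can also be read from CSV (`time,event,features...`)
with `read_cohort_csv()`, and a thin CLI with `simulate`, `train`,
`evaluate` and demo subcommands is installed under `inst/cli/`.

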