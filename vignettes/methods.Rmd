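---
title: "Methods: a discrete Bayesian belief network for organizational patient-safety factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a discrete Bayesian belief network for organizational patient-safety factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safetybbn)
```

## The problem

Hospital staff surveys aggregate to one record per hospital: eight
organizational-factor scores on a 0--10 scale (equality/diversity/inclusion,
safety culture, staff health and wellbeing, support from immediate managers,
perceived quality of care, team working, and two safe-environment scores for
bullying/harassment and violence) and one outcome, the proportion of staff
who report having seen patient-safety errors, on [0, 1]. The package models
the joint distribution of these nine variables with a discrete Bayesian
belief network (BBN), learned from data rather than elicited from experts,
and uses it for two things:

1. **Prediction** -- the cross-validated accuracy of predicting the
   discretized error proportion from the factor scores, against a
   majority-class baseline.
2. **Scenario analysis** -- conditioning each factor on its worst or best
   band and reading off the change in the probability of the worst error
   band, which yields *vulnerability* and *resilience* rankings of the
   factors.

Raw hospital-level microdata are not redistributable, so the package ships a
calibration (marginal moments plus a Spearman rank-correlation structure for
`n = 413` hospitals) and a generator that emulates the survey from it. Every
downstream method is exercised on that synthetic emulation or on a
user-supplied CSV of real records.

## Synthetic survey generation

The generator is a Gaussian copula with clipped-normal margins.

* **Copula choice.** The calibration records Spearman rank correlations.
  For a Gaussian copula, latent Pearson correlation $r$ induces Spearman
  correlation $\rho_S = \tfrac{6}{\pi}\arcsin(r/2)$ between any two
  continuous margins, independent of the margins themselves. We therefore
  set the latent correlation to $r = 2\sin(\pi\rho_S/6)$
  (`spearman_to_latent_pearson()`) so the generated sample attains the
  prescribed rank correlations without further tuning.
* **Margins.** Each latent normal coordinate is mapped through its own
  normal CDF/quantile pair to a $N(\mu, \sigma^2)$ margin with the
  calibrated mean and SD, then clipped to the calibrated observed
  [low, high]. At the calibrated dispersions the clipping is rare (the
  observed ranges sit roughly $\pm 3\sigma$ from the means), so moments
  and rank correlations are essentially unaffected, while impossible
  values (scores outside the range ever observed) cannot occur.
* **Correlation repair.** Printed correlation tables are rounded to two
  decimals and assembled block-wise, so the 9x9 matrix carries no
  positive-definiteness guarantee. `repair_correlation()` clips eigenvalues
  at a floor of `1e-8` and renormalizes the diagonal, iterating, with a
  convex blend toward the identity as a fallback when the alternating step
  stalls on the PSD boundary. The maximum entry-wise perturbation is
  reported as an attribute. The packaged calibration happens to be positive
  definite both before and after the latent transform, so no repair fires
  by default; the machinery exists for user calibrations.
* **What is and is not emulated.** The generator matches means, SDs,
  observed ranges and the full Spearman structure. It does *not* reproduce
  skewness, kurtosis or tail behaviour of the real survey -- a Gaussian
  copula with symmetric margins is the maximum-entropy-style neutral choice
  given only the published summaries. One practical consequence is
  discussed under *Validation* below.

## Discretization

`fit_uniform_width()` splits each variable's **observed** range into `k`
equal-width bins (`k` = 2 or 3), labelled s1 (low score / few errors) to sk.
Binning the theoretical 0--10 scale instead would leave most states empty,
because the hospital-level SDs ($\approx$ 0.2--0.3) are tiny relative to the
scale. Conventions:

* bins are left-closed / right-open, except the last bin, which is closed,
  so the observed maximum lands in state `k` and a value exactly on an
  interior cutpoint takes the higher state;
* a scheme reused on new data clamps out-of-range values to the extreme
  states, warns, and reports the clamp count in an attribute;
* note the orientation: for factor scores s1 is the *worst* band (low
  score), while for the error proportion s`k` is the worst band (most
  errors).

## Structure learning

Three learners over the nine discrete variables:

* **PC** (`learn_pc()`): constraint-based skeleton search with conditioning
  sets of growing size, using the $G^2$ log-likelihood-ratio test of
  conditional independence at $\alpha = 0.05$. Degrees of freedom are
  computed per stratum, dropping empty rows/columns, which keeps the test
  calibrated in sparse strata. V-structures are oriented from separating
  sets, Meek rules R1--R3 are closed, and the remaining undirected edges
  are extended to a DAG deterministically (lexicographic order with cycle
  flips), so one run returns one DAG.
* **Greedy thick thinning** (`learn_gtt()`): starts from the empty graph,
  repeatedly adds the single best-scoring admissible arc (thickening), then
  repeatedly deletes the best-scoring removal (thinning), under the BDeu
  score.
* **Bayesian search** (`learn_bayesian_search()`): hill climbing over
  add/delete/reverse moves with random restarts (default 20) from random
  DAGs, seeded for reproducibility; the best-scoring climb wins.

Scoring uses **BDeu** with equivalent sample size `ess = 1`: a small,
conventional prior weight appropriate for `n` in the low hundreds, under
which the score is decomposable (cached per family) and likelihood
equivalent, so covered-edge reversals tie exactly. Both greedy learners
expose their accepted-move score traces, which tests verify to be strictly
increasing.

## Parameters and inference

`fit_cpts()` estimates each conditional probability table with a Laplace
pseudocount of $\alpha = 1$. With up to $3^2$ parent configurations over 413
records, unobserved configurations occur; the pseudocount keeps every CPT
row a proper distribution and every joint probability positive, which exact
inference and the scenario engine rely on. (Setting `alpha = 0` is allowed
but errors informatively if a configuration is unobserved.)

`posterior_marginals()` performs exact inference by variable elimination
with a min-degree elimination ordering. The test suite checks it against an
independent full-joint enumeration oracle on dozens of random networks.

## Validation

`kfold_validate()` reports a confusion matrix for predicting the error
state. Design decisions:

* the structure is learned **once on the full data** and only the CPTs are
  refit per fold (the published protocol for this study size; refitting the
  structure per fold is available via `refit_structure = TRUE`);
* folds come from a seeded shuffle of `rep(1:k, length.out = n)`, so every
  record is predicted exactly once and runs are reproducible;
* prediction is the MAP state of the posterior given the record's factor
  states, ties broken toward the lower state, with the prior MAP as
  fallback;
* accuracy = trace / n (`accuracy()`), reported next to the majority-class
  baseline (`majority_baseline()`). Defaults: 6 folds, 3 states.

**A known limitation worth stating plainly.** Under the calibrated
generator the conditional distribution of the 3-state error band given any
single factor band never moves the argmax away from the middle state: the
Bayes-optimal classifier on the synthetic population *is* the majority
rule. This is a property of the elliptical, thin-tailed emulation (real
surveys have skew and outliers that carry extra signal), not of the BBN
machinery; fitted models at `n = 413` therefore hover at, and only
occasionally above, the baseline. The scenario rankings, which read
probability shifts rather than argmaxes, are unaffected and replicate
stably.

## Scenario analysis

`backward_propagation()` conditions on an error state and reports each
factor's posterior shift (total-variation distance, halved L1).
`impact_assessment()` conditions each factor, one at a time, on its worst
band (s1, low score) and best band (s`k`) and records the change, in
percentage points, of $P(\text{error} = \text{worst band})$. Two choices to
note:

* this is **conditioning, not intervention**: the question asked is "what
  do we expect of hospitals observed in this band?", which matches
  evidence propagation in a BBN; no causal do-operator semantics are
  claimed;
* the worst error band defaults to the highest state of the target (most
  errors reported).

`rank_factors()` turns the s1 column into the *vulnerability* ranking
(largest increase first) and the s`k` column into the *resilience* ranking
(most negative change first), with ties sharing averaged ranks so rank sums
are invariant. `spearman_rank_corr()` compares two rankings by Pearson
correlation of the rank vectors, which is the tie-corrected Spearman
coefficient.

## Defaults at a glance

| Quantity | Default | Why |
|---|---|---|
| states `k` | 3 | low/medium/high bands; 2 available for sensitivity |
| CI test level | 0.05 | conventional; per-stratum dof reduction |
| BDeu `ess` | 1 | weak prior for n in the hundreds |
| restarts / max iterations (BS) | 20 / 500 | plateaus well before either limit at 9 nodes |
| CV folds | 6 | 413 / 6 ≈ 69 records per fold |
| pseudocount `alpha` | 1 | proper CPTs under unobserved parent configs |
| worst error band | highest state | target is an error proportion |

All problem sizes (nine variables, `n = 413`, two or three states) are the
package's own modelling choices for this application; nothing in the
machinery is restricted to them.

## One run, end to end

```r
library(safetybbn)
report <- run_pipeline(pipeline_config(states = 3, algorithm = "pc",
                                       k_folds = 6, seed = 1))
print(report)
```

The numbered scripts under `analysis/` perform the same steps one stage at
a time, persisting every intermediate artifact under `results/`.
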