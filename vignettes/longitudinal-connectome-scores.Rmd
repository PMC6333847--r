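---
title: "Longitudinal connectome progression scores: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal connectome progression scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Parkinson's disease (PD) neurodegeneration begins years before clinical
diagnosis.  A progression marker usable in that prodromal window should
(i) be computable from non-invasive imaging, (ii) measure *change over
time* rather than a cross-sectional state, and (iii) generalize from
manifest disease to at-risk subjects without retraining.  `longconn`
implements such a marker from paired diffusion-MRI connectomes.

The data unit is a symmetric 16x16 connectome over a subcortical
parcellation of the nigrostriatal system (left/right red nucleus,
substantia nigra, subthalamic nucleus, caudate, putamen, external and
internal globus pallidus, thalamus), with three connectivity metrics per
area pair: streamline count, streamline-averaged fractional anisotropy
(FA) and streamline-averaged mean diffusivity (MD).  For one subject
with baseline and year-1 follow-up scans, each metric's matrix is
vectorized over the strict upper triangle (120 pairs) and the
longitudinal feature is the element-wise absolute difference

$$x_d = |x_{fu} - x_b|,$$

the per-edge L1 distance with the sign discarded: the marker models
*magnitude* of connectivity change, not its direction.  The three metric
blocks are concatenated into a 360-feature vector.  No feature selection
is applied.

A logistic regression with L1 penalty (coordinate descent, fixed
inverse-regularization C = 1, never tuned) is trained to separate
Control from de novo PD longitudinal vectors under stratified k-fold
cross-validation with k equal to the PD group size (21 in the emulated
design, so test folds hold 2 or 3 subjects and class balance is
preserved in every fold).  Each Control/PD subject is scored
out-of-fold; the held-out prodromal (PROD) cohort is scored by
unweighted model averaging of the k fold models' probabilities and never
enters any training fold, permutation null, or threshold choice.

Feature relevance uses a label-permutation null: per fold, the same
model is refit on the training features with labels randomly swapped
(class counts preserved), and each observed weight is expressed as the
absolute distance from the null mean in null standard deviations.
Connections at or above five null SDs are reported as prominent - a
deliberately conservative cut motivated by the Chebyshev inequality.

Evaluation reports the Mann-Whitney AUC with a nonparametric bootstrap
percentile interval (1000 repetitions, each keeping 80% of the
prediction-label pairs with replacement; the 5th and 95th percentiles
are reported, i.e. a 90% interval), the threshold maximizing
$\mathrm{sens}^2 + \mathrm{spec}^2$, confusion metrics at that threshold
and at the conventional 0.5, and a Wald p-value for the score in a
logistic model adjusting for age and gender.  The PROD cohort is
subtyped by the Control/PD-derived threshold (score >= threshold =
PD-like subgroup 1), and clinical trajectories (UPDRS-III, H&Y, MoCA,
SDM over baseline / 1y / 1.5y) are summarized per subgroup as mean, SD
and interquartile range - deliberately without significance tests at
these subgroup sizes.

## The synthetic cohort: what it emulates and what it does not

The study's imaging data are access-gated, so the package carries a
generator whose defaults are the study's stated world: 30 Controls, 21
PD, 16 PROD; within-subject baseline/follow-up correlation rho = 0.9;
five affected (pair, metric) connections - two streamline-count and
three FA edges among the pallidal, putaminal, caudate and thalamic
nodes - carrying a longitudinal effect of 3 change-SD units in PD-like
subjects; 11/16 of PROD subjects drawn from the PD-like change model
(matching the reported subgroup split), with the prodromal effect
attenuated by 0.8 on the grounds that prodromal degeneration is subtler
than manifest disease.

Marginals respect each metric's support: counts are negative-binomial
(pair-specific log-normal means, median about 50 streamlines,
dispersion 10), FA is Gaussian jitter (SD 0.04, a realistic test-retest
magnitude) clamped to [0, 1], MD is Gaussian jitter (SD 0.035e-3) around
0.7e-3 mm^2/s floored at a small positive value.  Follow-up values are
correlated redraws on the sampling scale, so the noise-only longitudinal
change has SD $\sigma\sqrt{2(1-\rho)}$ per edge.  Zero-streamline cells
force FA = MD = 0 (no streamlines, nothing to average), which produces
occasional large FA/MD changes when an edge flickers across zero - a
real feature of sparsely connected pairs.  Crucially, groups differ
*only* in longitudinal change: baseline levels carry no group
information, so a classifier can only succeed by reading progression.
Covariates mirror the cohort table (age ~ N(66, 5) truncated, male
fractions 19/30, 17/21, 14/16; scan intervals ~400 days).  Clinical
scales follow the latent class: PD-like subjects drift upward on
UPDRS-III/H&Y; control-like subjects stay near zero and stable; MoCA
and SDM are absent at the 1.5-year visit, as in the emulated protocol.

What the generator does **not** emulate: scanner/site effects,
registration or tractography failure modes, baseline group differences,
realistic spatial covariance between edges, conversion dynamics.  A
green test therefore establishes that the pipeline recovers implanted
longitudinal structure under honest nulls - not that the published
effect sizes are reproducible; those were measured on restricted data
and are out of desk-scale reach.

## Numerical and design choices

- **Edge order**: nodes are ordered left-then-right within structures
  listed in the atlas order; pairs enumerate the strict upper triangle
  row-major.  The diagonal is excluded: self-loops are not connections
  and their FA/MD are ill-defined.  Any fixed order is statistically
  equivalent; tables should be matched by (pair, metric), not index.
- **Regularization mapping**: the untuned scikit-learn-style C = 1 maps
  to the coordinate-descent penalty lambda = 1/(nC).  The elastic net
  mixes at 0.5; all hyperparameters are frozen by construction.
- **Scaling**: per-training-fold z-scoring is the default so that
  count-scale features do not dominate the penalty over FA/MD-scale
  features; `scaling = "none"` reproduces a raw-feature run.  The
  setting is recorded in every report.  Constant features scale to zero
  rather than dividing by zero.
- **SVM and random forest**: no R implementation ships in this
  environment, so the linear SVM is a primal squared-hinge minimizer
  (L-BFGS) with the margin squashed through the logistic function to
  land in [0, 1] (how the original analysis mapped SVM outputs to
  scores is unstated), and the random forest is bagged Gini CART with
  mtry = sqrt(p), 100 trees, depth 8.  Both are menu comparators; the
  primary model is the L1 logistic regression.
- **Permutation null**: relabellings preserve class counts; the default
  1000 permutations can be lowered (floor 100) for speed.  Features the
  null never selects have SD ~ 0: if the observed weight also sits at
  the null mean the distance is zero and z = 0; only a nonzero distance
  over zero spread is flagged degenerate (NA), never infinite.
- **Cross-fold aggregation of z**: the default is the **median** across
  folds.  Under the null, the per-fold z of a sparse weight is
  heavy-tailed - a feature the permutations select with probability p
  scores roughly $1/\sqrt{p}$ on the rare occasions the observed fit
  selects it - and mean aggregation lets a minority of spiked folds
  push a noise feature over the prominence cut (measured ~1-1.5% of
  features at z >= 5 on effect-free cohorts, above the ~1% a
  conservative 5-SD rule should allow; the median measures ~0.8% and
  recovers implanted edges equally well).  Mean and max are available
  and the rule is recorded in the output.
- **Threshold search**: candidate thresholds are midpoints between
  consecutive distinct scores (plus the two extremes), the decision
  rule is score >= t, ties in $\mathrm{sens}^2+\mathrm{spec}^2$ break
  toward the lower threshold (favouring sensitivity in a screening
  context), and a perfectly separating score returns the midpoint of
  the separating gap.
- **Bootstrap**: prediction-label pairs are resampled jointly,
  unstratified (stratification is not described in the emulated
  procedure); single-class resamples are redrawn.  The interval is the
  raw 5th/95th percentile pair of the replicate AUCs and is labelled as
  such.
- **Separation fallback**: when the covariate-adjusted logistic fit
  separates perfectly, a Jeffreys-penalized (Firth) fit computed
  in-package supplies the Wald p, and the result is flagged.
- **Subtyping**: score exactly at the threshold goes to the PD-like
  subgroup - a subject at a screening cut-off should be flagged.
- **Determinism**: one master seed derives separate streams for cohort
  structure, connectome noise and clinical scores; fold splits, refits
  and bootstraps are seeded; identical config + seed give byte-identical
  output files (numerics are written at full precision, `%.17g`).

## Scaled-down checks

The test suite exercises the full design at reduced Monte-Carlo budgets
(100-permutation nulls, 5-20 simulation repetitions) so the default run
stays within minutes; the package defaults remain at the stated 1000
permutations and bootstrap repetitions.  Known limitations: the null
false-positive rate of the 5-SD rule under *mean* aggregation exceeds
1% (see above); the generator's independence across edges makes
recovery easier than correlated real connectomes; and model-menu
rankings on synthetic cohorts are qualitative, not magnitude
reproductions.

## A worked run

```{r, eval = FALSE}
library(longconn)

cfg <- simulation_config(seed = 1L)
res <- run_full_analysis(cfg, n_perm = 200, n_boot = 1000)
res
res$prominent[, c("node_a", "node_b", "metric", "z")]
```
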