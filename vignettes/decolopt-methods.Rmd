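---
title: "Models and methods behind decolopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind decolopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decolopt)
```

## The problem

Microbial decolorization of azo textile dyes such as Direct Blue 71 is a
bioprocess whose yield depends jointly on dye loading, nitrogen supply and
pH. `decolopt` implements the standard optimization workflow for such a
process: a three-factor Box--Behnken experiment, a second-order response
surface fitted by least squares with full ANOVA diagnostics, a small
feedforward neural network trained by batch backpropagation as a
non-parametric competitor, desirability-based location of the operating
optimum, and a comparison layer (R², adjusted R², absolute average
deviation) that arbitrates between the two predictors.

The canonical dataset shipped with the package
(`db71_runs()`) is a 17-run Box--Behnken table over dye concentration
(50--150 ppm), yeast extract (0.5--3 g/L) and pH (6--7.5), with measured
decolorization percentages between 54.43 and 94.9 and five replicated
center runs.

## Coding and the Box--Behnken design

Factors are coded as $x = (X - m)/h$ where $m$ is the midpoint and $h$ the
half-range of the design limits, so the limits map to $\pm 1$ and the
center to 0. Two consequences drive everything downstream: the intercept
of the coded quadratic is the predicted response at the center point, and
the 3-factor Box--Behnken columns are mutually orthogonal for the linear
and interaction terms ($\sum x^2 = 8$ for linear, 4 for interaction
columns), which makes the partial sums of squares coincide with sequential
ones for those terms.

`bbd_design()` emits the 12 edge runs in factor-pair blocks (AB, AC, BC;
within a block the $(-,-), (+,-), (-,+), (+,+)$ order) followed by the
center replicates. The canonical dataset's printed order is kept as data
order; freshly built designs can be shuffled with a seed, since run
randomization is part of the method but no published order exists to
reproduce. Natural settings are stored at full precision -- pH 6.645 is
not rounded to a grid.

Center replication defaults to 5 (17 runs total). The replicates are the
only source of a pure-error estimate, so fewer than 2 center runs
silently removes the lack-of-fit decomposition rather than fabricating
one.

## The quadratic response surface

`fit_quadratic()` fits the 10-term model
$$\hat y = b_0 + b_1 A + b_2 B + b_3 C + b_{12}AB + b_{13}AC + b_{23}BC +
b_{11}A^2 + b_{22}B^2 + b_{33}C^2$$
by ordinary least squares (delegated to `lm()`); rank deficiency is
reported naming the collinear terms rather than silently dropping them.
The ANOVA follows the Design-Expert conventions this literature reports:

* per-term sums of squares are partial (type III) -- the residual-SS
  increase when the term alone is deleted from the full model;
* the residual splits into lack of fit (between distinct settings) and
  pure error (within replicated settings), grouped by identical coded
  rows;
* $R^2 = 1 - SS_{res}/SS_{tot}$; the "ratio of identical sums" form
  sometimes printed for this quantity is degenerate and not used;
* PRESS is the leave-one-out deletion statistic
  $\sum_i (e_i/(1-h_{ii}))^2$, with predicted
  $R^2 = 1 - \mathrm{PRESS}/SS_{tot}$;
* adequate precision is
  $(\max_i \hat y_i - \min_i \hat y_i)/\sqrt{p\,\hat\sigma^2/n}$ with
  $p = 10$ terms; values above 4 indicate a usable signal;
* internally studentized residuals $e_i/(\hat\sigma\sqrt{1-h_{ii}})$ are
  exported with normal plotting positions from the
  $(i - 0.375)/(n + 0.25)$ rule.

On the canonical dataset this machinery reproduces the published
statistics to printed precision: model $F = 47.15$, lack-of-fit
$F = 2.35$, $R^2 = 0.9838$, PRESS $= 435.07$, predicted $R^2 = 0.8252$,
adequate precision $= 21.101$.

Numerical edge cases are handled explicitly: a leverage of 1 (a run the
model interpolates exactly, e.g. the single center of a 13-run
Box--Behnken) makes PRESS undefined -- `press_stat()` errors and
`rsm_anova()` degrades to `NA` with a warning; a zero residual variance
makes adequate precision infinite (warned); an exact fit returns all-zero
studentized residuals instead of 0/0 noise.

## The neural network

`train_mlp()` implements a 3--H--1 multilayer feedforward network trained
by full-batch gradient descent with momentum on the mean squared error of
scaled outputs -- classical batch backpropagation. Inputs use the coded
$[-1,1]$ scale; the response is mapped affinely from $[0,100]$ % into the
output transfer's working range ($[0.05, 0.95]$ for a sigmoid output,
$[-0.9, 0.9]$ for tanh), keeping targets away from the saturated tails.
Defaults (learning rate 0.1, momentum 0.9, initialization $\pm 0.3$, up to
100{,}000 epochs, early stop at a scaled training RMSE of $10^{-3}$, best
of 10 seeded restarts) are conventional settings for this trainer; the
commercial tool used in the original study does not disclose its
internals, so these are the package's own choices and every one is
overridable through `mlp_control()`. Gradients are analytic and are
checked against central finite differences in the test suite; a fixed
configuration is bit-reproducible because restart $r$ draws its weights
from seed $\texttt{seed} + r - 1$.

### The replicate ceiling

The published training/testing split holds out runs 3, 6, 9, 13 and 16,
leaving 12 training runs of which four are center replicates with
identical inputs and different measured responses. No deterministic map
from the three inputs can fit those four runs closer than their common
mean, which bounds the training SSE below by the replicate scatter
(9.95 squared-%) and hence caps the training RMSE at 0.911 % and the
training Pearson $R^2$ at 0.98405 (the supremum over the one free
degree of freedom, the shared center prediction). The trainer reaches
this ceiling to within $10^{-6}$, and an independent trainer (`nnet`)
lands on the same floor. Published claims of 0.999 on this split cannot
be reproduced by any input--output model and are treated as an artifact
of the original tool's undisclosed bookkeeping (its topology label
suggests a fourth input). The honest capacity check -- interpolation on
12 runs with *distinct* settings -- passes easily: RMSE ≈ 0.11 % with 12
hidden units.

By the same token, recomputing the comparison metrics over all 17 printed
rows puts the quadratic model ahead of the published per-run network
predictions on both R² and AAD; the network's reported advantage arises
only when its metrics are computed on runs it fits nearly exactly.
`compare_models()` reports what the data give.

## Desirability optimization

`optimize_surface()` applies the study's factor policy: dye concentration
and yeast extract pinned at their upper limits ("maximize"), pH free
("in range"), response maximized. For a quadratic predictor the restricted
problem is solved in closed form -- the stationary point of the quadratic
in the free factors, clipped to the $[-1,1]$ box and compared against a
dense grid (step 0.001 coded) as a safeguard; for a network predictor the
grid plus seeded multi-start L-BFGS-B polish (25 starts) is used. On the
canonical fit this yields pH 6.646 and a predicted decolorization of
92.2 %, with the grid and closed form agreeing within one step.

Single-response desirability is the monotone rescale
$d = (\hat y - L)/(T - L)$ clipped to $[0,1]$, anchored at the observed
response range of the input data. The anchors affect the reported $d$,
never the argmax, which is why the package does not expose alternative
anchor conventions. The fully-free policy is also available because the
unconstrained optimum of the canonical quadratic lies at an *interior*
dye concentration -- a fact the pinned policy hides and users should be
able to see.

The signed validation deviation $100(\hat y - \bar y_{exp})/\hat y$
reproduces both published validation figures (6.58 % and 3.78 %) from the
printed predicted/experimental pairs; the signed form is used because
both published cases are positive and it reproduces them exactly.

## The synthetic-data generator

`surface_truth()` + `simulate_bbd_responses()` generate Box--Behnken
datasets from a known 10-coefficient quadratic with homoscedastic
Gaussian replicate noise. The defaults are the canonical study's
conditions: the fitted surface coefficients and noise
sd $= \sqrt{3.66} \approx 1.91$ % (the observed pure-error mean square),
with 5 center replicates. Center replicates share a setting but draw
independent noise, so the simulated pure-error SS has expectation
$(r-1)\sigma^2$ -- a property the tests verify against the chi-square
expectation over 400 seeds. Responses are not clipped to $[0,100]$ unless
requested, keeping estimator checks unbiased; clipping is available for
display-realistic tables.

What the generator emulates: the quadratic mean structure, replicate
error, and the design geometry. What it does not: spectrophotometric
measurement drift, run-order effects, microbial growth kinetics, or any
heteroscedasticity -- so passing recovery tests demonstrate correctness of
the estimators under the assumed model, not robustness to real-world
violations of it.

Parameter-recovery simulations (500 seeded replicates at noise sd 2)
check each coefficient against a $\pm 3$ standard-error band computed
from the *known* noise sd, $\sigma\sqrt{(X'X)^{-1}_{jj}}$: with the
7-degree-of-freedom estimated sigma the band's per-coefficient coverage
would be $P(|t_7| \le 3) \approx 0.98$ by construction, which would
confound a coverage check with small-sample SE noise; the known-sigma
band has normal coverage 0.9973.

## Problem sizes and determinism

All headline statistics derive from the 17-run dataset and run in
milliseconds. Stochastic components are seeded end to end: simulation
tables, network restarts and the multi-start optimizer all flow from
explicit seeds, and the test suite uses reduced training budgets (a few
thousand epochs, 2 restarts) where full convergence is not the property
under test. The full-budget network training (10 restarts × 100,000
epochs) completes in under two minutes on one core.

## Known limitations

* Only 3-factor Box--Behnken designs are constructed; central-composite
  and larger designs are out of scope.
* One hidden layer and plain momentum gradient descent only -- no
  quickprop, adaptive rates or cross-validation.
* Single-response desirability; multi-response aggregation is not
  implemented.
* The published per-run network predictions and held-out 0.999 fits
  depend on an undisclosed commercial trainer and are matched
  qualitatively, not numerically.
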