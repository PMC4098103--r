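---
title: "Modeling exposure-lag-response associations with lagresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling exposure-lag-response associations with lagresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagresp)
```

## The model

When a health outcome is driven by protracted time-varying exposures, the
risk at time $t$ depends on the whole exposure history
$\mathbf{q}_{x,t} = (x_{t-\ell_0}, \dots, x_{t-L})^\top$ over a lag window
$[\ell_0, L]$, not on a scalar summary. `lagresp` represents this
dependency with a *cross-basis*: an exposure-response function $f(x)$ and a
lag-response function $w(\ell)$ are each expanded in a basis
($f_1, \dots, f_{v_x}$ and $c_1, \dots, c_{v_\ell}$), and the bidimensional
exposure-lag-response surface is modeled as

$$
s(x, t; \boldsymbol\eta) \;=\; \sum_{\ell=\ell_0}^{L} \sum_{j=1}^{v_x}
\sum_{k=1}^{v_\ell} \eta_{jk}\, f_j(x_{t-\ell})\, c_k(\ell),
$$

a sum over the lag window of a tensor product of the two marginal bases.
The $v_x \times v_\ell$ coefficients $\boldsymbol\eta$ are the degrees of
freedom spent on the association; because $s$ is linear in
$\boldsymbol\eta$, the transformed design matrix $\mathbf W$ can enter any
regression model with a linear predictor. Two special cases anchor the
interpretation: a linear $f(x)$ gives the classical distributed lag model
(a weighted cumulative exposure), and linear $f$ with constant $w$ is
exactly unweighted cumulative exposure with one coefficient. Lag $\ell$
refers to the exposure received in year $t-\ell$ (backward convention),
with lag 0 the exposure during the last year; the time grid is yearly.

The built-in regression engine is a Cox proportional-hazards model in
counting-process form: age is the time axis, subjects enter at their cohort
entry age (left truncation) and one $(\text{start}, \text{stop}]$ row is
created per risk set in which a subject appears, with the exposure history
re-evaluated at every risk-set age. Partial-likelihood maximization is
delegated to the `survival` package's counting-process fitter with the
Efron method for ties (Breslow available for cross-checks). The cohort
analysis adds, next to the cross-basis of interest, a fixed a-priori
smoking cross-basis (natural cubic spline with one knot at 2.5 yearly
packs $\times$ 100 for the exposure dimension; a step function with a
single cut-off at lag 20 for the lag dimension; lag window 2-40) and a
linear calendar-time term, spending 5 confounder df.

## Identifiability, centering and constraints

Inside the tensor product an intercept in $f(x)$ multiplies every lag-basis
column and makes $\mathbf W$ rank-deficient, so exposure bases are always
built without an intercept (`build_crossbasis()` enforces this). All risk
summaries are reported relative to a centering exposure $x_0$ by
subtracting the basis row at $x_0$ at prediction time; fitting is
unaffected because the Cox baseline hazard absorbs constants. The default
$x_0 = 0$ is the natural reference for occupational exposures and is
configurable everywhere.

Shape assumptions on the lag structure are imposed through the lag basis:
excluding the intercept of a B-spline basis removes the only basis function
that is non-zero at $\ell_0$, so every fitted curve starts from null risk
at the beginning of the lag window (*left constraint*); removing the
right-terminal basis function forces null risk at $\ell = L$ (*right
constraint*). Both are exact: the constrained rows of the basis matrix are
identically zero, so the prediction is zero for any coefficient vector.
Non-negativity or monotonicity constraints on $w(\ell)$ are out of scope —
they make the model non-linear in its parameters.

Out-of-range evaluation of spline bases is an error by default: silent
extrapolation of quadratic splines beyond the observed exposure range is
exactly the situation where fitted exposure-response curves become
untrustworthy. A first-order (linear) continuation is available behind an
explicit `extrapolate = TRUE` flag.

## Parameters that matter

* **Lag window** `l0..L` — years. Cohort default 2-40 (no effect in the
  last 2 years nor after 40); simulation default 0-40.
* **Basis kinds and knots** — quadratic B-splines are the default smooth
  choice (`degree = 2`); knots at exposure quartiles and at roughly one
  third / half / two thirds of the lag window (13.3, 20, 26.7 lags).
  Published analyses of this cohort place the upper candidate lag knot at
  26.6 or 26.7 in different places; the grid here uses 26.7, and knot
  positions are arguments throughout.
* **Step-basis parameterization** — $c$ cut-offs yield $c+1$ disjoint 0/1
  indicator columns when used with an intercept (the lag-basis case: no
  reference level is needed because the exposure basis carries no
  intercept and the cross-basis is identified); without an intercept the
  first stratum is the reference.
* **Natural cubic splines** — cubic B-splines with second derivatives zero
  at the boundary knots, df = #knots + 1 (+ intercept).
* **Reference `x0`** — default 0.
* **Confidence level** — 95% two-sided by default; the coverage indicator
  of the study driver can use the one-sided quantile instead
  (`two_sided = FALSE`), but coverage is benchmarked against a 95% nominal
  level, which corresponds to the two-sided $z_{0.975}$.

## Model selection

With many candidate $(f, w)$ pairs, the best-fitting model is chosen by
minimizing AIC or BIC adapted to censored survival data:
$\mathrm{AIC} = -2\hat\ell + 2k$ and
$\mathrm{BIC} = -2\hat\ell + \log(d)\,k$, where $k$ counts *all* estimated
coefficients (cross-basis of interest, confounder cross-bases, calendar
term) and $d$ is the number of uncensored events. The identity
$\mathrm{BIC} - \mathrm{AIC} = (\log d - 2)k$ is exposed in every criterion
table and used as an internal consistency check. Ties are broken towards
fewer coefficients, then candidate order. Estimates and intervals from a
selected model are conditional on selection; no post-selection correction
is attempted, and the simulation study quantifies the resulting
undercoverage empirically.

## Prediction

From a fitted model, `predict_lag_curve()`, `predict_exposure_curve()` and
`predict_grid()` evaluate the centered transformation
$z(x, \ell) = (\mathbf r(x) - \mathbf r(x_0)) \otimes \mathbf c(\ell)$ on a
grid and report $\hat\beta = z^\top \hat{\boldsymbol\eta}$ with
delta-method standard errors $\sqrt{z^\top \hat{\mathbf V} z}$ (pointwise
bands; simultaneous bands are not computed). `cumulative_effect()` sums
$z$ over an arbitrary exposure history before taking the quadratic form,
giving the overall cumulative log-HR of that history relative to a
constant-$x_0$ history, and `risk_trajectory()` applies it along a profile
to show how risk evolves as past exposures move through the lag window.
The lag-curve/exposure-curve slices are exactly rows and columns of the
bidimensional grid, and the cumulative effect equals the sum of per-lag
contributions — both identities are tested to numerical precision against
brute-force triple loops.

## The simulator and what it does (not) emulate

`gen_profiles()` draws occupational-like exposure histories on years
1-100: a Poisson number of spells (mean 6), geometric durations (mean 10
years), uniform intensities on 0-10, overlaps resolved by the maximum.
This produces serially correlated, spell-structured exposure as in mining
careers. Event and censoring times are integers drawn uniformly on 2-100,
with each subject independently marked for censoring with probability
0.25; the *permutational algorithm* then marries times to subjects: times
are processed in ascending order, an event time going to a not-yet-assigned
subject with probability proportional to $\exp$ of their true cumulative
effect at that time, a censoring time uniformly. With 400 subjects this
yields roughly 300 uncensored events and ~25% censoring. With all effects
zero the assignment provably reduces to a uniform permutation, which the
tests verify by goodness of fit on exactly-multinomial margins (a
chi-square *independence* test on the full subject-by-rank table is
miscalibrated because both margins are fixed).

Nine true scenarios cross $f_s \in \{$linear, plateau
($\propto \log(1+x)$), exponential ($\propto e^{x/5}-1$)$\}$ with
$w_s \in \{$constant, decay ($e^{-\ell/10}$), peak (Gaussian centered at
lag 15, anchored to zero at lag 40)$\}$. Lag weights are normalized to sum
to one so the amplitude — the log-HR of continuous exposure at intensity
10, default 4 — is carried by $f_s$ alone. The scale constants were
calibrated once so that the signals are detectable but not degenerate:
AIC-based selection detects the decay and peak lag structures essentially
always at 400 subjects, while in the linear-constant scenario (both null
hypotheses true) BIC keeps the 1-df model almost always. All constants are
exposed as arguments.

The generator emulates the *structure* of occupational cohort data, not
any particular cohort: real exposure-history distributions, measurement
error, within-interval allocation artifacts and secular trends are absent.
Passing simulation tests therefore demonstrates correctness of the
machinery and the qualitative selection behavior (AIC moderate
overfitting, BIC severe underfitting with larger bias and lower coverage
under lack of fit), not numerical agreement of bias/RMSE magnitudes with
any published cohort: those depend on the exposure-history distribution,
for which this package's spell model is a surrogate. In particular, the
per-replicate evaluation draws a random subject at a random time in
41-100, and subjects that happen to be essentially unexposed in that
window make *relative* error metrics heavy-tailed at small replication
counts; replicates with $|\beta_{true}| < 10^{-8}$ are excluded from
relative metrics (with a reported count) but retained for coverage.

## Cohort files

`read_cohort()` reads the 5-year-interval layout: a subject table (id,
entry age, exit age, event indicator, calendar year at entry) and a tidy
exposure table with cumulative radon (WLM) and smoking (packs x 100)
totals at the end of each interval. Cumulative increments are allocated
uniformly within the interval (increment / 5 per year) — the data do not
record the within-interval pattern, and uniform allocation is the neutral
choice; this is the main residual uncertainty when comparing against
analyses that allocated differently. Smoking is held constant at the last
yearly rate after the last reported age; radon is zero after the last
interval; exposure before the first interval (and before birth) is zero.
The calendar-time confounder is the calendar year at the risk-set age
(entry year + age elapsed); using the year at entry instead is a
configuration choice.

## Numerical choices

* Basis evaluation delegates to `splines::splineDesign` / `splines::ns`;
  repeated values in large history matrices are evaluated once and gathered
  (bit-identical to direct evaluation).
* Cox fitting: `survival` counting-process maximizer, Efron ties,
  `coxph.control()` defaults; non-convergence and rank deficiency are
  errors, not warnings, and a failed candidate is recorded and skipped
  during grid selection.
* Reproducibility: every stochastic entry point takes a seed; the study
  driver derives one independent sub-seed per replicate from the master
  seed, so replicates are reproducible individually.
* Problem sizes: the packaged tests and the acceptance script run the
  simulation study in scaled-down form (100 and 40-60 replicates at 400
  subjects rather than 500), with binomial tolerance bands widened
  accordingly; these sizes are a deliberate compromise between Monte-Carlo
  precision and turnaround.

## Known limitations

Penalized (smoothing-parameter) splines, shape-constrained lag responses,
post-selection inference corrections, stratified/frailty Cox models and
competing risks are out of scope. The independency assumption of the
simulator's product-form truth $f_s(x)\,w_s(\ell)$ cannot be tested
formally from a fitted cross-basis; proportionality of fitted slices is
the available graphical diagnostic.
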