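---
title: "Classifying oral-absorption shapes before population PK modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying oral-absorption shapes before population PK modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a richly sampled oral pharmacokinetic study, different subjects can
display visibly different absorption patterns: a plain first-order uptake,
a delayed and peaked uptake well described by a chain of transit
compartments (an Erlang input), or a mixed "split-peak" profile with an
early bump followed by a delayed main peak.  Forcing a single absorption
sub-model onto every subject lets the misfit leak into clearance and
volume estimates, while assigning sub-models by eye is slow and shows
inter-rater variability.  `pkprescreen` automates the assignment: it
simulates labeled profiles of the three shapes from a published
population model, trains a small feed-forward softmax classifier on the
shape of each profile, and applies it to observed 12-point
concentration-time profiles as a prescreening step before the population
analysis.

## Structural models

All three models share one-compartment disposition with elimination rate
$k = CL/V$, a single oral bolus $D$ at $t=0$ and bioavailable fraction
fixed at 1 (absolute bioavailability is neither identifiable from these
data nor relevant to a shape classifier, because the per-subject min-max
scaling removes all scale information anyway).

**First-order.** The depot empties at rate $k_a$:
$$C(t) = \frac{D\,k_a}{V(k_a-k)}\left(e^{-kt}-e^{-k_a t}\right),$$
with the analytic limit $(D/V)\,k\,t\,e^{-kt}$ substituted when
$|k_a - k| < 10^{-9}k$ to avoid catastrophic cancellation.

**Erlang transit chain.** The dose traverses $n$ sequential compartments,
each emptying at rate $k_{tr}$, so arrival times in the central
compartment follow an Erlang($n$, $k_{tr}$) density and
$$C(t) = \frac{D}{V}\,\frac{k_{tr}^n\,t^n\,e^{-kt}}{(n-1)!}\cdot
  \frac{\gamma\!\left(n,(k_{tr}-k)t\right)}{\left((k_{tr}-k)t\right)^n}.$$
For $(k_{tr}-k)t \ge 1$ this is evaluated through `pgamma()`; for smaller
or negative arguments a power series of the lower incomplete gamma is
used whose terms are all positive when $k_{tr} < k$, so the evaluation is
cancellation-safe in every regime, including $k_{tr} \approx k$ where a
naive partial-fraction expansion explodes.  Correctness is defined
against a numerical ODE oracle (`deSolve::lsoda`, rtol $10^{-10}$, atol
$10^{-14}$), not against any particular algebraic layout; the test suite
compares the two on randomized parameter sets and enforces the
structural reductions (a chain of length 1 is first-order absorption;
total exposure $AUC = D/CL$ is identical for all shapes).

**Split-peak (mixed).** A fraction $f$ of the dose takes the delayed
Erlang path and $1-f$ the fast first-order path:
$$C(t) = (1-f)\,C_{fo}(t) + f\,C_{Erlang}(t).$$
Both paths start at $t=0$ (no separate onset times) and share $CL$ and
$V$.  The source population estimates put the split-peak $k_a$ at
7.6 h$^{-1}$ — faster than the Erlang path — so the first-order
component supplies the early bump and the transit chain the delayed main
peak.  The printed parameter table does not say which path the 0.78
"fraction" refers to.  We resolved this by shape: with 78% of the dose
through the *first-order* path the typical mixed profile is a smooth
single peak essentially indistinguishable from a first-order profile
after scaling (and a three-class classifier then cannot exceed ~77%
accuracy), whereas with 78% through the *Erlang* path the typical
profile shows the early-shoulder-plus-main-peak shape that defines the
class.  `fraction` therefore denotes the share absorbed through the
transit chain.

## Number of transit compartments

The transit-chain length is not printed in the source material, so it is
exposed as a parameter (`n_transit`).  The default was chosen once, on
shape grounds: scanning $n$ at the typical split-peak parameters
($k_a$ 7.6, $k_{tr}$ 5.2, $f$ 0.78, 20-kg subject), $n = 8$ is the
smallest chain for which the mixed profile has a genuine interior local
minimum — an actual split peak — inside the sampled 0–6 h window, while
the typical Erlang-class profile still peaks at 1.37 h, within the
densely sampled 0.25–1.5 h region that the design targets.  Shorter
chains ($n \le 7$) smear the Erlang input so much that the "split-peak"
class never splits; longer chains push the Erlang-class peak past 1.6 h,
outside the dense sampling.

## Population simulation

The simulator reproduces the published study conditions: a 20-kg subject
receiving 10 mg, sampled at 0 (predose), 0.25, 0.5, 0.75, 1, 1.25, 1.5,
2, 2.5, 3, 4 and 6 h.  Typical values (per 70 kg: CL 22.6 L/h, V 38.9 L;
first-order $k_a$ 3.3 h$^{-1}$; Erlang $k_{tr}$ 8.2 h$^{-1}$; split-peak
$k_{tr}$ 5.2 h$^{-1}$, $k_a$ 7.6 h$^{-1}$, fraction 0.78) are scaled
allometrically (exponent 0.75 for clearance, 1 for volume; rate
constants unscaled) and individualized log-normally with
$\omega^2 = \ln(1+CV^2)$ so the realized coefficient of variation equals
the stated one: 29% (CL), 21% (V), 48% ($k_a$), 23% ($k_{tr}$).  CL and
V use the same population distribution for all three shapes.
Observations receive proportional residual error,
$C_{obs} = C(1+\varepsilon)$, $\varepsilon \sim N(0, 0.165^2)$, clipped
at zero (an event of probability ~$10^{-9}$ per observation); the
predose sample is structurally zero and stays zero under multiplicative
error.

The bounded absorbed fraction cannot carry an 80% coefficient of
variation on the natural scale — a (0,1)-bounded variable with mean 0.78
has CV at most ~0.53 — so the printed "0.78 (80%)" is read the way such
estimates are conventionally reported for logit-transformed parameters:
a logit-normal distribution centred at $\mathrm{logit}(0.78)$ with SD
0.80 on the logit scale.  About 96% of draws then fall in (0.4, 0.97);
the rare extreme draws produce mixed profiles that genuinely resemble a
pure shape, which is the main source of irreducible classification
error discussed below.

One master seed deterministically spawns independent sub-streams for
parameter sampling, residual error, the train/validation split, weight
initialization and batch shuffling, so changing, say, the residual-error
magnitude never perturbs the sampled parameters, and an entire pipeline
run is bit-reproducible from a single integer.

## Feature scaling and the classifier

Each profile is standardized per subject onto $[0,1]$:
$$CS_i = \frac{C_i - C_{min}}{C_{max} - C_{min}},$$
which preserves rank order and is invariant to positive affine changes
of the concentration scale; no training-set statistics are reused at
prediction time, so observed profiles are transformed identically to
simulated ones.  A constant profile has no shape and raises an error
rather than being silently coerced.

The classifier maps the 12 scaled concentrations to 3 class
probabilities through three hidden layers (ReLU) and a softmax output;
each node computes $y = f(b + \sum_n x_n w_n)$.  Depth 3 is fixed
(deeper networks showed no improvement on this problem); width 64 per
hidden layer is a default chosen to be comfortably over-parameterized
relative to 12 inputs while training in CPU minutes, and is
configurable.  Training minimizes categorical cross-entropy (natural
log, probabilities clamped at $10^{-12}$) by mini-batch gradient descent
with batch size 32 over 100 epochs, using the Adam optimizer at its
conventional settings (step 0.001, $\beta_1$ 0.9, $\beta_2$ 0.999) — the
era's framework default.  Weights initialize from a fan-in-scaled
uniform $U(\pm\sqrt{6/n_{in}})$, biases at zero.  Gradients are
hand-implemented backpropagation and are verified against central finite
differences in the test suite.  Argmax ties (exactly equal maximum
probabilities) are broken toward the first class in the canonical order
(first_order, erlang, split_peak) and flagged explicitly.  Model
artifacts are JSON with weights serialized at 17 significant digits, so
save → load → forward is bit-exact.

## Evaluation

`evaluate_model()` reports the 3×3 confusion matrix (rows = predicted,
columns = reference), accuracy (trace over total), mean cross-entropy,
the no-information rate (largest reference-class share), an exact
one-sided upper-tail binomial test of accuracy against the
no-information rate (the standard accuracy-vs-chance convention; the
sidedness is a package decision, as the source analysis does not state
it), and counts of correct/incorrect assignments above probability
thresholds (default 0.75 and 0.9).  Reported rates truncate at one
decimal place (45/48 prints as 93.7), matching the convention of the
published table this reproduces.

## What the tests do and do not show

The default full-scale run (10,000 profiles per shape, 70/30 stratified
split, 100 epochs; about 3 minutes on one CPU core) reaches ~99.5%
training and ~98.9% validation accuracy with validation cross-entropy
~0.04.  The published analysis this emulates reports 99.7%/99.4% with
loss below 0.01.  The residual gap traces to class overlap that is
irreducible under our documented generator choices: with a 48% CV on
$k_a$ and a wide logit-normal on the absorbed fraction, roughly 1% of
simulated profiles genuinely belong to more than one class (a
first-order subject with a very low $k_a$ draw is indistinguishable from
a mixed profile, even without residual error), and each such profile
contributes a large log-loss term.  Since the original transit-chain
length and fraction-variability handling are unprinted, exact
reproduction of the loss figure is not expected; the accuracy figures
reproduce within half a percentage point.  Tests therefore assert the
published tolerances where they are attainable and the suite documents
the rest.  A scaled-down variant (1,000 per shape, same settings,
~12 s) reaches ≥98% validation accuracy and is used in the routine test
suite; the methods and sizes are identical apart from the number of
simulated subjects.

Passing tests show that the pipeline reproduces its own study
conditions; they do not show that the classifier transfers to drugs
with different disposition, to designs with other sampling times, to
profiles with measurable predose baselines (endogenous compounds under
replacement therapy), or to data with below-quantification censoring —
none of which the generator emulates.  For such settings the network
should be retrained on simulations from the relevant population model.

## Numerical choices

* Degenerate $k_a = k$: analytic limit, switch at $|k_a-k| < 10^{-9}k$.
* Incomplete-gamma series for $(k_{tr}-k)t < 1$: terms to $j = 60$ or
  convergence at $10^{-18}$ relative, whichever first.
* ODE oracle: `lsoda`, rtol $10^{-10}$, atol $10^{-14}$; closed forms and
  oracle are compared with the relative-error denominator floored at
  $10^{-6}$ of the profile peak, below which the oracle's absolute
  tolerance dominates and the comparison would be meaningless.
* Stratified split: per-class holdout counts round half away from zero,
  the last class absorbing any drift from the overall target.
* Cross-entropy clamp $10^{-12}$; softmax computed with row-max
  subtraction.
* Time matching for observed datasets: nearest design time within
  0.01 h (clinical times are recorded to the minute); duplicated
  (subject, time) rows are a hard error, never silent deduplication.

## Worked example

```{r, eval = FALSE}
library(pkprescreen)

# simulate, split, train, evaluate from one seed (reduced size here)
res <- run_pipeline(pipeline_config(n_per_shape = 1000, seed = 2021))
res$summary
#>         data    n accuracy_pct    loss
#> 1   Training 2100         99.9 0.00493
#> 2 Validation  900         98.4 0.05000

# prescreen observed profiles with the trained network
obs <- read_profiles("observed.csv")        # NONMEM-style ID/TIME/DV
prescreen(obs$profiles, res$net, exclusions = obs$exclusions)
```
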