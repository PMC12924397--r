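---
title: "Validating movement-HMM behavioural states across temporal scales: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating movement-HMM behavioural states across temporal scales: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the simulator, the numerical choices
and the design decisions behind `movescale`. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The observation model

Within a *burst* — a maximal run of fixes at a constant relocation interval
for one individual — consecutive fixes define movement steps. Step `k`
links relocation `k` to `k+1`; its length is the planar Euclidean distance
in kilometres, and its turn angle is the signed heading change from step
`k-1` to step `k`, counter-clockwise positive, wrapped to `(-pi, pi]`. The
first step of every burst has no previous heading and its angle is treated
as missing; a zero-length step has an undefined heading, so the angles that
depend on it are missing too. Missing angles are marginalized out of the
likelihood (the emission density reduces to the step-length factor), the
standard treatment in movement HMMs. No step is ever computed across a
burst boundary, so the overnight gaps of a daylight-only collar schedule
never generate spurious steps. How fixes bridging the overnight gap should
be chained is genuinely ambiguous in field practice; treating every gap as
a hard burst boundary is the conservative reading adopted here.

Each hidden state `i` of an N-state Markov chain (transition matrix
`Gamma`) emits:

* step length: gamma with mean `mu_i` (km) and sd `sigma_i` (km) —
  the (mean, sd) parameterization is the one ecologists report; internally
  it is converted to (shape, rate). An optional point mass `zeta_i` at
  exactly zero is mixed in, because steps of exactly 0 km otherwise have
  no density. Zero inflation is engaged automatically exactly when zero
  steps occur in the data, and `zeta` is initialized at the empirical zero
  proportion.
* turn angle: von Mises with mean `theta_i` and concentration `kappa_i`;
  `kappa = 0` is the circular uniform. `theta` is estimated by default,
  with an option to fix it at 0.

The initial law `delta` is the stationary distribution of `Gamma` rather
than a free parameter — the standard movement-HMM default, which spends no
degrees of freedom on burst starts (there are many bursts, and each restart
would otherwise multiply nuisance parameters).

## Fitting

The forward log-likelihood is computed with a scaled forward recursion in
compiled code, summed over bursts with `delta` restarted at each burst, so
bursts of tens of thousands of steps do not underflow.

Maximization is multi-start maximum likelihood: `n_starts = 10` random
starting-parameter draws, keeping the converged fit with the highest
log-likelihood. Starting step means are drawn from disjoint quantile bands
of the observed positive step lengths — (5–40) and (60–98) percentiles for
two states; (5–40), (40–80), (80–98) for three — a reproducible stand-in
for the field practice of choosing starts by inspecting histograms.
Starting `sigma` is the drawn `mu` scaled by Uniform(0.5, 1.5), `kappa` is
Uniform(0.1, 5), and the starting transition matrix is mildly sticky
(diagonal Uniform(0.7, 0.95)) with random off-diagonal splits.

The optimizer is BFGS on an unconstrained working scale:

* `log mu`, `log sigma`; `logit zeta` when zero inflation is engaged;
* the angle parameters as the planar 2-vector
  `(kappa cos theta, kappa sin theta)` when the angle mean is estimated
  (its polar coordinates are exactly `(kappa, theta)`, so this subsumes a
  log-type positivity constraint on `kappa` while keeping `theta` free of
  wrap-around discontinuities); `log kappa` when `theta` is fixed at 0;
* each row of `Gamma` as multinomial logits with the diagonal as
  reference, evaluated with a max-shifted softmax so distant line-search
  probes cannot overflow.

The gradient is analytic. By the Fisher identity, the score of the HMM
log-likelihood is the posterior expectation of the complete-data score, so
a single forward–backward pass yields every partial derivative: posterior
state probabilities weight the per-observation emission scores, expected
transition counts give the `Gamma` derivatives, and the first-step
posteriors give the sensitivity to `delta`. Because `delta` is itself the
stationary distribution of `Gamma`, that last term is propagated through
the transition logits by exact central differences of the (tiny, N x N)
stationary-distribution map. The full score is verified against central
finite differences of the log-likelihood in the test suite (tolerance
1e-5). An analytic score makes the per-iteration cost independent of the
parameter count, which is what lets ~86,000-step datasets fit in seconds.

Convergence of a start requires the optimizer to report success under a
relative log-likelihood tolerance of 1e-8 (iteration cap 10^4) *and* a
relative gradient criterion `max |g| / (1 + |nll|) < 1e-4`. The gradient
test is relative rather than absolute because the log-likelihood of an
86,000-step dataset is of order 1e5, where an absolute gradient-norm cutoff
would declare essentially every correct optimum unconverged. If every start
fails, fitting aborts with per-start diagnostics.

After fitting, states are relabelled by ascending `mu`, which makes fits
permutation-invariant across starts and seeds, and two- and three-state
fits carry the nominal labels stationary/travelling and
stationary/foraging/travelling. Viterbi decoding breaks ties toward the
lower state index (deterministic, and exercised by a degenerate
equal-emission test); decoded states are attached to the *start* location
of each step — deliberately so, because that common reading is exactly the
interpretation whose temporal-scale fragility the package measures.

## The simulator

The generator is deliberately *not* the fitted model. Behaviour switches
happen on a 1-minute tick — finer than any fix interval studied — as a
first-order Markov chain over stationary/foraging/travelling, and movement
is a directed walk at tick scale: per-tick displacement length is gamma
(positive support, consistent with the fitted emission family), and the
heading evolves by von Mises increments with per-behaviour concentration.
Fitting a fix-scale HMM to tick-scale directed-walk output therefore faces
honest model mismatch, exactly as a real HMM faces real caribou. For
parameter-recovery tests a separate "model-exact" generator
(`simulateHMMData()`) draws steps and angles directly from the fitted
families at fix scale.

Default scenario (the package's reference study conditions, fixed once):

* 30 individuals, 60 full days each; fixes every 20 min inside a
  06:00–22:00 daylight window (subarctic summer collar schedule), thinned
  to 60 and 120 min by retaining every 3rd/6th location;
* mean fine-scale bouts of 60 / 30 / 20 minutes for stationary / foraging
  / travelling, i.e. per-tick stay probabilities `1 - 1/mean`; these sit in
  the tens-of-minutes range that direct observation studies of fine-scale
  ungulate behaviour report, and guarantee that 60- and 120-min intervals
  straddle multiple switches;
* per-tick speeds (km/min): stationary 0.0005 ± 0.0005 — so apparent
  stationary movement is dominated by GPS error — foraging 0.010 ± 0.008,
  travelling 0.050 ± 0.025 (3 km/h); heading concentrations 0 / 0.8 / 8;
* isotropic Gaussian GPS error, sd 15 m, added to *reported* positions
  only. No caribou-specific GPS error magnitude is published for these
  collars; 15 m is a typical modern-collar figure and is configurable.
* each fix carries the behaviour at exactly that tick, emulating a ~10-s
  video clip, optionally dressed in raw single-label video codes (e.g. a
  foraging tick becomes "eating", standing 70% / drifting-forward 30%) so
  the label-binning stage is exercised end to end.

Every individual runs on a deterministically derived stream from one
master seed, so the entire dataset is a pure function of (specs, seed).

What the simulator does **not** emulate: habitat covariates,
inter-individual kinematic heterogeneity (the analysis pools individuals,
as fixed-effect HMM studies do), irregular fix failure, autocorrelated GPS
error, or multi-label video scoring beyond the single-label dialect.
Passing tests therefore show that the pipeline's inferences behave as the
theory predicts under controlled switching and kinematics — not that any
particular wild population matches the defaults.

## Label binning

Raw video labels reduce to the 2- or 3-category scheme under two dialects:
a single-label dialect (mutually exclusive behaviour and locomotion codes;
the two-state scheme reads locomotion, the three-state scheme reads
behaviour) and a multi-label dialect (sets of labels reduced by
deterministic precedence: low-movement, then locomotion, then feeding,
later rules overriding, so walking-with-eating is foraging). The complete
vocabularies and rule order ship as a versioned YAML
(`inst/extdata/binning_rules.yaml`). Records labelled "other" are excluded
— including, conservatively, multi-label records where "other" co-occurs
with valid labels, since the source protocols do not say how such records
were handled; "vigilance" is accepted as an alias of "vigilant". Unknown
labels are hard errors, never silently dropped, to protect against dialect
mix-ups. Three-state single-label records with no behaviour mapping
(e.g. locomotion-only) are excluded rather than guessed.

## Evaluation

* **Video match**: decoded states join instantaneous behaviour categories
  on individual + step-start timestamp, with a 1-minute default tolerance —
  schedules are intended to coincide exactly; the tolerance only absorbs
  clock jitter, and duplicate joins within tolerance raise an error rather
  than silently double-count. Confusion matrices pool individuals (the
  headline of interest is herd-level), and overall accuracy is the trace
  over the total. The accuracy computation is cross-checked against
  `caret::confusionMatrix` in the tests.
* **Cross-scale match**: the finer sequence is restricted to the coarser
  sequence's step-start locations (a guaranteed subset under every-nth
  resampling, enforced with an error otherwise) and label agreement is the
  proportion over shared locations.
* **Bout durations**: per state, mean run length multiplied by the
  relocation interval, runs computed strictly within bursts.

Resampling always starts at each burst's first fix (offset 0): the design
calls for one nested set of retained locations, not an ensemble over
offsets.

## Problem sizes and runtime choices

The test suite exercises the exhaustive-enumeration oracle on 100 random
instances with at most 3 states and 8 steps (where all `N^T` paths are
enumerable), parameter recovery on 5,000 model-exact steps, and the full
default scenario (30 x 60 days; about 86,000 steps at 20 min) for the
scale-degradation and bout-inflation phenomena; the whole suite runs in a
few minutes on one CPU thanks to the compiled kernels and analytic score.
`scripts/acceptance.R` reruns the full default grid from the seed it is
given.

## Known limitations

* The three-state "foraging" state inherits the intermediate step-length
  band and absorbs mixed behaviour; with heavily overlapping kinematics the
  global optimum occasionally places the middle state differently across
  seeds — the quantile-band starts and best-of-10 selection mitigate but
  cannot abolish multimodality.
* The relative gradient convergence criterion is a pragmatic choice;
  profile-likelihood confidence intervals are out of scope, as the analysis
  reports descriptive percentages only.
* Turn-angle sign convention is counter-clockwise positive; the von Mises
  is symmetric at `theta = 0`, so the convention only matters when angle
  means are estimated away from zero.
* Great-circle geometry, continuous-time models and imputation of missing
  fixes are deliberately out of scope: inputs are projected planar
  coordinates, and gaps split bursts.
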