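# movescale

Temporal-scale validation of hidden Markov model (HMM) behavioural states
inferred from GPS tracking data.

## The problem

Movement ecologists routinely fit HMMs to GPS tracks — gamma-distributed step
lengths and von Mises-distributed turn angles per hidden state — and read the
Viterbi-decoded states as behaviours ("stationary", "foraging",
"travelling"), usually attached to the start location of each step. Two
things can quietly break that reading:

1. **Overlapping movement signatures.** Behaviours like foraging produce
   step/turn distributions that overlap both resting and travelling, so the
   statistical states need not be the biological ones.
2. **Temporal scale.** Animals switch behaviours on scales of minutes; if
   fixes arrive every 20–120 minutes, many switches happen *inside* a step,
   and both the decoded state at a location and the apparent duration of
   behavioural bouts become artefacts of the sampling interval.

`movescale` packages the full validation experiment: simulate
behaviour-switching tracks with co-registered instantaneous behaviour labels
(standing in for collar video clips), fit 2- and 3-state HMMs to the same
track thinned to coarser and coarser relocation intervals, and measure (i)
how often decoded states match the labelled behaviour at step starts, (ii)
how often states at one temporal scale match states at another, and (iii)
how apparent bout durations inflate with the fix interval.

## The model

For steps *x_t* (km) and turn angles *a_t* (radians) within bursts of
constant-interval fixes, each hidden state *i* of an N-state Markov chain
with transition matrix Γ emits

- step length: `x_t ~ Gamma(mean μ_i, sd σ_i)`, with an optional point mass
  ζ_i at exactly zero;
- turn angle: `a_t ~ von Mises(θ_i, κ_i)` (marginalized out when undefined).

The initial law δ is the stationary distribution of Γ. The likelihood is
maximized over an unconstrained working scale by BFGS with an analytic score
derived from the forward–backward recursions, from 10 random starting-value
draws; the best converged fit is kept and states are relabelled by ascending
μ. Decoding uses the Viterbi algorithm with ties broken toward the lower
state index.

## Worked example

```r
library(movescale)

truth <- hmmParams(step_mean = c(0.05, 1), step_sd = c(0.05, 0.8),
                   angle_concentration = c(0.5, 3),
                   transition_matrix = matrix(c(.9, .1, .1, .9), 2, 2))
d <- simulateHMMData(truth, 2000, seed = 2)       # model-exact generation
fit <- fitHMM(d$steps, n_states = 2, n_starts = 10, seed = 3)
fit
#> 2-state movement HMM fit
#>   log-likelihood: -2540.130907  (best of 10 starts, 3 converged)
#>   steps: 2000
#>   state      label step_mean_km step_sd_km zero_mass angle_mean_rad
#> 1     1 stationary   0.04989495  0.0490235         0    -0.12277463
#> 2     2 travelling   0.99093481  0.7956664         0     0.02120617
#>   angle_concentration stationary_prob
#> 1           0.4651322       0.4494149
#> 2           2.8807201       0.5505851

mean(viterbiPath(d$steps, fit$params)$state == d$states)
#> [1] 0.9905
```

The fitted step means (0.050, 0.991 km) recover the generating values
(0.05, 1.0) to within a percent, and Viterbi decoding recovers 99% of the
true states — the behaviour you should expect when the fitted model *is*
the generating model. The interesting failures appear when it is not: run
the full grid with

```r
res <- runExperiment(experimentConfig(out_dir = "run1", seed = 1))
sapply(res$matches, function(m) m$overall_accuracy)
```

which, on the default scenario (30 individuals, 60 days, 1-min behaviour
switching, daylight-only 20-min fixes thinned to 60 and 120 min), shows
video-match accuracy falling from ~80% (2-state, 20 min) to ~41%
(3-state, 120 min), and stationary bouts apparently lengthening by >1.5x
as the interval coarsens — both artefacts of sampling scale, not of the
animals.

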