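# amtrack

Adaptive up-down threshold tracking and simulated amplitude-modulation
detection experiments, in R.

Auditory psychophysics labs estimate detection thresholds with adaptive
staircases: the stimulus gets harder after successes and easier after a
failure, homing in on a criterion performance level without sweeping the
whole stimulus range. `amtrack` packages the computational core of such an
experiment — a three-alternative forced-choice (3-AFC) amplitude-modulation
detection test (AMDT) — as headless, testable components for anyone who
wants to validate an adaptive procedure, characterize an experiment
platform's event timing, or prototype staircase designs against a simulated
listener before spending participant hours.

## What it implements

**Staircase.** A transformed up-down (n-down-1-up) procedure with step-size
schedules keyed to reversal or trial counts: the tracked modulation depth
steps down after `n_down` consecutive correct answers, up after one error.
A 3-down-1-up rule equilibrates where three successes in a row are as
likely as not, at response probability

&nbsp;&nbsp;&nbsp;&nbsp;*p\** = 0.5^(1/3) ≈ 0.794.

**Observer.** A cumulative-Gaussian psychometric model,
*p(d)* = ½[1 + erf((*d* − *μ*)/(*σ*√2))] = Φ((*d* − *μ*)/*σ*), with
midpoint *μ* = −9 dB and spread *σ* = 2 dB by default; answers are drawn by
comparing one uniform variate per trial against *p(d)*. Inverting the model
at *p\** predicts the staircase's convergence depth,
*d\** = *μ* + *σ* Φ⁻¹(0.5^(1/3)) = −7.3613 dB for the defaults.

**Stimuli.** Unit-RMS AM-tone synthesis (depth in dB, *m* = 10^(depth/20)),
dB gains, band-limited resampling, multichannel mixing with sample-accurate
onset scheduling, per-channel SPL calibration, and 32-bit-float WAV I/O.

**Session.** The full 3-AFC AMDT: balanced randomized target positions
(12 per position per 36-trial block), four carrier/modulation conditions
(400/1000 Hz × 5/10 Hz), stimulus onsets at 0.5/1.5/2.5 s, start/end
markers on a deterministic virtual clock, everything reproducible from a
seed.

**Validation statistics.** Converged-window analysis over the trials
spanning each run's last six smallest-step reversals (per-run mean and
population SD; convergence estimation and variability; estimation
variability across runs), plus latency/jitter reports for paired
marker/onset timestamp streams with a synthetic stream generator and a
WAV onset detector.

## Worked example

```r
library(amtrack)

## analytic predictions for the default observer and 3-down-1-up rule
convergence_probability(3)
#> [1] 0.7937005
expected_convergence_depth(psychometric_model(-9, 2), 3)
#> [1] -7.361343

## simulate the full validation design and summarize convergence
fit <- amdt_experiment(seed = 1)
summary(fit)
#> Simulated 3-AFC amplitude-modulation detection experiment
#>
#> Call:  amdt_experiment(seed = 1)
#>
#> Design: 10 participants x 4 conditions, 108 trials per condition run
#> Observer: midpoint -9 dB, std 2 dB; target convergence -7.3613 dB
#> Threshold estimate: -7.0831 dB
#>
#> Staircase convergence report (40 runs, last 6 smallest-step reversals)
#>   convergence estimation : -7.0831 dB (target -7.3613 dB)
#>   convergence variability: 0.5288 dB
#>   estimation variability : 0.5165 dB
#>
#> Per-run converged means (dB):
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  -8.438  -7.371  -7.102  -7.083  -6.627  -6.259
```

The threshold estimate is the average converged depth over the 40 condition
runs (10 participants × 4 conditions); it sits a few tenths of a dB above
the analytic convergence point because runs spend part of their converged
window still descending and the 0.5-dB step quantizes the oscillation
around equilibrium. Convergence variability is the mean within-run spread
of the converged depths; estimation variability is the spread of the
per-run means across runs. `plot(fit)` draws the 40 run means with error
bars against the analytic target; `plot(fit, "track")` shows a single
staircase trajectory.

Lower-level pieces compose the same way the experiment uses them:

```r
am <- synthesize_am_tone(400, 5, depth_db = -6.0206, duration_s = 0.5)
am
#> <audio_track: 22050 samples @ 44100 Hz (0.5 s), RMS 1>

sc <- staircase_init(staircase_config(6, c(1, 0.5), 1, max_trials = 108))
sc <- staircase_update(sc, TRUE)   # feed answers as they come in
```

A thin command-line wrapper (`inst/cli/amtrack`) exposes the pipeline as
`synth`, `simulate`, `analyze` and `timing-audit` subcommands over YAML/JSON
configs; see `inst/extdata/example-config.yaml`.

## Further reading

The methods vignette (`vignettes/adaptive-amdt.Rmd`) documents the models
and their assumptions, the staircase bookkeeping conventions, the design of
the simulated validation study, numerical choices, and what the synthetic
observer does and does not say about real listeners.
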