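---
title: "Adaptive up-down tracking for amplitude-modulation detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive up-down tracking for amplitude-modulation detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amtrack)
```

`amtrack` is a headless toolkit for auditory psychophysics built around one
experiment: a three-alternative forced-choice (3-AFC) amplitude-modulation
detection test (AMDT) driven by a transformed up-down staircase and answered
by a simulated observer. This vignette explains the models the package
implements, the parameters that matter and their defaults, the numerical
choices, and what the simulations can and cannot tell you about real
listeners.

## The task and the stimuli

Each trial presents three 500-ms tones at 0.5, 1.5 and 2.5 s from trial
start (a 1-s inter-onset grid). Two are flat carrier tones; one, at a
uniformly random position, is sinusoidally amplitude modulated:

$$s(t) = \bigl(1 + m \sin 2\pi f_{mod} t\bigr)\,\sin 2\pi f_c t,$$

with modulation depth expressed in decibels, $depth = 20\log_{10} m$, so
0 dB is full modulation and $-20$ dB means $m = 0.1$. The observer's job is
to say which interval was modulated; the adaptive track makes the target
harder (more negative depth) as the observer succeeds.

All waveforms are normalized to unit RMS, the package's common reference
level; playback gains, mixing levels and SPL calibration are all expressed
in dB relative to that baseline. A per-channel `calibration_profile()`
stores the measured-minus-nominal offset so `calibrate_level()` can convert
a target SPL into a software level.

Synthesis choices worth stating explicitly:

* **Over-modulation.** A tracked depth above 0 dB implies $m > 1$, which no
  physical AM stimulus realizes. The synthesis clamps $m$ at 1 while the
  staircase's tracked value is left untouched; the track therefore starts
  (at its 6 dB default) in a region where every stimulus is simply fully
  modulated. This only affects rendered audio, never the tracking logic.
* **Sample grid.** Default rate 44.1 kHz; onsets and durations quantize to
  the nearest sample with half-away-from-zero rounding, so a 0.5-s onset at
  44.1 kHz is exactly sample 22050.
* **Resampling** is spectral (FFT) band-limited interpolation: exact for
  the band-limited tones this package produces, with the usual caveat that
  the signal is treated as periodic, so broadband material with strong
  onsets can show edge ringing. The contract tested is conservative:
  duration preserved within one sample, sub-Nyquist sine energy within 1%,
  correlation with the analytic waveform above 0.999.

## The staircase

The adaptive procedure is the classic transformed up-down rule: after
`n_down` consecutive correct responses the tracked value steps down; after
a single error it steps up. With `n_down = 3` the equilibrium point is
where three successes in a row are as likely as not,
$p^3 = \tfrac12 \Rightarrow p^\ast = 0.5^{1/3} \approx 0.794$.

Step sizes follow an ordered schedule: the default is 1 dB until the first
reversal, 0.5 dB afterwards. Two bookkeeping conventions had to be fixed
because verbal descriptions of up-down procedures rarely pin them down:

* **Reversal definition.** A reversal is recorded at the trial where an
  executed step's direction differs from the previous executed step's
  direction. Trials on which nothing moves (a first or second correct in a
  row) can never be reversals, and the first executed step records none.
  This is the standard Levitt bookkeeping.
* **Schedule advance.** The reversal that crosses a change point advances
  the schedule immediately, so the new (smaller) step applies from the next
  executed step onward, while the reversal itself is recorded with the step
  that was in effect when it happened.

Both conventions are locked in by a property test that replays random
answer sequences through an independent transcription of the verbal rules
(1000 cases per run) and demands identical trajectories and reversal lists.

The tracked value is unbounded by default; optional saturation bounds exist
for live use. Values always live on the lattice
$start + a\cdot s_1 + b \cdot s_2 + \dots$ with integer $a, b$, which the
suite also checks.

## The simulated observer

The probability of a correct response is a cumulative-Gaussian psychometric
function of depth,

$$p(d) = \tfrac12\Bigl[1 + \mathrm{erf}\Bigl(\tfrac{d - \mu}{\sigma\sqrt2}\Bigr)\Bigr]
       = \Phi\!\Bigl(\tfrac{d-\mu}{\sigma}\Bigr),$$

with midpoint $\mu = -9$ dB and spread $\sigma = 2$ dB by default. Answers
are drawn by comparing one uniform variate per trial against $p(d)$ — one
draw per trial, not per interval. Note what this model deliberately omits:
a 3-AFC listener who hears nothing still guesses right one time in three,
but the default observer's probability falls to zero instead of flooring at
1/3. That is intentional — the simulated validation design generates
answers straight from the sigmoid — and the floor is available as
`guess_rate = 1/3` for anyone who wants the guessing-corrected geometry
(`expected_convergence_depth()` inverts it consistently).

Inverting $p$ at the staircase's target probability gives the depth the
track should converge to:

$$d^\ast = \mu + \sigma\,\Phi^{-1}\!\bigl(0.5^{1/3}\bigr) = -7.3613\ \mathrm{dB}$$

for the defaults. $\Phi^{-1}$ is evaluated by `qnorm`, accurate to well
below $10^{-10}$, so this constant is exact to the digits shown. Published
accounts of this design often quote a convergence depth read off a plotted
psychometric curve, which can differ from the closed form in the third
decimal; the package always reports the analytically inverted value.

## The session and the validation design

A session (`run_session()`) shuffles the condition order and runs each
condition — a carrier/modulation pair; the default four are
400/1000 Hz × 5/10 Hz — as balanced blocks of $3 \times 12$ trials in which
each target position occurs exactly 12 times. Markers bracket every trial
(`start` at the first stimulus onset, `end` at the last offset) on a
deterministic virtual clock advancing 4 s per trial, so a session's marker
stream is exactly reproducible from its seed; an injectable real clock is a
straightforward extension for live use but deliberately not part of the
simulation path. Each participant uses an independent stream seeded
`base_seed + participant`.

One design decision deserves its arithmetic spelled out. The validation
design plays each condition three times (`repetitions = 3`) with a *single*
adaptive track per condition persisting across its three 36-trial blocks,
i.e. 108 trials per scored condition run. The alternative reading — a
fresh 36-trial track per condition — cannot support the convergence
analysis at all: descending from the 6 dB start to the $\approx -7.4$ dB
equilibrium needs at least 13 down-steps of 1 dB, and each down-step costs
three correct trials, so the descent alone exceeds 36 trials and a short
track essentially never accumulates six reversals at the smallest step.
With the persistent 108-trial track, every run converges and the window
statistics below are well defined; with ten participants and four
conditions the analysis covers $M = 40$ condition runs. The per-block
bookkeeping (36 trials per condition play, 12 per position, 144 trials per
participant per play-through) is unchanged by this choice.

## Convergence statistics

A run's converged region is the set of trials spanning its last six
reversals at the smallest step size: inclusive from the trial of the
6th-from-last qualifying reversal to the trial of the last one. The window
edges are a convention (verbal definitions leave them open); ours includes
both endpoint trials. From the window depths $depth(i,j)$ of run $j$:

* per-run mean $depth_{mean}(j)$ and **convergence estimation**
  $\frac1M\sum_j depth_{mean}(j)$;
* per-run population standard deviation $depth_{std}(j)$ (divisor $N$) and
  **convergence variability** $\frac1M\sum_j depth_{std}(j)$;
* **estimation variability**: the population standard deviation of
  $depth_{mean}(j) - d^\ast$ about its own mean. Because the target enters
  every term identically the result is invariant to it; the suite asserts
  this identity.

Population ($1/N$, $1/M$) divisors are used throughout, matching the
definitions this design is validated against, not the sample ($N-1$)
convention of `sd()`.

With the default design and seeds the package obtains a convergence
estimation around $-7.1$ to $-7.3$ dB, convergence variability around
0.45–0.55 dB and estimation variability around 0.45–0.55 dB. The small
systematic offset of the estimate above $d^\ast$ is real, not a bug: runs
spend their early window trials still descending, and the 0.5 dB step
quantizes the oscillation around the equilibrium.

## Timing audits

For marker/onset pairs the package computes per-event differences
$diff(i,j) = x_l(i,j) - x_s(i,j)$, per-run mean latency, per-run random
error (zero-mean by construction, asserted to machine precision), the
standard error of the mean across runs (population divisor $M$), and
quartiles of the pooled random error using linear interpolation between
order statistics (`quantile` type 7; the choice matters at these small
$N$ and is therefore stated). `generate_timing_streams()` fabricates
grid-aligned onsets plus markers with injected latency and Gaussian jitter;
the acceptance check demands the report recover an injected 10-ms latency
within $3\cdot SEM$ and a 2-ms jitter SD within 10% on 48 events × 10 runs.
Real loopback measurements depend on drivers, buffers and hardware, and
published quartile/SEM figures from physical setups are explicitly not
something a synthetic audit can or should reproduce; `detect_onsets()`
(causal moving-average envelope, fractional-of-peak threshold, refractory
gap) exists so recorded WAV loopbacks can be audited with the same report.

## What the simulations do and do not show

The synthetic observer is stationary, memoryless and exactly
Gaussian-sigmoidal; it has no lapses, no attention drift, no learning, no
interval bias, and (by default) no guessing floor. Passing validation
therefore demonstrates that the *procedure* — staircase bookkeeping,
scheduling, logging and statistics — behaves correctly, not that a human
AMDT threshold would be recovered with this precision. Stimulus rendering
is likewise idealized: no sound card, no buffering, no physical playback
chain.

## Problem sizes and runtime

The shipped tests and the acceptance analysis use the full validation
design (10 participants × 4 conditions × 108 trials, 40 scored runs),
1000-case replay-equivalence sweeps, and $10^4$–$10^5$-draw response-rate
checks; everything completes in well under a minute on a single core,
which is why no smaller "fast" path exists.
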