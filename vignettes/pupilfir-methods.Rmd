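---
title: "Methods: FIR deconvolution and kernel modelling of pupil-size time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FIR deconvolution and kernel modelling of pupil-size time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilfir)
```

## The problem

Pupil size is a single number per time point that mixes several sources:
fast, cognitively driven arousal responses ("phasic"); much larger
responses to blinks and (micro-)saccades, driven by transient changes in
effective retinal illumination; and a slowly drifting baseline ("tonic")
linked to arousal state. Naive event-locked averaging confounds these.
`pupilfir` separates them with a regression approach: every event type's
impulse response is estimated *simultaneously* by least squares, so that
linear contamination of the interesting responses by ocular responses is
removed, and the slow baseline is analysed as a signal of its own.

## Preprocessing

A raw recording (typically 1000 Hz) passes through a fixed stage order:

1. **Blink interpolation.** Samples from 150 ms before each blink onset
   to 150 ms after its offset are replaced by the straight line joining
   the boundary samples; overlapping windows are merged first. Windows
   clipped by a recording edge hold the nearest valid value. Remaining
   brief dropout runs are repaired with the same rule and zero padding.
2. **Band-pass (phasic branch).** Zero-phase third-order Butterworth,
   0.02--4 Hz. The low-pass removes measurement noise above the pupil's
   own bandwidth; the high-pass removes drifts that the event-locked
   model cannot account for.
3. **Low-pass (tonic branch).** Zero-phase third-order Butterworth at
   0.02 Hz applied to the same interpolated signal; this slow component
   is the tonic pupil size.
4. **Normalization.** Each condition segment is demeaned; all segments
   of a session are divided by one standard deviation computed from the
   session's concatenated band-passed signal, so between-condition
   amplitude comparisons stay meaningful. Units are then z-scores.
5. **Resampling to 10 Hz** by averaging blocks centred on the output
   sample times (no timing bias; see "Numerical choices").

Zero-phase (forward--backward) filtering is used throughout because a
causal filter would delay every kernel by its group lag and bias the
timing results; the direction of filtering is a package design choice.

### Numerical choices in the filters

Butterworth coefficients in transfer-function form degenerate
numerically when the normalized cutoff is tiny (0.02 Hz at 1000 Hz is
2e-5 of the sampling rate). `zerophase_lowpass()` therefore
block-averages the signal down to an internal rate at which the
normalized cutoff is at least 0.01, filters there, and interpolates back;
content above the internal Nyquist frequency is in the filter's deep
stop band by construction. Each pass is initialized at the steady state
of the first sample and the signal is padded by odd reflection, so a
constant input is reproduced to ~1e-10 and a slow exponential decay
(tau = 60 s) is tracked to a few tenths of a percent away from the
record edges. High-pass filtering is implemented as the complement
`x - lowpass(x)`, which is zero-phase and numerically exact at any
cutoff. Within roughly one filter time constant of the record edges the
output is dominated by boundary effects, as with any finite-record
filter; analyses should discard those margins where they matter.

## FIR deconvolution

For event types $c = 1..E$ with a kernel window $[-0.5, 5)$ s at 10 Hz
($L = 55$ lags per kernel, $E \cdot L = 220$ columns for the standard
four types), the design matrix $X$ contains staggered 0/1 indicators:
for an event at time $t$ and lag $\ell_j$, the row nearest $t + \ell_j$
of column $(c, j)$ is 1. The kernel estimate is the least-squares
solution

$$\hat h = (X^\top X)^{-1} X^\top y,$$

computed through the SVD of $X$. If the design is ill-conditioned
(condition number above 1e10; short runs with few blinks can be rank
deficient), small singular values are dropped and the minimum-norm
solution is returned with a warning. Events are mapped to the nearest
sample (round-to-nearest, unbiased for uniformly distributed event
phases). Blink kernels are anchored at blink *offset* (eye reopening);
saccade event times are taken to be saccade offsets as reported by the
tracker.

Estimated kernels are post-processed the way group results are usually
reported: a zero-phase 4 Hz low-pass, then subtraction of the mean over
the $[-0.5, 0)$ s baseline window.

**Variance partition.** The contribution of event type $c$ is
quantified as $\mathrm{Var}(X_c \hat h_c) / \sum_{c'}
\mathrm{Var}(X_{c'} \hat h_{c'})$ — the variance of the fitted
contribution of that type, normalized across types. Covariance
cross-terms between types are excluded so the fractions are
non-negative and sum to one; this convention is recorded in the output.
With the canonical kernels and realistic event rates the ocular types
(blinks + saccades) dominate the partition, which is the package's main
argument for always modelling them.

## Parametric kernels

Three families describe the estimated responses:

* `gamma_kernel(shape k, scale θ, gain)` — gain-scaled gamma
  *probability density*. The gain multiplies the normalized density
  (the kernel integrates to `gain`); under this convention the two
  published parameter tables describe the same curves, which is the
  evidence for the reading (peak times agree to < 0.2 s and peak
  amplitudes to < 15% between parameterizations; the blink-negative
  mode $(k-1)\theta$ matches the printed time to peak to three
  decimals).
* `erlang_kernel(scale s, shape n, t_peak)` — unnormalized
  $s\,x^{n}e^{-n x / x_{max}}$, whose extremum lies exactly at
  `t_peak`, making timing directly readable from the parameter.
* `double_gamma_kernel(negative, positive)` — the biphasic blink
  response: fast constriction then slow re-dilation, with the
  negative component's mode constrained to precede the positive one's.

`canonical_kernels()` returns the published constants in both
parameterizations. Note the Erlang blink-negative scale (−6661.622) is
large only because the form is unnormalized; the curve's peak is
≈ −0.77 z, in agreement with the gamma parameterization.

**Fitting.** `fit_kernel()` does least squares on lags ≥ 0. Amplitude
parameters enter linearly and are profiled out exactly at every
objective evaluation; the remaining shape parameters are searched by
Nelder--Mead on log scale from a fixed list of deterministic starts
(moment-based plus canonical-parameter initializations), so fits are
bit-for-bit reproducible. Double-gamma fits reject parameter vectors
that violate the sign or mode-ordering constraints. All-zero input is
returned with zero gain and flagged degenerate.

**Nuisance cleaning.** `nuisance_clean()` implements the recommended
GLM: convolve the blink and saccade impulse trains with the canonical
(or fitted) kernel shapes truncated at 6 s (beyond which the canonical
curves are < 1% of peak), add an intercept, solve ordinary least
squares, and hand the residuals to further analysis. Regressors carry
the kernels' own gains, so a fitted coefficient of 1 means "the data
contain this response at exactly its canonical amplitude".

**Tonic decay.** Within a run, tonic pupil size falls roughly
exponentially from its initial level. `fit_exponential_decay()` fits
$a e^{-t/\tau} + c$; given $\tau$ the problem is linear, so only
$\tau$ is searched (golden-section on log scale over
[duration/200, 10·duration]), making the fit deterministic and robust.
A non-decaying input pins $\tau$ at the bound and warns.

## Group statistics

`cluster_permutation_test()` is the standard nonparametric fix for
per-lag multiple comparisons: per-lag t statistics (one-sample against
zero, or paired through differencing), a two-sided cluster-forming
threshold at p < 0.05 (df = n−1), cluster mass = summed t over
contiguous same-sign supra-threshold lags, and a null distribution of
the maximum absolute mass from random sign flips.
`p = (1 + #{null ≥ observed}) / (1 + n_perm)`, so p-values are never
zero and are reproducible given the seed. The cluster-forming threshold
and the default 1000 permutations are declared package defaults, not
values taken from any particular study. A zero-variance lag is guarded
by a small epsilon rather than producing an infinite t.

`median_split_by_tonic()` partitions events of the types of interest at
the median of their per-event tonic values (window mean of the tonic
signal over −0.5..0 s, z-scored per run; ties go to the low side) and
deconvolves each half with the full nuisance design retained. All-equal
tonic values trigger an event-order parity fallback and a degenerate
flag.

## The synthetic-session generator

`experiment_spec()` + `simulate_session()` emulate the study design the
analysis was built for: two sound types whose inter-event intervals are
either narrowly Gaussian (mean 3 s, sd 0.4 s in version 1; 5 s / 0.5 s
in version 2) or 1.5 s plus an exponential of matching mean (flat
hazard); identities either alternate strictly or follow a Markov chain
with 40% transition probability; blinks and saccades at 0.11 and 0.8 Hz;
event-locked responses from the canonical kernels; a tonic drift
(default: amplitude 1 z, tau 60 s — a run-length-scale decay matching
the "first minutes of a recording" phenomenology); white Gaussian
measurement noise at the raw rate (default sd 0.1 z); and blink-induced
dropout (samples zeroed and flagged invalid, ±20 ms around each blink)
for the interpolation stage to repair.

Design choices worth flagging:

* **Refractory ocular events.** Blinks and saccades are renewal
  processes — exponential intervals plus a dead time (0.15 s for
  saccades, 0.5 s for blinks) with the intensity corrected so the
  long-run rates equal the nominal rates exactly. Intersaccadic
  intervals below ~150 ms are physiologically impossible, and two
  same-type events inside one 0.1 s analysis bin cannot be represented
  by a 0/1 indicator design at all, so a pure Poisson model would
  inject artificial misfit the real eye never produces.
* **Tonic-phasic coupling** is modelled multiplicatively: each event's
  kernel is scaled by $1 - \beta \cdot z(t_{event})$, where $z$ is the
  z-scored tonic value at the event. This is the simplest generative
  form able to produce the median-split effect; $\beta$ defaults to 0
  so the baseline generator is assumption-free about the coupling.
* **Noise** is white at the raw rate; the band-pass stage shapes it.
  Real pupil noise has 1/f character and the generator makes no claim
  to reproduce it.
* Saccade amplitudes are log-normal with analytic mode below 1 degree
  (microsaccades dominate), matching the observed amplitude
  distribution qualitatively.

### What recovery tests do and do not show

With event times aligned to the 10 Hz analysis grid and no noise, the
staggered design is exactly specified and deconvolution plus parametric
fitting returns the canonical gains to better than 1e-3 — this is the
package's identifiability check, and the configuration used by
`scripts/acceptance.R`. With *continuous* event times the design is
misspecified by sub-sample jitter: each event's response is sampled at
lags offset by up to ±50 ms, which acts as a random smoothing and adds
irreducible misfit. Single-session gain estimates then vary by roughly
±0.01--0.02 even without noise. Both regimes are exercised by the test
suite; real recordings are of course in the second one.

A subtler, known limitation concerns the 0.02 Hz high-pass: it removes
each kernel train's *own* slow spectral content, leaving a systematic,
hump-shaped deficit of order 0.01 z on the recovered sound kernels
(baseline subtraction removes only its constant part). Estimates from
band-passed data therefore sit slightly but systematically off the
unfiltered generative truth. Because simulated subjects share identical
true kernels, the between-subject standard error is of order 0.002 z,
several times smaller than that bias, so a per-lag "within 2 SEM of
truth" criterion fails at many sound-kernel lags despite gains, shapes
and timing being recovered well. This is a property of the published
pipeline itself (any kernel estimated from high-passed data carries it),
not of this implementation; it is visible here only because the
simulation makes the unfiltered truth available.

## Problem sizes used in the shipped tests

Test problem sizes are chosen as the smallest that make each property
measurable: 300 s sessions (≈100 sounds, 240 saccades, 33 blinks) for
recovery checks, 38 simulated subjects for group-level coverage
(matching the study's sample size), 200 null simulations × 1000
permutations for type-I calibration of the cluster test, and 10
sessions per coupling level for the median-split direction and null
checks.
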