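# pupilfir

FIR deconvolution and kernel modelling for pupillometry.

Pupil size recorded during cognitive experiments mixes three things: a
fast, event-locked arousal response of interest; much larger responses
to blinks and (micro-)saccades, driven by transient changes in
effective retinal illumination; and a slowly drifting tonic baseline.
`pupilfir` untangles them for anyone analysing pupil time series —
psychophysicists, cognitive neuroscientists, and methods developers who
need a tested reference implementation with synthetic ground truth.

## The method

The phasic signal `y` (band-passed 0.02–4 Hz, z-scored, 10 Hz) is
modelled as a superposition of event-locked impulse responses. For each
event type a finite impulse-response (FIR) kernel over lags −0.5..5 s
(55 samples per kernel, 220 design columns for the standard four types)
is estimated *simultaneously* by least squares on a staggered 0/1
indicator design matrix `X`:

    h = (XᵀX)⁻¹ Xᵀ y

so blink- and saccade-driven variance cannot masquerade as a cognitive
response. Estimated kernels are then described parametrically with
gamma-family shapes:

* gamma density with gain: `v(x) = gain · x^(k−1) e^(−x/θ) / (θᵏ Γ(k))`
* Erlang-gamma: `v(x) = s · xⁿ e^(−n·x/x_max)` (peak exactly at `x_max`)
* double gamma (negative + positive component) for the biphasic blink
  response

`canonical_kernels()` ships both published parameterizations (auditory
event, blink negative/positive, saccade). The tonic branch (0.02 Hz
low-pass) yields per-event baseline values and an exponential decay fit
within runs; `cluster_permutation_test()` provides nonparametric
inference on kernel time courses, and `nuisance_clean()` regresses
canonical blink/saccade responses out of a signal via a convolution
GLM. A full synthetic-session generator (`experiment_spec()`,
`simulate_session()`) reproduces the study design — 2×2 timing/identity
predictability, Poisson-with-refractory ocular events, tonic drift,
noise, blink dropout — and returns ground truth for every stage.

## Worked example

Simulate a 5-minute session, preprocess, deconvolve all four event
types at once, and fit a gamma kernel to the auditory response:

```r
library(pupilfir)

spec <- experiment_spec(run_duration = 300, seed = 42)
ses  <- simulate_session(spec)

pre <- preprocess_pupil(ses$raw,
                        blinks = events_of_type(ses$truth$events, "blink"),
                        normalize = FALSE)   # simulator output is already in z-units

design <- build_design_matrix(ses$truth$events,
                              n_samples = length(pre$phasic$samples),
                              rate = 10, window = c(-0.5, 5),
                              event_types = c("sound_high", "sound_low",
                                              "blink", "saccade"))
fit <- postprocess_kernels(fir_deconv(design, pre$phasic))
summary(fit)
#> <fir_fit> 4 event types x 55 lags (window [-0.5, 5) s @ 10 Hz)
#>   R^2 = 0.9751, residual sd = 0.03823
#>   types: sound_high, sound_low, blink, saccade
#>
#> Per-type peak and timing:
#>               peak t_peak
#> sound_high  0.2079    1.2
#> sound_low   0.1825    1.4
#> blink      -0.7273    0.8
#> saccade    -0.1710    0.9
#>
#> Explained-variance fractions:
#> sound_high  sound_low      blink    saccade
#>     0.0790     0.0724     0.6564     0.1922
#> Total R^2: 0.9751
```

The peaks and timing land where the canonical kernels put them: the
sound response peaks near 0.2 z at ~1.3 s, the blink response is a
large fast constriction (−0.73 z at 0.8 s) followed by slow
re-dilation, and the ocular types jointly account for ~85% of the
explained variance — the reason they must be modelled rather than
ignored. Fitting a parametric kernel and the tonic decay:

```r
round(coef(fit_kernel(fit$lags,
                      rowMeans(fit$kernels[, c("sound_high", "sound_low")]),
                      family = "gamma")), 3)
#> shape scale  gain
#> 4.753 0.346 0.340

fit_exponential_decay(pre$tonic)$tau
#> [1] 52.3      # seconds; the generator's true time constant is 60
```

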