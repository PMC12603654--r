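# durerp

Duration effects and overlap correction for regression ERPs.

Event-related brain responses — EEG ERPs, fixation-related potentials,
fMRI BOLD responses — often change shape with the *duration* of the
eliciting event (a fixation, a stimulus presentation, a reaction time),
and in continuous recordings they *overlap* with the responses to
neighboring events. In many designs the inter-event distance equals the
event duration, making the two confounds perfectly collinear. `durerp`
is a simulation and estimation toolkit for this joint problem, for
researchers analyzing continuous neural time series:

* **Simulator** — duration-modulated ground-truth kernels (`hanning`,
  `scaled_hanning`, `half_hanning`), block-structured event sequences
  with duration ≡ inter-event distance, AR(1)/white/pink noise, zero-phase
  windowed-sinc high-pass filtering.
* **Estimation** — regression ERPs `y ~ 1 + f(dur)` with linear,
  equal-count-binned (`bin(dur, 10)`) and quantile-breakpoint B-spline
  (`spl(dur, 5)`) duration encodings, fit either mass-univariately on
  epochs or with FIR time-expansion (deconvolution / linear overlap
  correction) on the continuous signal:

  y(t) = Σ_events Σ_lags Σ_terms x_term(event) · β(term, lag) · 1[t = onset + lag] + ε(t)

* **Evaluation** — marginal-effect time courses over a duration grid,
  max-marginal-effect summaries, and normalized MSE against ground truth
  (model MSE / intercept-only MSE; < 1 beats classical averaging) swept
  over scenarios and seeded repetitions.
* **Group statistics** — one-sample Hotelling T² on spline coefficients
  across subjects with Benjamini–Yekutieli FDR correction.

## Worked example

```r
library(durerp)

spec <- kernel_spec("scaled_hanning", sfreq = 50)   # peak grows with duration
sim  <- simulate_study(spec, dist = "halfnormal", n_events = 500, seed = 1)
sim$signal
#> <durerp_signal> 1 channel(s) x 25104 samples @ 50 Hz, t0=-2s (502.1 s)

w   <- basis_spec(-0.1, max(sim$events$duration) + 0.5, 50)
fit <- fit_model(sim$signal, sim$events, "y ~ 1 + spl(dur, 5)", w,
                 overlap_correction = TRUE)
fit
#> <durerp_fit> y ~ 1 + spl(dur, 5) [deconv] (deconvolution): 1 channel(s) x 1547 coefficient(s); rank 1547

eff <- marginal_effects(fit)        # curves at the 15 interior duration quantiles
round(mse_vs_truth(eff, spec, duration_effect_simulated = TRUE), 4)
#> [1] 0.2556

fit0 <- fit_model(sim$signal, sim$events, "y ~ 1", w, overlap_correction = TRUE)
eff0 <- marginal_effects(fit0, grid = eff$durations)
round(normalize_mse(mse_vs_truth(eff, spec, TRUE), mse_vs_truth(eff0, spec, TRUE)), 3)
#> [1] 0.689
```

The last number is the headline quantity: the spline-duration deconvolution
model reaches 69% of the error of classical averaging on this dataset —
modeling duration and correcting overlap simultaneously beats ignoring
duration, despite their perfect collinearity. `autoplot(eff)` draws the
marginal-effect curves; `run_sweep(sweep_config(...))` repeats such
comparisons over scenarios and repetitions, and `summarize_sweep()` reports
median normalized MSE per model. `tidy()` / `glance()` give broom-style
tables for fits, and `inst/cli/durerp` exposes
`simulate | fit | effects | evaluate | sweep` subcommands for shell use.

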