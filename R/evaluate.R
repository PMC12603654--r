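#' Mean squared error of marginal-effect predictions against ground truth
#'
#' For every grid duration the ground-truth kernel (the duration-modulated
#' kernel at that duration, or the fixed reference kernel if no duration
#' effect was simulated) is zero-padded into the analysis window, aligned at
#' lag 0, and compared with the predicted curve; the squared error is then
#' averaged over grid durations, lags, and channels. Kernels extending past
#' the window are truncated at its edge.
#'
#' @param effects A `durerp_effects` from [marginal_effects()].
#' @param spec The [kernel_spec()] used in the simulation; its `sfreq` must
#'   match the fitted sampling rate.
#' @param duration_effect_simulated Was the duration effect simulated? If
#'   `FALSE` the truth is the reference-duration kernel for every grid value.
#' @return Raw MSE (signal units squared).
#' @export
mse_vs_truth <- function(effects, spec, duration_effect_simulated = TRUE) {
  stopifnot(inherits(effects, "durerp_effects"), inherits(spec, "durerp_kernel_spec"))
  if (abs(spec$sfreq - effects$sfreq) > 1e-9) {
    rlang::abort("kernel and effect lag grids are misaligned (different sampling rates)")
  }
  L <- length(effects$lag_sec)
  idx0 <- which.min(abs(effects$lag_sec))
  if (abs(effects$lag_sec[idx0]) > 1e-9) {
    rlang::abort("effect lag grid does not contain lag 0; cannot align ground truth")
  }
  truth <- matrix(0, nrow = length(effects$durations), ncol = L)
  for (i in seq_along(effects$durations)) {
    d <- if (duration_effect_simulated) effects$durations[i] else spec$ref_duration
    k <- make_kernel(spec, d)
    n <- min(length(k), L - idx0 + 1)
    truth[i, idx0:(idx0 + n - 1)] <- k[seq_len(n)]
  }
  errs <- vapply(seq_len(dim(effects$curves)[3]), function(ch) {
    mean((effects$curves[, , ch] - truth)^2)
  }, numeric(1))
  mean(errs)
}

#' Normalize an MSE against the intercept-only reference
#'
#' @param model_mse Raw MSE of the model under evaluation.
#' @param reference_mse Raw MSE of the intercept-only fit of the same
#'   dataset under the same overlap-correction setting (must be > 0).
#' @return `model_mse / reference_mse`; values below 1 mean the model beats
#'   classical averaging.
#' @export
normalize_mse <- function(model_mse, reference_mse) {
  if (!is.finite(reference_mse) || reference_mse <= 0) {
    rlang::abort("reference MSE must be positive (degenerate noise-free edge case)")
  }
  model_mse / reference_mse
}

#' Root-mean-square amplitude of marginal-effect curves
#'
#' Used to quantify the wave-like estimation artifact that appears when
#' duration is both a predictor and the inter-event spacing of the FIR
#' time-expanded design: on pure-noise data the estimates should be near
#' zero, so a large RMS flags the collinearity artifact.
#'
#' @param effects A `durerp_effects`.
#' @return Scalar RMS over all grid durations, lags, and channels.
#' @export
effect_curve_rms <- function(effects) {
  stopifnot(inherits(effects, "durerp_effects"))
  sqrt(mean(effects$curves^2))
}

default_encodings <- function() {
  list(intercept  = "y ~ 1",
       linear     = "y ~ 1 + dur",
       categorical = "y ~ 1 + bin(dur, 10)",
       spline5    = "y ~ 1 + spl(dur, 5)",
       spline10   = "y ~ 1 + spl(dur, 10)")
}

#' Evaluation sweep configuration
#'
#' Defines the scenario grid and analysis settings for [run_sweep()]. The
#' defaults mirror the simulation study: 500 events in blocks of 25, the
#' three kernel shapes, duration effect and overlap each on/off, uniform and
#' half-normal spacing distributions, five model encodings (intercept,
#' linear, 10-bin categorical, 5- and 10-function B-splines) each fit with
#' and without overlap correction, normalized MSE at the 15 interior
#' duration quantiles, and 50 repetitions.
#'
#' @param shapes,duration_effect,overlap,distributions Scenario factors.
#' @param encodings Named list of model formulas; must contain `intercept`
#'   (the normalization reference).
#' @param corrections Overlap-correction settings to fit.
#' @param n_events,block_size,inter_block_interval Event-sequence settings.
#' @param noise A [noise_spec()].
#' @param filter_cutoff High-pass -6 dB cutoff (Hz) or `NULL`.
#' @param sfreq Sampling frequency (Hz) for kernels and signal.
#' @param ref_duration,base_amplitude Kernel parameters.
#' @param tmin Epoch/FIR window start (s, relative to onset).
#' @param grid Duration grid for marginal effects and MSE.
#' @param repetitions Repetitions per scenario.
#' @param global_seed Integer master seed.
#' @return A list of class `durerp_sweep_config`.
#' @export
sweep_config <- function(shapes = c("scaled_hanning", "hanning", "half_hanning"),
                         duration_effect = c(TRUE, FALSE),
                         overlap = c(TRUE, FALSE),
                         distributions = c("halfnormal", "uniform"),
                         encodings = default_encodings(),
                         corrections = c(TRUE, FALSE),
                         n_events = 500, block_size = 25,
                         inter_block_interval = 5,
                         noise = noise_spec(),
                         filter_cutoff = 0.5,
                         sfreq = 50, ref_duration = 0.5, base_amplitude = 1,
                         tmin = -0.1,
                         grid = "quantiles:15",
                         repetitions = 50,
                         global_seed = 1) {
  stopifnot("intercept" %in% names(encodings))
  structure(as.list(environment()), class = "durerp_sweep_config")
}

scenario_seed <- function(global_seed, scenario_index, repetition) {
  ((global_seed %% 40009) * 40013 + scenario_index * 4001 + repetition * 101) %%
    2147483629L
}

#' Fit and score all configured models on one simulated dataset
#'
#' @param sim A list with `signal` and `events` (as from [simulate_study()]).
#' @param kspec The generating [kernel_spec()].
#' @param config A [sweep_config()] (supplies encodings, corrections, grid,
#'   window start).
#' @param duration_effect_simulated Whether the dataset was simulated with a
#'   duration effect (defines the ground truth for the MSE).
#' @param corrections Overlap-correction settings to evaluate (default from
#'   config).
#' @return Tibble with one row per encoding x correction: `model`,
#'   `overlap_correction`, `raw_mse`, `normalized_mse`.
#' @export
evaluate_dataset <- function(sim, kspec, config = sweep_config(),
                             duration_effect_simulated = TRUE,
                             corrections = NULL) {
  corrections <- corrections %||% config$corrections
  window <- basis_spec(config$tmin,
                       max(sim$events$duration) + config$ref_duration,
                       kspec$sfreq)
  rows <- list()
  for (corr in corrections) {
    mses <- purrr::imap(config$encodings, function(f, nm) {
      tryCatch({
        fit <- fit_model(sim$signal, sim$events, f, window,
                         overlap_correction = corr, model_tag = nm)
        eff <- if (nm == "intercept") {
          # no duration term: evaluate the constant prediction on the same grid
          marginal_effects(fit, grid = intercept_grid(sim$events, config$grid))
        } else {
          marginal_effects(fit, grid = config$grid)
        }
        mse_vs_truth(eff, kspec, duration_effect_simulated)
      }, error = function(e) {
        rlang::inform(sprintf("model %s (correction=%s) failed: %s", nm, corr,
                              conditionMessage(e)))
        NA_real_
      })
    })
    ref <- mses$intercept
    for (nm in names(mses)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        model = nm, overlap_correction = corr,
        raw_mse = mses[[nm]],
        normalized_mse = if (is.na(mses[[nm]]) || is.na(ref)) NA_real_ else
          normalize_mse(mses[[nm]], ref))
    }
  }
  dplyr::bind_rows(rows)
}

intercept_grid <- function(events, grid) {
  if (is.character(grid) && grepl("^quantiles:", grid)) {
    k <- as.integer(sub("^quantiles:", "", grid))
    unname(stats::quantile(events$duration, probs = seq_len(k) / (k + 1)))
  } else as.numeric(grid)
}

#' Run the full simulation-evaluation sweep
#'
#' For every scenario (shape x duration effect x overlap x distribution) and
#' repetition: simulate a continuous dataset, fit every configured encoding
#' with and without overlap correction, compute marginal effects on the
#' duration-quantile grid, and score normalized MSE against the ground
#' truth. Fully seeded and deterministic given `config$global_seed`;
#' per-model failures are recorded as `NA` rows rather than aborting.
#'
#' @param config A [sweep_config()].
#' @param progress Print a line per scenario? Default `FALSE`.
#' @return Long tibble: scenario fields, `repetition`, `model`,
#'   `overlap_correction`, `raw_mse`, `normalized_mse`.
#' @export
run_sweep <- function(config = sweep_config(), progress = FALSE) {
  stopifnot(inherits(config, "durerp_sweep_config"))
  scen <- tidyr::expand_grid(shape = config$shapes,
                             duration_effect = config$duration_effect,
                             overlap = config$overlap,
                             dist = config$distributions)
  out <- list()
  for (si in seq_len(nrow(scen))) {
    sc <- scen[si, ]
    if (progress) {
      rlang::inform(sprintf("scenario %d/%d: %s dur=%s overlap=%s %s",
                            si, nrow(scen), sc$shape, sc$duration_effect,
                            sc$overlap, sc$dist))
    }
    kspec <- kernel_spec(sc$shape, ref_duration = config$ref_duration,
                         sfreq = config$sfreq,
                         base_amplitude = config$base_amplitude)
    for (rep_i in seq_len(config$repetitions)) {
      seed <- scenario_seed(config$global_seed, si, rep_i)
      sim <- simulate_study(kspec, dist = sc$dist,
                            n_events = config$n_events,
                            block_size = config$block_size,
                            inter_block_interval = config$inter_block_interval,
                            duration_effect = sc$duration_effect,
                            overlap = sc$overlap,
                            noise = config$noise,
                            filter_cutoff = config$filter_cutoff,
                            seed = seed)
      res <- evaluate_dataset(sim, kspec, config,
                              duration_effect_simulated = sc$duration_effect)
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble::tibble(shape = sc$shape, duration_effect = sc$duration_effect,
                       overlap = sc$overlap, dist = sc$dist,
                       repetition = rep_i, seed = seed),
        res)
    }
  }
  dplyr::bind_rows(out)
}

#' Summarize a sweep by median normalized MSE
#'
#' @param results Output of [run_sweep()].
#' @return Tibble with medians per scenario x model x correction.
#' @export
summarize_sweep <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$shape, .data$duration_effect, .data$overlap,
                    .data$dist, .data$model, .data$overlap_correction),
    median_normalized_mse = stats::median(.data$normalized_mse, na.rm = TRUE),
    n = dplyr::n(), .groups = "drop")
}

#' Boxplot of normalized MSE per model
#'
#' @param results Output of [run_sweep()], typically filtered to one
#'   scenario.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_sweep <- function(results, ...) {
  df <- dplyr::filter(results, .data$model != "intercept")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$normalized_mse,
                                   fill = .data$overlap_correction)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(y = "normalized MSE (1 = classical averaging)", x = NULL) +
    ggplot2::theme_minimal()
}
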