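#' Sample an event sequence with collinear duration/overlap structure
#'
#' Draws inter-event distances i.i.d. from a uniform or half-normal
#' distribution and builds a block-structured event table in which, within a
#' block, each event's duration equals the distance to the next event. This
#' makes the duration effect and the temporal overlap perfectly collinear,
#' the defining difficulty of the study design. The last event of each block
#' has no successor; its duration is an independent draw from the same
#' distribution.
#'
#' With `overlap = FALSE` durations are still drawn from the named
#' distribution, but onsets are spaced `duration + clearance` apart so that
#' responses (and analysis epochs, for a clearance at least as long as the
#' epoch window) never overlap.
#'
#' @param dist `"uniform"` (on \[0, 3.5\] s) or `"halfnormal"`
#'   (|Normal(0, 1)|), mimicking experimentally set stimulus durations and
#'   free-viewing fixation durations respectively.
#' @param n_events Number of events (>= 1). Default 500.
#' @param block_size Events per block; after each block an event-free gap of
#'   `inter_block_interval` seconds is inserted. Default 25.
#' @param inter_block_interval Gap between blocks in seconds. Default 5.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param overlap If `FALSE`, space events out (see above). Default `TRUE`.
#' @param clearance Extra spacing (s) used when `overlap = FALSE`.
#' @param min_distance Lower floor (s) applied to sampled distances so every
#'   kernel has at least a few samples of support. Default 0.06 s (3 samples
#'   at a 50 Hz sampling rate).
#' @param trial_type Label assigned to all events. Default `"event"`.
#' @return A tibble with columns `onset`, `duration`, `trial_type`
#'   (an event table). Onsets are strictly increasing and start at 0.
#' @export
sample_event_sequence <- function(dist = c("uniform", "halfnormal"),
                                  n_events = 500, block_size = 25,
                                  inter_block_interval = 5, seed = NULL,
                                  overlap = TRUE, clearance = 4,
                                  min_distance = 0.06,
                                  trial_type = "event") {
  dist <- match.arg(dist)
  stopifnot(n_events >= 1, block_size >= 1)
  if (block_size < n_events && inter_block_interval <= 0 && overlap) {
    rlang::abort("`inter_block_interval` must be positive when events span several blocks.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  draw <- function(n) {
    d <- switch(dist,
                uniform = stats::runif(n, 0, 3.5),
                halfnormal = abs(stats::rnorm(n, 0, 1)))
    pmax(d, min_distance)
  }

  durations <- draw(n_events)
  block <- (seq_len(n_events) - 1) %/% block_size
  if (overlap) {
    # within a block the next onset is exactly `duration` away; the final
    # event of a block keeps its independent duration draw
    gaps <- durations
    gaps[diff(c(block, utils::tail(block, 1) + 1)) != 0] <- NA # block-final events
    onset <- numeric(n_events)
    for (i in seq_len(n_events)[-1]) {
      step <- if (is.na(gaps[i - 1])) durations[i - 1] + inter_block_interval else gaps[i - 1]
      onset[i] <- onset[i - 1] + step
    }
  } else {
    step <- durations + clearance
    extra <- ifelse(diff(c(block, utils::tail(block, 1) + 1))[-n_events] != 0,
                    inter_block_interval, 0)
    onset <- c(0, cumsum(step[-n_events] + extra))
  }

  tibble::tibble(onset = onset, duration = durations, trial_type = trial_type)
}

#' Render an event table into a continuous noise-free signal
#'
#' Places one ground-truth kernel per event at `round(onset * sfreq)` and sums
#' them wherever supports overlap (linear superposition). The returned signal
#' is zero-padded by `total_padding` seconds at both ends (`t0 = -total_padding`).
#'
#' @param events Event table (tibble with `onset`, `duration`).
#' @param spec A [kernel_spec()].
#' @param total_padding Zero padding in seconds at each end. Default 2 s.
#' @param duration_effect If `FALSE`, every event is rendered with the
#'   reference-duration kernel (the recorded durations remain as covariates).
#' @param amplitude If `0`, no signal is rendered (pure-noise studies).
#' @return A single-channel [signal()].
#' @export
render_continuous <- function(events, spec, total_padding = 2,
                              duration_effect = TRUE, amplitude = NULL) {
  stopifnot(nrow(events) > 0, inherits(spec, "durerp_kernel_spec"))
  sfreq <- spec$sfreq
  pad <- as.integer(round(total_padding * sfreq))
  durs <- if (duration_effect) events$duration else rep(spec$ref_duration, nrow(events))
  max_len <- max(vapply(durs, function(d) kernel_support(spec, d), integer(1)))
  n <- as.integer(round(max(events$onset) * sfreq)) + max_len + 2L * pad
  y <- numeric(n)
  if (is.null(amplitude) || amplitude != 0) {
    for (i in seq_len(nrow(events))) {
      k <- make_kernel(spec, durs[i])
      s0 <- as.integer(round(events$onset[i] * sfreq)) + pad + 1L
      idx <- s0:(s0 + length(k) - 1L)
      if (utils::tail(idx, 1) > n) {
        rlang::abort("internal error: kernel extends beyond the allocated signal.")
      }
      y[idx] <- y[idx] + k
    }
  }
  signal(y, sfreq = sfreq, t0 = -total_padding)
}

#' Noise specification
#'
#' @param kind `"none"`, `"white"`, `"ar1"`, or `"pink"`.
#' @param amplitude Marginal standard deviation of the noise (signal units).
#' @param ar_coefficient AR(1) coefficient in (-1, 1); used for `kind = "ar1"`.
#' @param seed Integer seed.
#' @return Object of class `durerp_noise_spec`.
#' @export
noise_spec <- function(kind = c("ar1", "white", "pink", "none"),
                       amplitude = 0.4, ar_coefficient = 0.9, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(amplitude >= 0)
  if (kind == "ar1") stopifnot(abs(ar_coefficient) < 1)
  structure(list(kind = kind, amplitude = amplitude,
                 ar_coefficient = ar_coefficient, seed = seed),
            class = "durerp_noise_spec")
}

generate_noise <- function(noise, n) {
  if (noise$kind == "none" || noise$amplitude == 0) return(numeric(n))
  if (!is.null(noise$seed)) withr::local_seed(noise$seed)
  x <- switch(noise$kind,
    white = stats::rnorm(n),
    ar1 = {
      burn <- 500L
      e <- stats::rnorm(n + burn, sd = sqrt(1 - noise$ar_coefficient^2))
      z <- stats::filter(e, noise$ar_coefficient, method = "recursive")
      as.numeric(z)[(burn + 1):(burn + n)]
    },
    pink = {
      # shape a white spectrum by 1/sqrt(f); exact unit variance by rescale
      m <- n + n %% 2
      f <- c(1, seq_len(m - 1))
      sc <- 1 / sqrt(pmin(f, m - f + 1))
      z <- Re(stats::fft(stats::fft(stats::rnorm(m)) * sc, inverse = TRUE)) / m
      z <- z[seq_len(n)]
      z / stats::sd(z)
    })
  noise$amplitude * x
}

#' Add generated noise to a signal
#'
#' @param sig A [signal()].
#' @param noise A [noise_spec()]. Amplitude 0 or kind `"none"` returns the
#'   input unchanged; otherwise the same generated noise trace is produced
#'   for a given seed.
#' @return A [signal()] of the same shape.
#' @export
add_noise <- function(sig, noise) {
  stopifnot(inherits(sig, "durerp_signal"), inherits(noise, "durerp_noise_spec"))
  if (noise$kind == "none" || noise$amplitude == 0) return(sig)
  out <- sig
  for (ch in seq_len(nrow(sig$data))) {
    ns <- noise
    if (!is.null(ns$seed)) ns$seed <- ns$seed + ch - 1L
    out$data[ch, ] <- sig$data[ch, ] + generate_noise(ns, ncol(sig$data))
  }
  out
}

# windowed-sinc FIR high-pass: lowpass by Hamming-windowed sinc at the cutoff
# (-6 dB there by half-band symmetry), spectrally inverted with an exact DC
# null (taps sum to zero by construction).
design_highpass <- function(sfreq, cutoff, transition = 0.5) {
  n_taps <- as.integer(ceiling(3.3 * sfreq / transition))
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  m <- (n_taps - 1L) / 2L
  k <- -m:m
  fc <- cutoff / sfreq
  lp <- 2 * fc * sinc_fn(2 * fc * k)
  w <- 0.54 + 0.46 * cos(pi * k / m) # Hamming
  lp <- lp * w
  lp <- lp / sum(lp)
  hp <- -lp
  hp[m + 1L] <- hp[m + 1L] + 1
  hp
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Magnitude response of an FIR filter
#'
#' @param taps FIR coefficients.
#' @param freqs Frequencies in Hz at which to evaluate.
#' @param sfreq Sampling frequency in Hz.
#' @return Numeric vector of magnitudes (linear scale).
#' @export
fir_response <- function(taps, freqs, sfreq) {
  k <- seq_along(taps) - 1
  vapply(freqs, function(f) {
    Mod(sum(taps * exp(-2i * pi * f / sfreq * k)))
  }, numeric(1))
}

#' Zero-phase FIR high-pass filter
#'
#' Applies a Hamming-windowed-sinc high-pass whose magnitude response is 0.5
#' (-6 dB) at `cutoff_minus6db` and exactly zero at DC. The symmetric
#' (linear-phase) kernel is applied once with group-delay compensation, so the
#' overall application is zero-phase and keeps the designed -6 dB point. The
#' signal is zero-padded by half the kernel length at both ends before
#' convolution; output length equals input length.
#'
#' @param sig A [signal()].
#' @param cutoff_minus6db -6 dB cutoff frequency in Hz (0 < cutoff < Nyquist).
#' @param transition Transition bandwidth in Hz (default 0.5).
#' @return Filtered [signal()].
#' @export
highpass_filter <- function(sig, cutoff_minus6db = 0.5, transition = 0.5) {
  stopifnot(inherits(sig, "durerp_signal"))
  if (cutoff_minus6db <= 0 || cutoff_minus6db >= sig$sfreq / 2) {
    rlang::abort("`cutoff_minus6db` must lie strictly between 0 and the Nyquist frequency.")
  }
  h <- design_highpass(sig$sfreq, cutoff_minus6db, transition)
  m <- (length(h) - 1L) / 2L
  out <- sig
  for (ch in seq_len(nrow(sig$data))) {
    x <- c(numeric(m), sig$data[ch, ], numeric(m))
    y <- stats::filter(x, h, method = "convolution", sides = 2)
    out$data[ch, ] <- as.numeric(y)[(m + 1L):(m + ncol(sig$data))]
  }
  out
}

#' One-call simulation pipeline
#'
#' Samples an event sequence, renders the duration-modulated kernels into a
#' continuous signal, adds noise, and (optionally) high-pass filters —
#' the full data-generating process of the simulation study.
#'
#' @inheritParams sample_event_sequence
#' @param spec A [kernel_spec()].
#' @param duration_effect Render kernels modulated by event duration
#'   (`TRUE`) or the fixed reference kernel for every event (`FALSE`).
#' @param signal_present If `FALSE` the rendered signal is all-zero
#'   (pure-noise studies); events are still returned.
#' @param noise A [noise_spec()] (its `seed` field is overridden by `seed + 1`
#'   when `seed` is given, keeping event sampling and noise independent).
#' @param filter_cutoff High-pass -6 dB cutoff in Hz, or `NULL` to skip
#'   filtering. Default 0.5 Hz; filtering is applied after noise addition.
#' @param total_padding Zero padding (s) at both ends of the signal.
#' @return List with elements `signal` ([signal()]) and `events` (tibble).
#' @export
simulate_study <- function(spec,
                           dist = c("halfnormal", "uniform"),
                           n_events = 500, block_size = 25,
                           inter_block_interval = 5,
                           duration_effect = TRUE, overlap = TRUE,
                           signal_present = TRUE,
                           noise = noise_spec(),
                           filter_cutoff = 0.5,
                           clearance = 4,
                           total_padding = 2,
                           seed = NULL) {
  dist <- match.arg(dist)
  ev_seed <- if (is.null(seed)) NULL else seed
  events <- sample_event_sequence(dist, n_events, block_size,
                                  inter_block_interval, seed = ev_seed,
                                  overlap = overlap, clearance = clearance)
  sig <- render_continuous(events, spec, total_padding = total_padding,
                           duration_effect = duration_effect,
                           amplitude = if (signal_present) NULL else 0)
  if (!is.null(seed)) noise$seed <- seed + 1L
  sig <- add_noise(sig, noise)
  if (!is.null(filter_cutoff)) sig <- highpass_filter(sig, filter_cutoff)
  list(signal = sig, events = events)
}
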