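#' Parametric duration-modulated ground-truth kernels
#'
#' A kernel specification describes a family of "proto-ERP" shapes whose
#' sampled time course depends on the duration of the eliciting event. All
#' three families coincide at the reference duration and are built from a
#' raised-cosine (hanning) window:
#'
#' \describe{
#'   \item{`hanning`}{the window is stretched along the time axis only; the
#'     peak amplitude is constant across durations.}
#'   \item{`scaled_hanning`}{the window is stretched along both axes: the
#'     peak amplitude grows linearly with duration
#'     (`base_amplitude * duration / ref_duration`).}
#'   \item{`half_hanning`}{the rising half (up to the reference peak) is
#'     identical for every duration; only the falling half is stretched to
#'     fill the remaining support.}
#' }
#'
#' @param shape One of `"hanning"`, `"scaled_hanning"`, `"half_hanning"`.
#' @param ref_duration Reference duration in seconds (> 0) at which all
#'   three shapes produce the same sample vector. Default 0.5 s.
#' @param sfreq Sampling frequency in Hz (> 0). Default 100 Hz.
#' @param base_amplitude Peak amplitude (signal units) at the reference
#'   duration. Default 1.
#' @return An object of class `durerp_kernel_spec`.
#' @examples
#' spec <- kernel_spec("scaled_hanning", sfreq = 100)
#' k <- make_kernel(spec, duration = 0.8)
#' length(k) # round(0.8 * 100)
#' @export
kernel_spec <- function(shape = c("hanning", "scaled_hanning", "half_hanning"),
                        ref_duration = 0.5, sfreq = 100, base_amplitude = 1) {
  shape <- match.arg(shape)
  stopifnot(ref_duration > 0, sfreq > 0)
  structure(
    list(shape = shape, ref_duration = ref_duration, sfreq = sfreq,
         base_amplitude = base_amplitude),
    class = "durerp_kernel_spec"
  )
}

#' @export
print.durerp_kernel_spec <- function(x, ...) {
  cat(sprintf("<durerp_kernel_spec> shape=%s ref_duration=%gs sfreq=%gHz amplitude=%g\n",
              x$shape, x$ref_duration, x$sfreq, x$base_amplitude))
  invisible(x)
}

# raised cosine of n samples, peak 1, zero at both ends
hanning_window <- function(n) {
  if (n == 1) return(0)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Number of samples a kernel occupies at a given duration
#'
#' @param spec A [kernel_spec()].
#' @param duration Event duration in seconds.
#' @return Integer sample count, `round(duration * sfreq)`.
#' @export
kernel_support <- function(spec, duration) {
  as.integer(round(duration * spec$sfreq))
}

#' Sample a ground-truth kernel at a given duration
#'
#' Evaluates the duration-modulated proto-ERP described by `spec` at one
#' duration. The support length is `round(duration * sfreq)` samples; all
#' kernels start and end at zero.
#'
#' @inheritParams kernel_support
#' @return Numeric vector of signal samples.
#' @export
make_kernel <- function(spec, duration) {
  stopifnot(inherits(spec, "durerp_kernel_spec"))
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
      duration <= 0) {
    rlang::abort("`duration` must be a single positive number.")
  }
  n <- kernel_support(spec, duration)
  if (n < 3) {
    rlang::abort(sprintf(
      "duration %.4g s gives a support of %d samples at %g Hz; at least 3 are required.",
      duration, n, spec$sfreq))
  }
  a <- spec$base_amplitude
  switch(spec$shape,
    hanning = a * hanning_window(n),
    scaled_hanning = a * (duration / spec$ref_duration) * hanning_window(n),
    half_hanning = {
      n_ref <- as.integer(round(spec$ref_duration * spec$sfreq))
      h <- as.integer(round(n_ref / 2))   # fixed rising-half length
      m <- n - h                          # stretched falling-half length
      if (m < 2) {
        rlang::abort(sprintf(
          "half_hanning needs a support longer than its fixed rising half (%d samples); got %d.",
          h, n))
      }
      rising <- hanning_window(n_ref)[seq_len(h)]
      # falling part: the tail of the reference raised cosine, re-sampled so
      # that it spans [x_h, 1] in the window's phase coordinate
      x_h <- h / (n_ref - 1)
      x <- x_h + (1 - x_h) * (seq_len(m) - 1) / (m - 1)
      falling <- 0.5 * (1 - cos(2 * pi * x))
      a * c(rising, falling)
    }
  )
}
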