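#' Read / write BIDS-style event tables
#'
#' Events are stored as tab-separated text with a header (`events.tsv`
#' dialect): columns `onset`, `duration` (seconds), `trial_type`, then any
#' covariate columns, preserved by name and order. Lines starting with `#`
#' (provenance headers written by [write_events()]) are ignored on read.
#'
#' @param path File path.
#' @return A tibble event table.
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  required <- c("onset", "duration", "trial_type")
  missing_cols <- setdiff(required, names(ev))
  if (length(missing_cols)) {
    rlang::abort(sprintf("events file is missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  for (col in c("onset", "duration")) {
    if (!is.numeric(ev[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(ev[[col]]))))[1]
      rlang::abort(sprintf("non-numeric value in column `%s`, row %d", col, bad))
    }
  }
  if (is.unsorted(ev$onset, strictly = TRUE)) {
    rlang::abort("event onsets must be strictly increasing")
  }
  ev
}

#' @rdname read_events
#' @param events Event table (tibble with onset, duration, trial_type, ...).
#' @param meta Optional named list written as `# key: value` header lines
#'   (e.g. config hash and seed).
#' @export
write_events <- function(events, path, meta = list()) {
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)))
  header <- vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]),
                   character(1))
  events[] <- lapply(events, function(x) if (is.numeric(x)) signif(x, 9) else x)
  body <- readr::format_tsv(events)
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Write a fitted model as a tidy coefficient TSV
#'
#' @param fit A `durerp_fit`.
#' @param path Destination path.
#' @param meta Optional `# key: value` header entries.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(fit, path, meta = list()) {
  tb <- tidy(fit)
  header <- vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]),
                   character(1))
  writeLines(c(header, sub("\n$", "", readr::format_tsv(tb))), path)
  invisible(path)
}

#' Read / write a run configuration
#'
#' A run configuration is a flat YAML file describing the whole pipeline:
#' `global_seed`, a `simulation` block (kernel, event sampling, noise,
#' filter), a `model` block (formulas, window, overlap correction), and an
#' `evaluation` block (grid, repetitions). [config_hash()] gives a stable
#' digest that output files embed for provenance.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_config
#' @param config Named list.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Default run configuration
#'
#' @return Named list with `global_seed`, `simulation`, `model`, and
#'   `evaluation` blocks, matching the package defaults.
#' @export
default_config <- function() {
  list(
    global_seed = 1,
    simulation = list(
      shape = "scaled_hanning", ref_duration = 0.5, sfreq = 50,
      base_amplitude = 1, dist = "halfnormal", n_events = 500,
      block_size = 25, inter_block_interval = 5,
      duration_effect = TRUE, overlap = TRUE,
      noise = list(kind = "ar1", amplitude = 0.4, ar_coefficient = 0.9),
      filter_cutoff = 0.5),
    model = list(formula = "y ~ 1 + spl(dur, 5)", tmin = -0.1, tmax = NULL,
                 overlap_correction = TRUE),
    evaluation = list(grid = "quantiles:15", repetitions = 50))
}

#' Assemble package objects from a run configuration
#'
#' `config_kernel()` builds the [kernel_spec()], `config_noise()` the
#' [noise_spec()], and `config_simulate()` runs [simulate_study()] as
#' described by a configuration list (see [default_config()]).
#'
#' @param config Configuration list.
#' @return A kernel spec, noise spec, or simulation result respectively.
#' @export
config_kernel <- function(config) {
  s <- config$simulation
  kernel_spec(s$shape, ref_duration = s$ref_duration, sfreq = s$sfreq,
              base_amplitude = s$base_amplitude)
}

#' @rdname config_kernel
#' @export
config_noise <- function(config) {
  n <- config$simulation$noise
  noise_spec(n$kind, amplitude = n$amplitude,
             ar_coefficient = n$ar_coefficient %||% 0.9)
}

#' @rdname config_kernel
#' @param seed Optional seed overriding `config$global_seed`.
#' @export
config_simulate <- function(config, seed = NULL) {
  s <- config$simulation
  simulate_study(config_kernel(config), dist = s$dist, n_events = s$n_events,
                 block_size = s$block_size,
                 inter_block_interval = s$inter_block_interval,
                 duration_effect = s$duration_effect, overlap = s$overlap,
                 noise = config_noise(config),
                 filter_cutoff = s$filter_cutoff,
                 seed = seed %||% config$global_seed)
}
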