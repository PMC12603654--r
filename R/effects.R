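#' Marginal-effect time courses over a duration grid
#'
#' Evaluates the fitted linear predictor over a grid of durations while
#' holding all other covariates fixed: numeric covariates at their observed
#' means (or user-supplied values), categorical covariates at their
#' reference level. For each grid duration this yields one predicted
#' response time course per channel.
#'
#' @param fit A `durerp_fit` from [fit_model()].
#' @param grid Numeric vector of durations, or `"quantiles:k"` which expands
#'   to the `k` interior quantiles (probabilities `1/(k+1) .. k/(k+1)`) of
#'   the fitted durations. Default `"quantiles:15"`. Grid values outside the
#'   fitted range are clamped to it (with a warning from the encoder).
#' @param held `"means"` or a named list of covariate values to hold fixed.
#' @param event_type Which trial_type to evaluate (default: the first one).
#' @param duration_cov Name of the duration covariate (default `"dur"`,
#'   which also matches the event table's `duration` column).
#' @return Object of class `durerp_effects`: list with `durations`,
#'   `lag_sec`, `curves` (array duration x lag x channel), `held`, `sfreq`.
#' @export
marginal_effects <- function(fit, grid = "quantiles:15", held = "means",
                             event_type = NULL, duration_cov = "dur") {
  stopifnot(inherits(fit, "durerp_fit"))
  event_type <- event_type %||% fit$column_meta$event_type[1]
  pinfo <- fit$predictors[[event_type]]
  if (is.null(pinfo)) rlang::abort(sprintf("no fitted terms for event type `%s`", event_type))
  pred <- pinfo$predictors
  w <- pinfo$window

  is_dur_term <- vapply(pred$encoders, function(e) {
    e$term$encoding != "intercept" &&
      e$term$covariate %in% c(duration_cov, "dur", "duration")
  }, logical(1))
  dur_values <- NULL
  if (any(is_dur_term)) dur_values <- pred$encoders[[which(is_dur_term)[1]]]$values

  if (is.character(grid) && grepl("^quantiles:", grid)) {
    k <- as.integer(sub("^quantiles:", "", grid))
    if (is.null(dur_values)) {
      rlang::abort("quantile grid requested but the model has no duration term")
    }
    grid <- unname(stats::quantile(dur_values, probs = seq_len(k) / (k + 1)))
  }
  grid <- as.numeric(grid)
  if (length(grid) < 1) rlang::abort("empty duration grid")

  # one design row per grid duration
  rows <- lapply(seq_along(pred$encoders), function(i) {
    e <- pred$encoders[[i]]
    tm <- e$term
    if (tm$encoding == "intercept") {
      matrix(1, length(grid), 1)
    } else if (is_dur_term[i]) {
      e$encode(grid)
    } else {
      held_val <- if (is.list(held) && !is.null(held[[tm$covariate]])) {
        held[[tm$covariate]]
      } else if (is.numeric(e$values)) {
        mean(e$values)
      } else {
        NA # categorical reference level -> all-zero indicators
      }
      if (is.na(held_val[1]) && !is.numeric(e$values)) {
        matrix(0, length(grid), length(e$names))
      } else {
        m <- e$encode(rep(held_val, length.out = 1))
        matrix(rep(m, each = length(grid)), nrow = length(grid))
      }
    }
  })
  V <- do.call(cbind, rows)              # n_grid x p

  idx <- which(fit$column_meta$event_type == event_type)
  L <- w$n_lags
  nch <- nrow(fit$coefficients)
  curves <- array(0, dim = c(length(grid), L, nch))
  for (ch in seq_len(nch)) {
    B <- matrix(fit$coefficients[ch, idx], nrow = L)  # L x p (term-major cols)
    curves[, , ch] <- V %*% t(B)
  }
  structure(list(durations = grid,
                 lag_sec = (w$tmin_samples + 0:(L - 1)) / fit$sfreq,
                 curves = curves,
                 held = if (is.list(held)) held else list(),
                 sfreq = fit$sfreq, window = w,
                 model_tag = fit$model_tag, event_type = event_type),
            class = "durerp_effects")
}

#' @export
print.durerp_effects <- function(x, ...) {
  cat(sprintf("<durerp_effects> %d duration(s) x %d lag(s) x %d channel(s) [%s]\n",
              dim(x$curves)[1], dim(x$curves)[2], dim(x$curves)[3], x$model_tag))
  invisible(x)
}

#' Tidy marginal effects into a long table
#'
#' @param x A `durerp_effects`.
#' @param ... Unused.
#' @return Tibble with channel, lag_seconds, duration, prediction.
#' @export
tidy.durerp_effects <- function(x, ...) {
  d <- dim(x$curves)
  tidyr::expand_grid(channel = seq_len(d[3]),
                     duration = x$durations,
                     lag_seconds = x$lag_sec) |>
    dplyr::arrange(.data$channel, .data$duration, .data$lag_seconds) |>
    dplyr::mutate(prediction = as.vector(aperm(x$curves, c(2, 1, 3))))
}

#' Maximal marginal effect per channel and lag
#'
#' The maximum over all pairs of grid durations of the absolute difference
#' between their predicted curves — for scalar predictions per (channel,
#' lag) this is the range (max minus min) across the duration grid. The
#' quantity is nonnegative by construction and invariant to adding a
#' lag-wise constant to all curves.
#'
#' @param effects A `durerp_effects` with at least 2 grid durations.
#' @return Tibble with channel, lag_seconds, max_effect.
#' @export
max_marginal_effect <- function(effects) {
  stopifnot(inherits(effects, "durerp_effects"), length(effects$durations) >= 2)
  d <- dim(effects$curves)
  out <- lapply(seq_len(d[3]), function(ch) {
    m <- effects$curves[, , ch, drop = FALSE][, , 1]
    tibble::tibble(channel = ch, lag_seconds = effects$lag_sec,
                   max_effect = apply(m, 2, max) - apply(m, 2, min))
  })
  dplyr::bind_rows(out)
}

#' Plot marginal-effect curves
#'
#' @param object A `durerp_effects`.
#' @param channel Channel to plot. Default 1.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.durerp_effects <- function(object, channel = 1, ...) {
  df <- dplyr::filter(tidy(object), .data$channel == !!channel)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_seconds, y = .data$prediction,
                                   group = .data$duration,
                                   colour = .data$duration)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(name = "duration (s)") +
    ggplot2::labs(x = "time relative to event onset (s)", y = "predicted response",
                  title = object$model_tag) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
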