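#' Term specification for a duration / covariate encoding
#'
#' @param covariate Covariate name (`"dur"` refers to the event duration
#'   column) or `"intercept"`.
#' @param encoding One of `"intercept"`, `"linear"`, `"categorical"`,
#'   `"bspline"`.
#' @param n_bins Number of equal-count bins for `"categorical"` (>= 2).
#' @param df Number of B-spline basis functions for `"bspline"` (>= 3).
#' @return Object of class `durerp_term_spec`.
#' @export
term_spec <- function(covariate, encoding = c("linear", "intercept",
                                              "categorical", "bspline"),
                      n_bins = 10, df = 5) {
  encoding <- match.arg(encoding)
  if (encoding == "categorical") stopifnot(n_bins >= 2)
  if (encoding == "bspline") stopifnot(df >= 3)
  structure(list(covariate = covariate, encoding = encoding,
                 n_bins = n_bins, df = df),
            class = "durerp_term_spec")
}

term_label <- function(term) {
  switch(term$encoding,
    intercept = "(Intercept)",
    linear = term$covariate,
    categorical = sprintf("bin(%s,%d)", term$covariate, term$n_bins),
    bspline = sprintf("spl(%s,%d)", term$covariate, term$df))
}

#' Parse a Wilkinson-style formula into term specifications
#'
#' Accepts the dialect used throughout the package:
#' `y ~ 1`, `y ~ 1 + dur`, `y ~ 1 + bin(dur, 10)`, `y ~ 1 + spl(dur, 5)`,
#' and sums thereof (e.g. `y ~ 1 + spl(dur, 4) + condition`). Bare names are
#' linear terms (categorical covariates are expanded at encoding time).
#'
#' @param formula Formula string or `formula` object.
#' @return List of [term_spec()] objects (intercept always first).
#' @export
parse_formula <- function(formula) {
  f <- if (inherits(formula, "formula")) {
    paste(deparse(formula[[3]]), collapse = " ")
  } else {
    sub("^[^~]*~", "", as.character(formula))
  }
  parts <- trimws(strsplit(f, "+", fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  terms <- list(term_spec("intercept", "intercept"))
  for (p in setdiff(parts, "1")) {
    m_bin <- regmatches(p, regexec("^bin\\(\\s*([^,)]+)\\s*(?:,\\s*(\\d+)\\s*)?\\)$", p))[[1]]
    m_spl <- regmatches(p, regexec("^spl(?:ine)?\\(\\s*([^,)]+)\\s*,\\s*(\\d+)\\s*\\)$", p))[[1]]
    if (length(m_bin)) {
      nb <- if (m_bin[3] == "") 10L else as.integer(m_bin[3])
      terms <- c(terms, list(term_spec(m_bin[2], "categorical", n_bins = nb)))
    } else if (length(m_spl)) {
      terms <- c(terms, list(term_spec(m_spl[2], "bspline", df = as.integer(m_spl[3]))))
    } else if (grepl("^[A-Za-z._][A-Za-z0-9._]*$", p)) {
      terms <- c(terms, list(term_spec(p, "linear")))
    } else {
      rlang::abort(sprintf("cannot parse formula term `%s`", p))
    }
  }
  terms
}

#' Full B-spline basis on quantile breakpoints
#'
#' Cubic B-spline basis whose `n_breakpoints` breakpoints sit at evenly
#' spaced quantiles of `x` (boundary breakpoints at the observed range, the
#' remaining `n_breakpoints - 2` in the interior). The complete
#' (intercept-including) basis has `n_breakpoints + 2` functions and its
#' rows sum to one inside the knot span (partition of unity). A term
#' `spl(x, 5)` therefore spans 5 quantile segments of the covariate, which
#' keeps the effective flexibility comparable between, say, 5 and 10
#' "splines" and the much stiffer single-interior-knot basis that
#' `splines::bs(df = 5)` would give.
#'
#' @param x Covariate values.
#' @param n_breakpoints Number of quantile breakpoints (>= 3).
#' @return A `bs` basis matrix with `n_breakpoints + 2` columns (fewer if
#'   duplicate quantiles collapse).
#' @export
bspline_basis <- function(x, n_breakpoints) {
  br <- unique(stats::quantile(x, seq(0, 1, length.out = n_breakpoints),
                               names = FALSE))
  splines::bs(x, knots = br[-c(1, length(br))], intercept = TRUE)
}

#' Encode a covariate into design columns
#'
#' * `linear` — one column of raw values.
#' * `categorical` — `n_bins` equal-count (quantile) bins, treatment-coded
#'   against the lowest bin, so `n_bins - 1` indicator columns and the
#'   intercept carries the reference bin. Ties are broken by rank.
#' * `bspline` — cubic B-spline basis on `df` quantile breakpoints (see
#'   [bspline_basis()]); the first basis column is dropped (absorbed into
#'   the intercept) for identifiability, leaving `df + 1` columns.
#'
#' Non-numeric (factor/character) covariates with a `linear` term are
#' treatment-coded against their first level.
#'
#' @param term A [term_spec()].
#' @param values Covariate values observed at the events.
#' @return List with `cols` (matrix), `names` (column labels), and
#'   `encode` (function mapping new covariate values to the same columns;
#'   values outside the observed range are clamped with a warning).
#' @export
encode_duration <- function(term, values) {
  stopifnot(inherits(term, "durerp_term_spec"), length(values) > 0)
  lbl <- term_label(term)
  switch(term$encoding,
    intercept = {
      enc <- function(v) matrix(1, nrow = length(v), ncol = 1)
      list(cols = enc(values), names = lbl, encode = enc)
    },
    linear = {
      if (!is.numeric(values)) {
        lev <- levels(as.factor(values))
        enc <- function(v) {
          fv <- factor(v, levels = lev)
          m <- stats::model.matrix(~fv)[, -1, drop = FALSE]
          colnames(m) <- paste0(term$covariate, ":", lev[-1])
          m
        }
        m <- enc(values)
        list(cols = m, names = colnames(m), encode = enc)
      } else {
        enc <- function(v) matrix(as.numeric(v), ncol = 1)
        list(cols = enc(values), names = lbl, encode = enc)
      }
    },
    categorical = {
      nb <- term$n_bins
      if (length(unique(values)) < nb) {
        rlang::abort(sprintf(
          "covariate `%s` has too few distinct values (%d) for %d equal-count bins",
          term$covariate, length(unique(values)), nb))
      }
      rk <- rank(values, ties.method = "first")
      bin <- ceiling(rk * nb / length(values))
      # interior cut points midway between adjacent bins, for new values
      srt <- sort(values)
      sizes <- tabulate(bin, nb)
      hi <- cumsum(sizes)
      breaks <- (srt[hi[-nb]] + srt[hi[-nb] + 1]) / 2
      enc_from_bin <- function(b, n) {
        m <- matrix(0, nrow = n, ncol = nb - 1)
        for (j in 2:nb) m[b == j, j - 1] <- 1
        colnames(m) <- paste0(lbl, ".", 2:nb)
        m
      }
      enc <- function(v) enc_from_bin(findInterval(v, breaks) + 1L, length(v))
      list(cols = enc_from_bin(bin, length(values)),
           names = paste0(lbl, ".", 2:nb), encode = enc,
           breaks = breaks)
    },
    bspline = {
      if (!is.numeric(values)) rlang::abort(sprintf(
        "spline term requires a numeric covariate (`%s` is not)", term$covariate))
      basis <- bspline_basis(values, term$df)
      rng <- range(values)
      enc <- function(v) {
        if (any(v < rng[1] | v > rng[2])) {
          rlang::warn(sprintf(
            "%d value(s) outside the fitted range of `%s` clamped to the knot span",
            sum(v < rng[1] | v > rng[2]), term$covariate))
          v <- pmin(pmax(v, rng[1]), rng[2])
        }
        unclass(stats::predict(basis, v))[, -1, drop = FALSE]
      }
      nms <- paste0(lbl, ".", seq_len(ncol(basis) - 1) + 1)
      list(cols = unclass(basis)[, -1, drop = FALSE], names = nms, encode = enc)
    })
}

#' Winsorize a numeric vector at empirical percentiles
#'
#' Values below the `lower_pct` percentile are set to that percentile and
#' values above the `upper_pct` percentile to that percentile; everything in
#' between is untouched. Used to tame long reaction-time tails before
#' entering them as model covariates.
#'
#' @param values Numeric vector.
#' @param lower_pct,upper_pct Percentiles in \[0, 100\], `lower < upper`.
#'   Defaults 5 and 95 (a "90% winsorization").
#' @return Clipped numeric vector of the same length.
#' @export
winsorize <- function(values, lower_pct = 5, upper_pct = 95) {
  stopifnot(lower_pct >= 0, upper_pct <= 100, lower_pct < upper_pct)
  q <- stats::quantile(values, c(lower_pct, upper_pct) / 100, names = FALSE)
  pmin(pmax(values, q[1]), q[2])
}

#' Analysis window / FIR basis specification
#'
#' Half-open lag window `[tmin, tmax)` relative to event onset, discretized
#' at `sfreq`: `n_lags = round((tmax - tmin) * sfreq)` one-sample FIR lags.
#'
#' @param tmin,tmax Window bounds in seconds (`tmin < tmax`).
#' @param sfreq Sampling frequency in Hz.
#' @return Object of class `durerp_basis_spec` with fields `tmin`, `tmax`,
#'   `sfreq`, `n_lags`, `tmin_samples`.
#' @export
basis_spec <- function(tmin, tmax, sfreq) {
  stopifnot(tmin < tmax, sfreq > 0)
  n_lags <- as.integer(round((tmax - tmin) * sfreq))
  stopifnot(n_lags >= 1)
  structure(list(tmin = tmin, tmax = tmax, sfreq = sfreq, n_lags = n_lags,
                 tmin_samples = as.integer(round(tmin * sfreq))),
            class = "durerp_basis_spec")
}

# covariate values for a term, resolving the `dur` alias
term_values <- function(term, events) {
  if (term$encoding == "intercept") return(rep(1, nrow(events)))
  cov <- term$covariate
  if (cov %in% names(events)) return(events[[cov]])
  if (cov == "dur" && "duration" %in% names(events)) return(events$duration)
  rlang::abort(sprintf("covariate `%s` not found in the event table", cov))
}

# per-event-type predictor block: dense n_events x p matrix + encoders + names
build_predictors <- function(events, terms) {
  enc <- lapply(terms, function(tm) {
    v <- term_values(tm, events)
    out <- encode_duration(tm, v)
    out$values <- v
    out$term <- tm
    out
  })
  cols <- do.call(cbind, lapply(enc, `[[`, "cols"))
  nms <- unlist(lapply(enc, `[[`, "names"))
  term_of_col <- rep(vapply(terms, term_label, character(1)),
                     vapply(enc, function(e) length(e$names), integer(1)))
  basis_index <- unlist(lapply(enc, function(e) seq_along(e$names)))
  list(X = cols, names = nms, encoders = enc, terms = terms,
       term_of_col = term_of_col, basis_index = basis_index)
}

#' Build an epoch-stacked (mass-univariate) design
#'
#' One regression per epoch time point: the design has one row per event and
#' one column per predictor; the returned extractor cuts signal epochs
#' `[onset + tmin, onset + tmax)` per event. Events whose epochs would extend
#' beyond the signal are dropped (their count is reported in `n_dropped`).
#'
#' @param events Event table.
#' @param terms List of [term_spec()] (or a formula string for
#'   [parse_formula()]).
#' @param window A [basis_spec()].
#' @param sig Optional [signal()]; when given, epochs are extracted
#'   immediately and boundary events dropped consistently.
#' @return List with `X` (n_events x p design), `column_meta`,
#'   `extract_epochs(sig)`, `kept`, `n_dropped`, `predictors`.
#' @export
build_epoch_design <- function(events, terms, window, sig = NULL) {
  if (is.character(terms) || inherits(terms, "formula")) terms <- parse_formula(terms)
  stopifnot(inherits(window, "durerp_basis_spec"))
  pred <- build_predictors(events, terms)
  kept <- rep(TRUE, nrow(events))
  if (!is.null(sig)) {
    s0 <- time_to_sample(sig, events$onset) + window$tmin_samples
    kept <- s0 >= 1 & (s0 + window$n_lags - 1) <= n_samples(sig)
  }
  n_dropped <- sum(!kept)
  if (n_dropped > 0) {
    rlang::inform(sprintf("dropped %d event(s) with epochs outside the signal", n_dropped))
  }
  extract_epochs <- function(sig, channel = 1) {
    s0 <- time_to_sample(sig, events$onset) + window$tmin_samples
    ok <- which(s0 >= 1 & (s0 + window$n_lags - 1) <= n_samples(sig))
    t(vapply(ok, function(i) sig$data[channel, s0[i]:(s0[i] + window$n_lags - 1)],
             numeric(window$n_lags)))
  }
  meta <- tibble::tibble(
    event_type = events$trial_type[1],
    term = pred$term_of_col,
    basis_index = pred$basis_index,
    name = pred$names)
  list(X = pred$X[kept, , drop = FALSE], column_meta = meta,
       extract_epochs = extract_epochs, kept = which(kept),
       n_dropped = n_dropped, predictors = pred, window = window)
}

#' FIR time-expanded (deconvolution) design matrix
#'
#' For every event, every predictor column value `v`, and every lag `l` in
#' the window, `v` is added at continuous-signal row
#' `onset_sample + tmin_samples + l`. Columns of different event types are
#' concatenated horizontally; rows outside `[1, n_samples]` are truncated
#' (never wrapped) and their count reported.
#'
#' @param events Event table (may contain several `trial_type`s).
#' @param spec_per_type Named list mapping trial_type to
#'   `list(terms = <formula or term list>, window = basis_spec)`; a single
#'   unnamed spec is applied to every type present.
#' @param sfreq Sampling frequency in Hz.
#' @param n_samples Number of continuous samples (design rows).
#' @param t0 Time of the first sample (seconds), as in [signal()].
#' @return List with `X` (sparse `dgCMatrix`), `column_meta` (one row per
#'   column: event_type, term, basis_index, lag, lag_sec), `predictors` (per
#'   type), `n_truncated`.
#' @export
time_expand_fir <- function(events, spec_per_type, sfreq, n_samples, t0 = 0) {
  types <- unique(events$trial_type)
  if (!is.null(spec_per_type$terms)) {
    spec_per_type <- stats::setNames(rep(list(spec_per_type), length(types)), types)
  }
  missing_types <- setdiff(types, names(spec_per_type))
  if (length(missing_types)) {
    rlang::abort(sprintf("no model specification for trial_type(s): %s",
                         paste(missing_types, collapse = ", ")))
  }
  ii <- list(); jj <- list(); xx <- list()
  meta <- list(); preds <- list()
  offset <- 0L
  n_trunc <- 0L
  for (ty in types) {
    sp <- spec_per_type[[ty]]
    terms <- if (is.character(sp$terms) || inherits(sp$terms, "formula")) {
      parse_formula(sp$terms)
    } else sp$terms
    w <- sp$window
    stopifnot(inherits(w, "durerp_basis_spec"))
    ev <- events[events$trial_type == ty, , drop = FALSE]
    pred <- build_predictors(ev, terms)
    preds[[ty]] <- list(predictors = pred, window = w)
    p <- ncol(pred$X)
    L <- w$n_lags
    s0 <- as.integer(round(ev$onset * sfreq)) - as.integer(round(t0 * sfreq)) +
      1L + w$tmin_samples
    # triplets: event e, predictor col j, lag l
    n_ev <- nrow(ev)
    rows <- rep(s0, times = L) + rep(0:(L - 1L), each = n_ev)  # n_ev*L
    for (j in seq_len(p)) {
      v <- pred$X[, j]
      keep <- rows >= 1L & rows <= n_samples & rep(v != 0, times = L)
      n_trunc <- n_trunc + sum((rows < 1L | rows > n_samples) & rep(v != 0, times = L))
      ii[[length(ii) + 1L]] <- rows[keep]
      jj[[length(jj) + 1L]] <- offset + (j - 1L) * L + rep(0:(L - 1L), each = n_ev)[keep] + 1L
      xx[[length(xx) + 1L]] <- rep(v, times = L)[keep]
    }
    meta[[ty]] <- tibble::tibble(
      event_type = ty,
      term = rep(pred$term_of_col, each = L),
      basis_index = rep(pred$basis_index, each = L),
      name = rep(pred$names, each = L),
      lag = rep(0:(L - 1L), times = p),
      lag_sec = (w$tmin_samples + rep(0:(L - 1L), times = p)) / sfreq)
    offset <- offset + p * L
  }
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_samples, offset))
  if (n_trunc > 0) {
    rlang::inform(sprintf("truncated %d design entr(ies) outside the signal", n_trunc))
  }
  list(X = X, column_meta = dplyr::bind_rows(meta), predictors = preds,
       n_truncated = n_trunc)
}
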