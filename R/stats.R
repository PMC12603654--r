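#' One-sample Hotelling T-squared test against the zero vector
#'
#' Tests whether the mean coefficient vector across subjects is zero —
#' applied per (channel-or-ROI, lag) cell to the spline coefficients of a
#' duration effect. With `n` subjects and `p` coefficients,
#' `T2 = n * xbar' S^-1 xbar`, `F = T2 (n - p) / (p (n - 1))` with
#' `(p, n - p)` degrees of freedom.
#'
#' @param data Numeric matrix, subjects x coefficients (`n > p`, no missing
#'   values), or a numeric vector for `p = 1` (then `T2` equals the squared
#'   one-sample t statistic).
#' @return Tibble with `T2`, `F`, `df1`, `df2`, `p_value`.
#' @export
hotelling_t2 <- function(data) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  stopifnot(is.numeric(data), !anyNA(data))
  n <- nrow(data); p <- ncol(data)
  if (n <= p) rlang::abort(sprintf(
    "Hotelling T2 needs more subjects (%d) than coefficients (%d)", n, p))
  xbar <- colMeans(data)
  if (all(xbar == 0)) {
    return(tibble::tibble(T2 = 0, F = 0, df1 = p, df2 = n - p, p_value = 1))
  }
  S <- stats::cov(data)
  Sinv <- tryCatch(solve(S), error = function(e) rlang::abort(sprintf(
    "singular covariance in Hotelling T2 cell (n=%d, p=%d)", n, p)))
  T2 <- drop(n * t(xbar) %*% Sinv %*% xbar)
  Fstat <- T2 * (n - p) / (p * (n - 1))
  tibble::tibble(T2 = T2, F = Fstat, df1 = p, df2 = n - p,
                 p_value = stats::pf(Fstat, p, n - p, lower.tail = FALSE))
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence,
#' using the harmonic-sum correction constant `c(m) = sum_{i<=m} 1/i`
#' (so BY-adjusted values are never smaller than Benjamini-Hochberg ones).
#' Computed via [stats::p.adjust()].
#'
#' @param pvalues Raw p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1.
#' @export
by_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BY")
}

#' Group test of spline coefficients across subjects
#'
#' Runs [hotelling_t2()] in every (event_type, term, lag) cell of a stack of
#' per-subject tidy coefficient tables and applies [by_fdr()] across all
#' cells. Intended for the coefficients of a spline duration term: the test
#' is performed on the coefficients themselves, not on the marginal-effect
#' values used for display.
#'
#' @param coef_tables List of per-subject tidy coefficient tibbles (as from
#'   `tidy(fit)`), all with identical (event_type, term, basis_index,
#'   lag_seconds) layouts.
#' @param term Term label to test (e.g. `"spl(dur,5)"`).
#' @param channel Channel to test. Default 1.
#' @return Tibble with one row per lag: `lag_seconds`, `T2`, `F`, `p_raw`,
#'   `p_fdr`.
#' @export
group_spline_test <- function(coef_tables, term, channel = 1) {
  cells <- lapply(coef_tables, function(tb) {
    dplyr::filter(tb, .data$term == !!term, .data$channel == !!channel) |>
      dplyr::arrange(.data$lag_seconds, .data$basis_index)
  })
  lags <- unique(cells[[1]]$lag_seconds)
  res <- purrr::map_dfr(lags, function(lg) {
    M <- do.call(rbind, lapply(cells, function(tb) {
      tb$estimate[tb$lag_seconds == lg]
    }))
    ht <- hotelling_t2(M)
    tibble::tibble(lag_seconds = lg, T2 = ht$T2, F = ht$F, p_raw = ht$p_value)
  })
  res$p_fdr <- by_fdr(res$p_raw)
  res
}

#' One-sample t-tests on maximal-marginal-effect differences
#'
#' Display companion to [group_spline_test()]: tests, per lag, whether the
#' subject-wise difference in maximal marginal effect (e.g. with minus
#' without overlap correction) is zero, with BY-FDR correction across lags.
#'
#' @param diffs Numeric matrix, subjects x lags, of per-subject differences.
#' @param lag_seconds Optional lag labels (length = ncol).
#' @return Tibble with `lag_seconds`, `t`, `p_raw`, `p_fdr`.
#' @export
max_effect_ttest <- function(diffs, lag_seconds = NULL) {
  stopifnot(is.matrix(diffs), nrow(diffs) >= 2)
  lag_seconds <- lag_seconds %||% seq_len(ncol(diffs))
  res <- purrr::map_dfr(seq_len(ncol(diffs)), function(j) {
    tt <- stats::t.test(diffs[, j])
    tibble::tibble(lag_seconds = lag_seconds[j],
                   t = unname(tt$statistic), p_raw = tt$p.value)
  })
  res$p_fdr <- by_fdr(res$p_raw)
  res
}
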