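#' Solve a (possibly sparse) least-squares system
#'
#' Normal-equations solve with a dense Cholesky factorization; on
#' rank-deficient systems falls back to the SVD minimum-norm solution and
#' records the numerical rank. All-zero design columns are detected first,
#' reported with a warning, and their coefficients forced to zero.
#'
#' @param X Design matrix (base matrix or `Matrix` sparse matrix), n x p.
#' @param Y Response: numeric vector (length n) or matrix (n x m) for
#'   multiple simultaneous responses (channels or epoch time points).
#' @return List with `coefficients` (p x m matrix), `rank`, `rss`
#'   (residual sum of squares per response).
#' @export
solve_least_squares <- function(X, Y) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= ncol(X))
  p <- ncol(X)
  csums <- if (inherits(X, "Matrix")) Matrix::colSums(X^2) else colSums(X^2)
  zero_cols <- which(csums == 0)
  active <- setdiff(seq_len(p), zero_cols)
  if (length(zero_cols)) {
    rlang::warn(sprintf("%d all-zero design column(s); coefficients forced to 0",
                        length(zero_cols)))
  }
  Xa <- X[, active, drop = FALSE]
  XtX <- as.matrix(Matrix::crossprod(Xa))
  XtY <- as.matrix(Matrix::crossprod(Xa, Y))
  sol <- tryCatch({
    R <- chol(XtX)
    list(beta = backsolve(R, forwardsolve(t(R), XtY)), rank = length(active))
  }, error = function(e) NULL)
  if (is.null(sol)) {
    # rank-deficient: minimum-norm solution via eigen decomposition of X'X
    eg <- eigen(XtX, symmetric = TRUE)
    tol <- max(nrow(X), p) * .Machine$double.eps * max(eg$values, 0)
    pos <- eg$values > tol
    beta <- eg$vectors[, pos, drop = FALSE] %*%
      ((t(eg$vectors[, pos, drop = FALSE]) %*% XtY) / eg$values[pos])
    sol <- list(beta = beta, rank = sum(pos))
  }
  beta <- matrix(0, nrow = p, ncol = ncol(Y))
  beta[active, ] <- sol$beta
  fitted <- as.matrix(X %*% beta)
  rss <- colSums((as.matrix(Y) - fitted)^2)
  list(coefficients = beta, rank = sol$rank, rss = rss)
}

new_fit_result <- function(coefficients, column_meta, model_tag, mode,
                           predictors, diagnostics, sfreq) {
  structure(list(coefficients = coefficients, column_meta = column_meta,
                 model_tag = model_tag, mode = mode, predictors = predictors,
                 diagnostics = diagnostics, sfreq = sfreq),
            class = "durerp_fit")
}

#' @export
print.durerp_fit <- function(x, ...) {
  cat(sprintf("<durerp_fit> %s (%s): %d channel(s) x %d coefficient(s); rank %s\n",
              x$model_tag, x$mode, nrow(x$coefficients), ncol(x$coefficients),
              paste(x$diagnostics$rank, collapse = "/")))
  invisible(x)
}

#' Fit a regression-ERP model to a continuous signal
#'
#' The same model formula can be estimated two ways:
#'
#' * `overlap_correction = TRUE` — the design is FIR time-expanded over the
#'   continuous signal ([time_expand_fir()]) and solved as one least-squares
#'   problem per channel; temporally adjacent responses are deconvolved.
#' * `overlap_correction = FALSE` — classical mass-univariate estimation:
#'   epochs are cut around each event and an independent regression is
#'   solved at every epoch time point ([build_epoch_design()]).
#'
#' Either way the result is indexable by `(event_type, term, basis, lag)`,
#' so downstream marginal-effect and evaluation code is mode-agnostic.
#'
#' @param sig A [signal()].
#' @param events Event table (tibble with `onset`, `duration`, `trial_type`).
#' @param formulas Formula string (applied to every trial_type), or a named
#'   list mapping trial_type to a formula / list of [term_spec()].
#' @param window A [basis_spec()], or named list per trial_type.
#' @param overlap_correction Logical; see above.
#' @param model_tag Optional label stored in the result.
#' @return A `durerp_fit` object.
#' @export
fit_model <- function(sig, events, formulas, window, overlap_correction = TRUE,
                      model_tag = NULL) {
  stopifnot(inherits(sig, "durerp_signal"))
  types <- unique(events$trial_type)
  spec_per_type <- normalize_model_spec(formulas, window, types)
  tag <- model_tag %||% paste0(
    paste(vapply(spec_per_type, function(s) {
      if (is.character(s$terms)) s$terms else "custom"
    }, character(1)), collapse = "; "),
    if (overlap_correction) " [deconv]" else " [mass-univariate]")

  if (overlap_correction) {
    de <- time_expand_fir(events, spec_per_type, sfreq = sig$sfreq,
                          n_samples = n_samples(sig), t0 = sig$t0)
    nch <- nrow(sig$data)
    coefs <- matrix(0, nrow = nch, ncol = ncol(de$X))
    ranks <- integer(nch); rss <- numeric(nch)
    for (ch in seq_len(nch)) {
      ls <- solve_least_squares(de$X, sig$data[ch, ])
      coefs[ch, ] <- ls$coefficients[, 1]
      ranks[ch] <- ls$rank; rss[ch] <- ls$rss
    }
    new_fit_result(coefs, de$column_meta, tag, "deconvolution",
                   de$predictors,
                   list(rank = ranks, rss = rss, n_truncated = de$n_truncated,
                        n_dropped = 0L),
                   sig$sfreq)
  } else {
    metas <- list(); blocks <- list(); preds <- list()
    ranks <- integer(0); rss_all <- 0; dropped <- 0L
    nch <- nrow(sig$data)
    for (ty in types) {
      sp <- spec_per_type[[ty]]
      ev <- events[events$trial_type == ty, , drop = FALSE]
      ed <- build_epoch_design(ev, sp$terms, sp$window, sig = sig)
      w <- sp$window
      L <- w$n_lags
      p <- ncol(ed$X)
      preds[[ty]] <- list(predictors = ed$predictors, window = w)
      cf <- array(0, dim = c(nch, p * L))
      for (ch in seq_len(nch)) {
        E <- ed$extract_epochs(sig, channel = ch)   # n_kept x L
        ls <- solve_least_squares(ed$X, E)          # p x L
        # flatten term-major to match the deconvolution column ordering
        cf[ch, ] <- as.vector(t(ls$coefficients))
        ranks <- c(ranks, ls$rank); rss_all <- rss_all + sum(ls$rss)
      }
      metas[[ty]] <- tibble::tibble(
        event_type = ty,
        term = rep(ed$column_meta$term, each = L),
        basis_index = rep(ed$column_meta$basis_index, each = L),
        name = rep(ed$column_meta$name, each = L),
        lag = rep(0:(L - 1L), times = p),
        lag_sec = (w$tmin_samples + rep(0:(L - 1L), times = p)) / sig$sfreq)
      blocks[[ty]] <- cf
      dropped <- dropped + ed$n_dropped
    }
    new_fit_result(do.call(cbind, blocks), dplyr::bind_rows(metas), tag,
                   "mass_univariate", preds,
                   list(rank = ranks, rss = rss_all, n_truncated = 0L,
                        n_dropped = dropped),
                   sig$sfreq)
  }
}

normalize_model_spec <- function(formulas, window, types) {
  per_type_formula <- is.list(formulas) && !inherits(formulas, "durerp_term_spec") &&
    !is.null(names(formulas)) && all(names(formulas) != "")
  get_formula <- function(ty) if (per_type_formula) formulas[[ty]] else formulas
  get_window <- function(ty) {
    if (inherits(window, "durerp_basis_spec")) window else window[[ty]]
  }
  out <- lapply(types, function(ty) {
    f <- get_formula(ty)
    if (is.null(f)) rlang::abort(sprintf("no formula for trial_type `%s`", ty))
    list(terms = f, window = get_window(ty))
  })
  stats::setNames(out, types)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted rERP model into a long coefficient table
#'
#' @param x A `durerp_fit`.
#' @param ... Unused.
#' @return Tibble with columns channel, event_type, term, basis_index,
#'   lag_seconds, estimate.
#' @export
tidy.durerp_fit <- function(x, ...) {
  nch <- nrow(x$coefficients)
  purrr::map_dfr(seq_len(nch), function(ch) {
    tibble::tibble(channel = ch,
                   event_type = x$column_meta$event_type,
                   term = x$column_meta$term,
                   basis_index = x$column_meta$basis_index,
                   lag_seconds = x$column_meta$lag_sec,
                   estimate = x$coefficients[ch, ])
  })
}

#' One-row model summary
#'
#' @param x A `durerp_fit`.
#' @param ... Unused.
#' @return Tibble with model_tag, mode, n_channels, n_coefficients, rank,
#'   rss, n_truncated, n_dropped.
#' @export
glance.durerp_fit <- function(x, ...) {
  tibble::tibble(model_tag = x$model_tag, mode = x$mode,
                 n_channels = nrow(x$coefficients),
                 n_coefficients = ncol(x$coefficients),
                 rank = min(x$diagnostics$rank),
                 rss = sum(x$diagnostics$rss),
                 n_truncated = x$diagnostics$n_truncated,
                 n_dropped = x$diagnostics$n_dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
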