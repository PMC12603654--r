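test_that("least-squares solver matches a dense pseudoinverse oracle", {
  set.seed(10)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- rnorm(20)
  fit <- solve_least_squares(X, y)
  oracle <- solve(t(X) %*% X, t(X) %*% y) # dense normal equations
  expect_lt(max(abs(fit$coefficients - oracle)), 1e-8)
  expect_equal(fit$rank, 8)

  # sparse input, multiple responses
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  Y <- matrix(rnorm(40), 20, 2)
  fit2 <- solve_least_squares(Xs, Y)
  expect_lt(max(abs(fit2$coefficients - solve(t(X) %*% X, t(X) %*% Y))), 1e-8)

  # zero response -> zero coefficients; zero column -> warning + zero coef
  expect_equal(max(abs(solve_least_squares(X, numeric(20))$coefficients)), 0)
  Xz <- cbind(X, 0)
  expect_warning(fz <- solve_least_squares(Xz, y), "all-zero")
  expect_equal(fz$coefficients[9, 1], 0)
})

test_that("rank-deficient systems return the minimum-norm solution", {
  set.seed(11)
  A <- matrix(rnorm(30 * 3), 30, 3)
  X <- cbind(A, A[, 1] + A[, 2]) # rank 3, 4 columns
  y <- rnorm(30)
  fit <- solve_least_squares(X, y)
  expect_equal(fit$rank, 3)
  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  beta_mn <- sv$v[, pos] %*% ((t(sv$u[, pos]) %*% y) / sv$d[pos])
  expect_lt(max(abs(fit$coefficients - beta_mn)), 1e-8)
})

test_that("intercept-only mass-univariate fit equals the epoch average", {
  spec <- kernel_spec("hanning", sfreq = 100)
  ev <- manual_events(rep(0.5, 12), clearance = 1.5)
  sig <- render_continuous(ev, spec)
  sig <- add_noise(sig, noise_spec("white", amplitude = 0.3, seed = 9))
  w <- basis_spec(-0.1, 0.6, 100)
  fit <- fit_model(sig, ev, "y ~ 1", w, overlap_correction = FALSE)
  d <- build_epoch_design(ev, "y ~ 1", w, sig = sig)
  E <- d$extract_epochs(sig)
  expect_equal(unname(fit$coefficients[1, ]), unname(colMeans(E)),
               tolerance = 1e-10)
})

test_that("deconvolution recovers overlapping kernels of two event types", {
  sfreq <- 100
  specA <- kernel_spec("hanning", ref_duration = 0.5, sfreq = sfreq)
  specB <- kernel_spec("half_hanning", ref_duration = 0.4, sfreq = sfreq,
                       base_amplitude = 1.5)
  set.seed(21)
  onsA <- cumsum(runif(40, 0.5, 1.2))
  onsB <- onsA + runif(40, 0.1, 0.4) # heavy overlap with A responses
  evA <- tibble::tibble(onset = onsA, duration = 0.5, trial_type = "A")
  evB <- tibble::tibble(onset = onsB, duration = 0.4, trial_type = "B")
  sig <- render_multi(list(evA, evB), list(specA, specB), sfreq)
  events <- dplyr::arrange(dplyr::bind_rows(evA, evB), onset)

  wA <- basis_spec(0, 0.5, sfreq); wB <- basis_spec(0, 0.4, sfreq)
  fit <- fit_model(sig, events, "y ~ 1",
                   window = list(A = wA, B = wB), overlap_correction = TRUE)
  kA <- make_kernel(specA, 0.5); kB <- make_kernel(specB, 0.4)
  estA <- fit$coefficients[1, fit$column_meta$event_type == "A"]
  estB <- fit$coefficients[1, fit$column_meta$event_type == "B"]
  expect_lt(max(abs(estA - kA)), 1e-6)
  expect_lt(max(abs(estB - kB)), 1e-6)

  # without overlap correction the averages are contaminated
  fit0 <- fit_model(sig, events, "y ~ 1",
                    window = list(A = wA, B = wB), overlap_correction = FALSE)
  estA0 <- fit0$coefficients[1, fit0$column_meta$event_type == "A"]
  expect_gt(max(abs(estA0 - kA)), 0.05)
})

test_that("deconvolution and mass-univariate agree on non-overlapping data", {
  spec <- kernel_spec("scaled_hanning", sfreq = 50)
  set.seed(31)
  ev <- manual_events(runif(40, 0.3, 1.2), clearance = 2.5)
  sig <- render_continuous(ev, spec)
  w <- basis_spec(-0.1, 1.7, 50)
  f1 <- fit_model(sig, ev, "y ~ 1 + dur", w, overlap_correction = TRUE)
  f2 <- fit_model(sig, ev, "y ~ 1 + dur", w, overlap_correction = FALSE)
  expect_lt(max(abs(f1$coefficients - f2$coefficients)), 1e-8)
  expect_equal(f1$column_meta$term, f2$column_meta$term)
})

test_that("fits are invariant to event order and nested in residual SS", {
  ks <- kernel_spec("scaled_hanning", sfreq = 50)
  sim <- simulate_study(ks, n_events = 80, seed = 5,
                        noise = noise_spec("white", 0.2, seed = 6))
  w <- basis_spec(-0.1, max(sim$events$duration) + 0.5, 50)
  fit_a <- fit_model(sim$signal, sim$events, "y ~ 1 + spl(dur, 5)", w, TRUE)
  shuffled <- sim$events[sample(nrow(sim$events)), ]
  fit_b <- fit_model(sim$signal, shuffled, "y ~ 1 + spl(dur, 5)", w, TRUE)
  expect_equal(fit_a$coefficients, fit_b$coefficients, tolerance = 1e-8)

  # adding a duration term never increases the in-sample residual SS
  fit0 <- fit_model(sim$signal, sim$events, "y ~ 1", w, TRUE)
  expect_lte(sum(fit_a$diagnostics$rss), sum(fit0$diagnostics$rss) + 1e-8)
})

test_that("tidy and glance expose the documented tables", {
  ks <- kernel_spec("hanning", sfreq = 50)
  sim <- simulate_study(ks, n_events = 40, seed = 8)
  w <- basis_spec(-0.1, 0.9, 50)
  fit <- fit_model(sim$signal, sim$events, "y ~ 1 + dur", w, FALSE)
  tb <- tidy(fit)
  expect_named(tb, c("channel", "event_type", "term", "basis_index",
                     "lag_seconds", "estimate"))
  expect_equal(nrow(tb), ncol(fit$coefficients))
  g <- glance(fit)
  expect_equal(g$mode, "mass_univariate")
  expect_true(all(is.finite(fit$coefficients)))
})
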