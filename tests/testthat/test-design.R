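test_that("duration encodings produce the documented columns", {
  lin <- encode_duration(term_spec("dur", "linear"), c(1, 2, 3))
  expect_equal(unname(lin$cols[, 1]), c(1, 2, 3))

  vals <- seq(0.01, 1, length.out = 100)
  cat10 <- encode_duration(term_spec("dur", "categorical", n_bins = 10), vals)
  expect_equal(ncol(cat10$cols), 9) # treatment coding against the lowest bin
  counts <- c(sum(rowSums(cat10$cols) == 0), colSums(cat10$cols))
  expect_equal(unname(counts), rep(10, 10)) # equal-count bins
  expect_true(all(cat10$cols %in% c(0, 1)))

  spl <- encode_duration(term_spec("dur", "bspline", df = 5), vals)
  # 5 breakpoints -> 7 basis functions, first absorbed by the intercept
  expect_equal(ncol(spl$cols), 6)
  expect_true(all(spl$cols >= 0 & spl$cols <= 1))

  expect_error(encode_duration(term_spec("x", "categorical", n_bins = 10),
                               rep(1:3, 10)), "x")
})

test_that("the full B-spline basis is a partition of unity", {
  set.seed(1)
  for (df in c(4, 5, 10)) {
    x <- abs(rnorm(200))
    basis <- bspline_basis(x, df)
    expect_true(all(abs(rowSums(basis) - 1) < 1e-10))
    # also at off-sample points inside the span
    newx <- seq(min(x) + 1e-6, max(x) - 1e-6, length.out = 57)
    expect_true(all(abs(rowSums(predict(basis, newx)) - 1) < 1e-10))
  }
})

test_that("winsorize clips exactly at the empirical percentiles", {
  x <- as.numeric(1:100)
  w <- winsorize(x, 5, 95)
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  expect_equal(min(w), q[1])
  expect_equal(max(w), q[2])
  inside <- x > q[1] & x < q[2]
  expect_equal(w[inside], x[inside]) # untouched values preserved in order
  expect_equal(winsorize(x, 0, 100), x) # degenerate bounds are the identity
})

test_that("formula parsing covers the Wilkinson dialect", {
  tms <- parse_formula("y ~ 1 + spl(dur, 5) + condition + bin(rt, 4)")
  labs <- vapply(tms, durerp:::term_label, character(1))
  expect_equal(labs, c("(Intercept)", "spl(dur,5)", "condition", "bin(rt,4)"))
  expect_equal(length(parse_formula("y ~ 1")), 1)
  expect_error(parse_formula("y ~ 1 + 2*x"), "parse")
})

test_that("epoch designs have one row per event and the stated shape", {
  ev <- manual_events(rep(c(0.4, 0.6), 10), clearance = 2)
  w <- basis_spec(-0.1, 1, 100)
  d <- build_epoch_design(ev, "y ~ 1 + dur", w)
  expect_equal(dim(d$X), c(20, 2))
  expect_equal(d$column_meta$term, c("(Intercept)", "dur"))

  # events whose epochs leave the signal are dropped, with the right count
  spec <- kernel_spec("hanning", sfreq = 100)
  sig <- render_continuous(ev, spec, total_padding = 0.2)
  t_end <- sig$t0 + ncol(sig$data) / 100
  expect_drop <- sum(ev$onset + 1 > t_end + 1e-9)
  d2 <- suppressMessages(build_epoch_design(ev, "y ~ 1", w, sig = sig))
  expect_equal(d2$n_dropped, expect_drop)
  expect_gt(expect_drop, 0)
})

test_that("FIR time expansion places values at the documented rows", {
  # one event, intercept-only, window [0, L): a shifted identity block
  ev <- tibble::tibble(onset = 1, duration = 0.5, trial_type = "event")
  w <- basis_spec(0, 0.1, 100) # 10 lags
  de <- time_expand_fir(ev, list(terms = "y ~ 1", window = w),
                        sfreq = 100, n_samples = 300, t0 = 0)
  expect_equal(Matrix::nnzero(de$X), 10)
  for (l in 0:9) expect_equal(de$X[101 + l, l + 1], 1)

  # E events, no truncation, no coincidence: nnz = E * n_lags * n_cols
  ev2 <- manual_events(c(0.3, 0.5, 0.7, 0.4), clearance = 1)
  w2 <- basis_spec(-0.1, 0.5, 100)
  de2 <- time_expand_fir(ev2, list(terms = "y ~ 1 + dur", window = w2),
                         sfreq = 100, n_samples = 2000, t0 = -1)
  expect_equal(Matrix::nnzero(de2$X), 4 * 60 * 2)
  expect_equal(nrow(de2$column_meta), ncol(de2$X))

  # two trial types with different windows: columns concatenate
  ev3 <- tibble::tibble(onset = c(0.5, 1.5, 2.2, 3.4), duration = rep(0.3, 4),
                        trial_type = c("A", "B", "A", "B"))
  de3 <- time_expand_fir(ev3,
    list(A = list(terms = "y ~ 1", window = basis_spec(0, 0.2, 100)),
         B = list(terms = "y ~ 1", window = basis_spec(0, 0.4, 100))),
    sfreq = 100, n_samples = 500, t0 = 0)
  expect_equal(ncol(de3$X), 20 + 40)
  expect_equal(as.integer(table(de3$column_meta$event_type)[c("A", "B")]),
               c(20L, 40L))
})

test_that("out-of-range rows are truncated, not wrapped", {
  ev <- tibble::tibble(onset = 0.05, duration = 0.3, trial_type = "event")
  w <- basis_spec(-0.1, 0.1, 100)
  expect_message(
    de <- time_expand_fir(ev, list(terms = "y ~ 1", window = w),
                          sfreq = 100, n_samples = 100, t0 = 0),
    "truncated")
  expect_equal(Matrix::nnzero(de$X), 20 - 5)
})
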