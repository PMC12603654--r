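test_that("event sequences have the collinear duration/overlap structure", {
  ev <- sample_event_sequence("halfnormal", n_events = 500, block_size = 25,
                              inter_block_interval = 5, seed = 7)
  expect_equal(nrow(ev), 500)
  expect_true(all(diff(ev$onset) > 0))
  # within blocks, duration(i) == onset(i+1) - onset(i) exactly
  block <- (seq_len(500) - 1) %/% 25
  inner <- which(diff(block) == 0)
  expect_equal(ev$duration[inner], diff(ev$onset)[inner], tolerance = 1e-12)
  expect_equal(stats::cor(ev$duration[inner], diff(ev$onset)[inner]), 1)
  # exactly 19 within-run gaps larger than the events (20 blocks -> 19 breaks
  # between them); block-final durations are independent draws
  expect_equal(sum(diff(block) != 0), 19)
  expect_true(all(diff(ev$onset)[diff(block) != 0] >= 5))
})

test_that("uniform inter-event distances have the right mean", {
  ev <- sample_event_sequence("uniform", n_events = 10000, block_size = 10000,
                              seed = 11)
  se <- (3.5 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(ev$duration) - 1.75), 3 * se)
})

test_that("sequences are reproducible and validated", {
  a <- sample_event_sequence("uniform", n_events = 50, seed = 5)
  b <- sample_event_sequence("uniform", n_events = 50, seed = 5)
  expect_identical(a, b)
  expect_error(sample_event_sequence("uniform", n_events = 50, block_size = 10,
                                     inter_block_interval = 0, seed = 1),
               "inter_block_interval")
})

test_that("rendering superposes kernels linearly", {
  spec <- kernel_spec("hanning", sfreq = 100)
  # single event: the signal slice equals the kernel exactly
  ev1 <- tibble::tibble(onset = 1, duration = 0.5, trial_type = "event")
  sig <- render_continuous(ev1, spec, total_padding = 1)
  k <- make_kernel(spec, 0.5)
  s0 <- (1 + 1) * 100 + 1
  expect_equal(sig$data[1, s0:(s0 + length(k) - 1)], k)
  expect_equal(sum(sig$data) - sum(k), 0, tolerance = 1e-12)

  # two overlapping events: overlapped samples are the elementwise sum
  ev2 <- tibble::tibble(onset = c(1, 1.2), duration = c(0.5, 0.5),
                        trial_type = "event")
  sig2 <- render_continuous(ev2, spec, total_padding = 1)
  manual <- numeric(ncol(sig2$data))
  for (on in c(1, 1.2)) {
    i0 <- round((on + 1) * 100) + 1
    manual[i0:(i0 + length(k) - 1)] <- manual[i0:(i0 + length(k) - 1)] + k
  }
  expect_equal(sig2$data[1, ], manual)
  expect_equal(sum(sig2$data), 2 * sum(k), tolerance = 1e-10)
})

test_that("noise generators match their nominal statistics", {
  z <- signal(numeric(1e5), sfreq = 100)
  white <- add_noise(z, noise_spec("white", amplitude = 1, seed = 2))
  expect_true(stats::sd(white$data) > 0.99 && stats::sd(white$data) < 1.01)

  ar <- add_noise(z, noise_spec("ar1", amplitude = 1, ar_coefficient = 0.9,
                                seed = 3))
  x <- ar$data[1, ]
  r1 <- stats::cor(x[-1], x[-length(x)])
  expect_true(r1 > 0.89 && r1 < 0.91)
  expect_equal(stats::sd(x), 1, tolerance = 0.05) # amplitude is the marginal SD

  # amplitude 0 and kind "none" are identities; same seed reproduces
  expect_identical(add_noise(z, noise_spec("white", amplitude = 0))$data, z$data)
  expect_identical(add_noise(z, noise_spec("none"))$data, z$data)
  a <- add_noise(z, noise_spec("pink", amplitude = 0.5, seed = 4))
  b <- add_noise(z, noise_spec("pink", amplitude = 0.5, seed = 4))
  expect_identical(a$data, b$data)
})

test_that("high-pass filter attenuates DC and passes the passband", {
  sfreq <- 100
  const <- signal(rep(3, 2000), sfreq)
  filt <- highpass_filter(const, 0.5)
  core <- filt$data[1, 500:1500]
  expect_lt(max(abs(core)), 1e-6 * 3)

  # 5 Hz unit sine passes within 2% in steady state
  t <- (0:3999) / sfreq
  sine <- signal(sin(2 * pi * 5 * t), sfreq)
  out <- highpass_filter(sine, 0.5)
  amp <- max(abs(out$data[1, 1000:3000]))
  expect_equal(amp, 1, tolerance = 0.02)

  expect_error(highpass_filter(const, 60), "Nyquist")
})

test_that("the full simulation pipeline is deterministic given a seed", {
  ks <- kernel_spec("scaled_hanning", sfreq = 50)
  a <- simulate_study(ks, n_events = 60, seed = 42)
  b <- simulate_study(ks, n_events = 60, seed = 42)
  expect_identical(a$signal$data, b$signal$data)
  expect_identical(a$events, b$events)
})
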