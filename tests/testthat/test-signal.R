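test_that("low-pass filter has unit DC gain and rejects bad cutoffs", {
  f <- lowpass_filter(trap_trace(rep(0.5, 2e5), fs = 1e4))
  expect_lt(max(abs(f$values - 0.5)), 1e-6)
  expect_equal(f$effective_fs, 100)
  expect_error(lowpass_filter(trap_trace(rnorm(100), fs = 4)),
               "Nyquist")
  expect_error(lowpass_filter(trap_trace(rnorm(1000), fs = 1000),
                              decimate_to_hz = 4),
               "decimate_to_hz")
})

test_that("a tone at 10x the cutoff is attenuated at least 40-fold", {
  t <- (0:199999) / 1e4
  x <- sin(2 * pi * 30 * t) + 1
  f <- lowpass_filter(trap_trace(x, fs = 1e4))
  expect_gt((1 / sqrt(2)) / sd(f$values), 40)
})

test_that("telegraph plateaus settle to the input levels away from edges", {
  ev <- simulate_event_sequence(0.4, 0.4, duration_s = 60, seed = 3)
  cfg <- sim_config(k_off = 0.4, sigma_unbound = 0, sigma_bound = 0,
                    fs = 1e4, duration_s = 60, seed = 3)
  f <- lowpass_filter(render_trace(ev, cfg))
  r <- rle(f$true_state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$lengths >= 250)   # dwells >= 2.5 s at 100 Hz
  expect_gt(length(long), 3)
  for (i in long) {
    centre <- (starts[i] + ends[i]) %/% 2
    level <- if (r$values[i] == 1) 1.01 else 1.0
    expect_lt(abs(f$values[centre] - level) / 0.01, 0.001)
  }
})

test_that("the filter is zero-phase (cross-correlation peak at lag 0)", {
  set.seed(9)
  x <- cumsum(rnorm(5000))
  f <- lowpass_filter(trap_trace(x, fs = 1000), cutoff_hz = 3,
                      decimate_to_hz = 1000)
  cc <- stats::ccf(f$values, x, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("decimation preserves dwell durations to one sample period", {
  ev <- simulate_event_sequence(2, 2, duration_s = 30, seed = 14)
  cfg <- sim_config(k_off = 2, fs = 1e4, duration_s = 30, seed = 14)
  f <- lowpass_filter(render_trace(ev, cfg))
  runs <- rle(f$true_state)
  d100 <- runs$lengths / f$effective_fs
  true_d <- ev$dwell_durations_s
  true_d <- true_d[true_d >= 2 / f$effective_fs]
  # every retained true dwell appears in the decimated labels within one
  # effective sample period
  for (td in true_d) {
    expect_true(any(abs(d100 - td) <= 1 / f$effective_fs))
  }
})

test_that("segmentation follows the 30 s / 10 s remainder convention", {
  f <- make_filtered(rnorm(100 * 100), fs = 100)
  segs <- segment_trace(f)
  expect_equal(vapply(segs, function(s) length(s$values) / 100, numeric(1)),
               c(30, 30, 30, 10))
  # 95 s: the 5 s remainder is dropped; kept portion concatenates back
  f2 <- make_filtered(rnorm(95 * 100), fs = 100)
  segs2 <- segment_trace(f2)
  expect_equal(length(segs2), 3L)
  expect_identical(unlist(lapply(segs2, `[[`, "values")),
                   f2$values[1:9000])
  # 110 s: everything analyzed
  f3 <- make_filtered(rnorm(110 * 100), fs = 100)
  expect_equal(sum(vapply(segment_trace(f3), function(s) length(s$values),
                          numeric(1))) / 100, 110)
  expect_warning(segment_trace(make_filtered(rnorm(500), fs = 100)),
                 "single segment")
})

test_that("two-Gaussian PDF fit recovers mixture parameters", {
  set.seed(7)
  n <- 50000
  x <- c(rnorm(round(0.78 * n), 1.01, 0.004), rnorm(round(0.22 * n), 1.0, 0.002))
  fit <- fit_two_gaussian_pdf(trap_trace(x, fs = 100))
  expect_true(fit$converged)
  expect_false(fit$single_state)
  expect_lt(abs(fit$A_B - 0.78), 0.05)
  expect_lt(abs(fit$A_U - 0.22), 0.05)
  expect_lt(abs(fit$sigma_B - 0.004) / 0.004, 0.2)
  expect_lt(abs(fit$sigma_U - 0.002) / 0.002, 0.2)
  expect_gt(fit$mu_B, fit$mu_U)
})

test_that("mixture component areas sum to one on converged fits", {
  for (s in 1:5) {
    set.seed(s)
    w <- runif(1, 0.3, 0.8)
    x <- c(rnorm(round(w * 3e4), 1.01, 0.004),
           rnorm(round((1 - w) * 3e4), 1.0, 0.002))
    fit <- fit_two_gaussian_pdf(trap_trace(x, fs = 100))
    expect_true(fit$converged)
    expect_lt(abs(fit$A_B + fit$A_U - 1), 0.05)
  }
})

test_that("single-Gaussian input raises the single-state flag", {
  set.seed(3)
  fit <- fit_two_gaussian_pdf(trap_trace(rnorm(20000, 1, 0.003), fs = 100))
  expect_true(fit$single_state)
  expect_error(normalized_bound_intensity(fit), "single-state")
})

test_that("normalized bound intensity is 100 * mu_B / mu_U", {
  f <- structure(list(A_B = .5, A_U = .5, mu_B = 1.01, mu_U = 1.00,
                      sigma_B = .004, sigma_U = .002,
                      converged = TRUE, single_state = FALSE),
                 class = "mixture_fit")
  expect_equal(normalized_bound_intensity(f), 101)
  f$mu_B <- f$mu_U
  expect_equal(normalized_bound_intensity(f), 100)
})
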