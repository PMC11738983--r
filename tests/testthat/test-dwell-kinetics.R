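test_that("dwell extraction run-length encodes and censors edges", {
  p <- make_state_path(c(0, 0, 1, 1, 1, 0, 0, 1), fs = 100)
  dw <- extract_dwells(p)
  expect_equal(dw$bound_s, 0.03)
  expect_equal(dw$unbound_s, 0.02)
  expect_equal(dw$censored_count, 2L)
  dw2 <- extract_dwells(p, drop_edges = FALSE)
  expect_equal(sort(dw2$unbound_s), c(0.02, 0.02))
  expect_equal(sort(dw2$bound_s), c(0.01, 0.03))
  expect_warning(out <- extract_dwells(make_state_path(c(0, 0, 1, 1))),
                 "edge-censored")
  expect_length(out$bound_s, 0)
})

test_that("dwell means from an inferred path approach the study taus", {
  tr <- make_study_trace(duration_s = 120, seed = 23)
  segs <- segment_trace(lowpass_filter(tr))
  sets <- lapply(seq_along(segs), function(i) {
    p <- fit_two_state_hmm(segs[[i]], seed = i)
    p <- correct_spurious_transitions(p, segs[[i]])
    extract_dwells(p, segment_id = paste0("s", i))
  })
  dw <- pool_dwells(sets)
  # the 3 Hz filter merges sub-0.1 s dwells, inflating both means; the
  # check is that both dwell classes sit in the right regime and inflate
  # together so that their ratio stays near tau_on/tau_off
  expect_gt(mean(dw$bound_s), 0.3)
  expect_lt(mean(dw$bound_s), 0.9)
  ratio <- mean(dw$unbound_s) / mean(dw$bound_s)
  expect_equal(ratio, 0.37 / 0.3968, tolerance = 0.15)
})

test_that("exponential CDF fit is exact on model-consistent input", {
  n <- 200
  tau <- 0.40
  x <- -tau * log(1 - (seq_len(n) - 0.5) / n)
  fit <- fit_exponential_cdf(x)
  expect_equal(fit$tau, 0.40, tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.9999)
  expect_equal(fit$method, "cdf-least-squares")
})

test_that("exponential CDF fit recovers tau from random draws", {
  set.seed(12)
  x <- rexp(1e4, rate = 1 / 0.40)
  fit <- fit_exponential_cdf(x)
  expect_equal(fit$tau, 0.40, tolerance = 0.02)
  expect_gt(fit$r_squared, 0.99)
})

test_that("CDF-fit tau agrees with the MLE on exponential data", {
  for (s in 1:5) {
    set.seed(100 + s)
    x <- rexp(200 + s * 100, rate = 1 / 0.37)
    fit <- fit_exponential_cdf(x)
    expect_lt(abs(fit$tau - fit$tau_mle) / fit$tau_mle, 0.05)
  }
})

test_that("CDF fit input validation", {
  expect_error(fit_exponential_cdf(c(1, 2, 3)), "at least 5")
  expect_error(fit_exponential_cdf(c(1, 2, 3, 0, 5)), "positive")
})

test_that("depletion quadratic reproduces the dense-grid oracle", {
  # oracle: dense grid search of the mass-balance residual over [0, Pt]
  resid <- function(pl, pt, lt, ts) {
    (1 + ts) * pl^2 - (pt + (1 + ts) * lt) * pl + pt * lt
  }
  grid <- seq(0, 10, by = 1e-5)
  oracle <- grid[which.min(abs(resid(grid, 10, 20, 0.925)))]
  expect_equal(oracle, 5.19481, tolerance = 1e-4)   # frozen oracle value
  expect_equal(solve_complex_concentration(10, 20, 0.925), oracle,
               tolerance = 1e-4)
})

test_that("weak binding drives the complex concentration to zero", {
  expect_lt(solve_complex_concentration(10, 20, 1e9), 1e-6)
})

test_that("the returned root satisfies the mass-action identity", {
  # moderate-depletion draws (the regime the assay operates in); in the
  # total-depletion corner L_total - PL cancels catastrophically and no
  # floating-point root can satisfy the identity to 1e-9
  set.seed(5)
  for (i in 1:20) {
    pt <- runif(1, 0.5, 50)
    lt <- pt * runif(1, 0.5, 3)
    ts <- exp(runif(1, -1, 1))
    pl <- solve_complex_concentration(pt, lt, ts)
    expect_gte(pl, 0)
    expect_lte(pl, min(pt, lt))
    lhs <- (pt - pl) * (lt - pl) / pl
    rhs <- ts * (lt - pl)
    expect_lt(abs(lhs - rhs) / rhs, 1e-9)
  }
})

test_that("kinetics identities hold for every result", {
  set.seed(8)
  for (i in 1:10) {
    pt <- runif(1, 1, 30)
    k <- compute_kinetics(runif(1, 0.2, 2), runif(1, 0.2, 2),
                          P_total = pt,
                          L_total = pt * runif(1, 0.5, 3))
    expect_equal(k$K_D, k$k_off / k$k_on, tolerance = 1e-12)
    expect_equal(k$PL + k$L_free, k$L_total, tolerance = 1e-9)
    expect_lte(k$PL, k$P_total + 1e-12)
  }
})

test_that("K_D increases with tau_on at fixed tau_off", {
  kds <- vapply(seq(0.2, 1.2, by = 0.2), function(ton) {
    compute_kinetics(ton, 0.4, 10, 20)$K_D
  }, numeric(1))
  expect_true(all(diff(kds) > 0))
})

test_that("standard-state Gibbs energy is zero at K_D = 1 M", {
  # tau* = 0.5 against 2 M ligand gives K_D = 1e6 uM = 1 M
  k <- compute_kinetics(0.2, 0.4, P_total = 10, L_total = 2e6)
  expect_equal(k$K_D, 1e6, tolerance = 1e-3)
  expect_equal(k$delta_G, 0, tolerance = 1e-2)
})
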