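test_that("polarization formula and inversion identity", {
  expect_equal(polarization(1, 1), 0)
  expect_equal(polarization(1, 0), 1)
  expect_equal(polarization(3, 1), 0.5)
  expect_error(polarization(0, 0), "positive")
  # identity: intensities constructed from a given P recover P
  for (p in seq(-0.9, 0.9, by = 0.3)) {
    i_par <- (1 + p) / 2
    i_perp <- (1 - p) / 2
    expect_equal(polarization(i_par, i_perp), p)
  }
})

test_that("one-site FP fit round-trips noiseless titrations", {
  fp <- simulate_fp_titration(9.4, 100, seq(1, 80, length.out = 16))
  fit <- fit_one_site_fp(fp)
  expect_true(fit$converged)
  expect_equal(fit$K_D, 9.4, tolerance = 1e-3)
  expect_equal(fit$P_max, 100, tolerance = 1e-3)
})

test_that("one-site FP fit recovers K_D from noisy replicate curves", {
  conc <- seq(1, 80, length.out = 16)
  reps <- do.call(rbind, lapply(1:3, function(r) {
    simulate_fp_titration(9.4, 100, conc, noise_sd = 2, seed = 100 + r)
  }))
  fit <- fit_one_site_fp(reps)
  expect_true(fit$converged)
  expect_lt(abs(fit$K_D - 9.4) / 9.4, 0.15)
})

test_that("FP fit is scale-equivariant", {
  fp <- simulate_fp_titration(9.4, 100, seq(1, 80, length.out = 12),
                              noise_sd = 1, seed = 4)
  f1 <- fit_one_site_fp(fp)
  fp2 <- fp
  fp2$P_mP <- fp2$P_mP * 3
  f2 <- fit_one_site_fp(fp2)
  expect_equal(f2$K_D, f1$K_D, tolerance = 1e-6)
  expect_equal(f2$P_max, 3 * f1$P_max, tolerance = 1e-6)
})

test_that("FP fit rejects under-determined titrations", {
  expect_error(fit_one_site_fp(data.frame(conc_uM = c(1, 2, 5),
                                          P_mP = c(10, 18, 35))),
               "4 distinct")
})

test_that("Tm extraction hits the construction midpoint", {
  mc <- simulate_melt_curve(53.5, 1.5, 0.8, 1.1, seq(20, 90, 0.1))
  expect_equal(melt_tm(mc)$T_m, 53.5, tolerance = 0.05)
  mc2 <- simulate_melt_curve(52.7, 1.5, 0.8, 1.1, seq(20, 90, 0.1))
  expect_equal(melt_tm(mc2)$T_m, 52.7, tolerance = 0.05)
})

test_that("Tm shift between apo and liganded curves is recovered", {
  shifts <- vapply(1:8, function(s) {
    a <- melt_tm(simulate_melt_curve(53.5, 1.5, 0.8, 1.1, seq(20, 90, 0.1),
                                     noise_sd = 0.002, seed = s,
                                     noise_mode = "relative"))$T_m
    b <- melt_tm(simulate_melt_curve(52.7, 1.5, 0.8, 1.1, seq(20, 90, 0.1),
                                     noise_sd = 0.002, seed = 500 + s,
                                     noise_mode = "relative"))$T_m
    a - b
  }, numeric(1))
  expect_equal(mean(shifts), 0.8, tolerance = 0.15)
})

test_that("Tm extraction is invariant to common intensity scaling", {
  tt <- seq(20, 90, 0.2)
  i330 <- 1000 * (1.2 - 0.2 / (1 + exp((53.5 - tt) / 1.5)))
  i350 <- 1000 * (0.95 + 0.2 / (1 + exp((53.5 - tt) / 1.5)))
  c1 <- structure(data.frame(temp_C = tt, I330 = i330, I350 = i350),
                  class = c("melt_curve", "data.frame"))
  c2 <- c1
  c2$I330 <- c2$I330 * 7.3
  c2$I350 <- c2$I350 * 7.3
  expect_equal(melt_tm(c1)$T_m, melt_tm(c2)$T_m, tolerance = 1e-9)
})

test_that("flat and featureless melt curves raise a no-transition error", {
  expect_error(melt_tm(simulate_melt_curve(53.5, 1.5, 1.0, 1.0,
                                           seq(20, 90, 0.5))),
               "no melting transition")
  lin <- structure(data.frame(temp_C = seq(20, 90, 0.5),
                              ratio = seq(0.8, 1.1, length.out = 141)),
                   class = c("melt_curve", "data.frame"))
  expect_error(melt_tm(lin), "no melting transition")
})

test_that("two-point CPMG R2 is exact on noiseless decays", {
  expect_equal(cpmg_r2(simulate_cpmg_pair(6.93, 100)), 6.93)
  expect_equal(cpmg_r2(simulate_cpmg_pair(1.85, 100)), 1.85)
  p <- list(I_short = exp(1), I_long = 1, t_short = 0, t_long = 0.1)
  expect_equal(cpmg_r2(p), 10)
  expect_equal(cpmg_r2(list(I_short = 5, I_long = 5,
                            t_short = 0.002, t_long = 0.102)), 0)
  # exact for arbitrary delays
  for (s in 1:5) {
    set.seed(s)
    r2 <- runif(1, 0.5, 30)
    ts <- runif(1, 0, 0.01)
    tl <- ts + runif(1, 0.01, 0.3)
    expect_equal(cpmg_r2(simulate_cpmg_pair(r2, 10, ts, tl)), r2,
                 tolerance = 1e-10)
  }
})

test_that("unphysical intensity growth yields a flagged negative R2", {
  expect_warning(r2 <- cpmg_r2(list(I_short = 1, I_long = 2,
                                    t_short = 0.002, t_long = 0.102)),
                 "unphysical")
  expect_lt(r2, 0)
})
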