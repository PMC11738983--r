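#' Fluorescence polarization from parallel/perpendicular intensities
#'
#' `P = (I_par - I_perp) / (I_par + I_perp)`, dimensionless in [-1, 1]
#' (multiply by 1000 for mP).
#'
#' @param I_parallel,I_perpendicular Emission intensities, a.u.
#' @return Polarization (vectorized).
#' @export
polarization <- function(I_parallel, I_perpendicular) {
  tot <- I_parallel + I_perpendicular
  if (any(tot <= 0)) {
    stop("total intensity must be positive", call. = FALSE)
  }
  (I_parallel - I_perpendicular) / tot
}

#' One-site binding fit of a fluorescence-polarization titration
#'
#' Nonlinear least-squares fit of `P(C) = P_max * C / (K_D + C)` to
#' polarization versus titrated protein concentration. `K_D` is
#' initialized at the concentration of half-maximal observed polarization
#' and `P_max` at 1.2x the maximum observed value; parameters are
#' constrained positive. The isotherm has zero intercept (P = 0 at C = 0);
#' an optional free intercept can be enabled for instrument offsets.
#'
#' @param curve An `fp_curve` (columns `conc_uM`, `P_mP`) or any data
#'   frame with those columns; replicate measurements at the same
#'   concentration are simply pooled.
#' @param background Scalar background polarization subtracted before
#'   fitting, mP.
#' @param free_intercept Fit an additive offset as well (default FALSE).
#' @return An `fp_fit` with `K_D` (uM), `P_max` (mP), `r_squared`,
#'   `converged` (and `intercept` when freed).
#' @export
fit_one_site_fp <- function(curve, background = 0, free_intercept = FALSE) {
  df <- as.data.frame(curve)
  if (!all(c("conc_uM", "P_mP") %in% names(df))) {
    stop("curve must have columns `conc_uM` and `P_mP`", call. = FALSE)
  }
  if (length(unique(df$conc_uM)) < 4L) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  df$P_mP <- df$P_mP - background
  p_max0 <- 1.2 * max(df$P_mP)
  half <- max(df$P_mP) / 2
  kd0 <- df$conc_uM[which.min(abs(df$P_mP - half))]
  if (kd0 <= 0) kd0 <- median(df$conc_uM[df$conc_uM > 0])
  form <- if (free_intercept) {
    P_mP ~ Pmax * conc_uM / (KD + conc_uM) + b0
  } else {
    P_mP ~ Pmax * conc_uM / (KD + conc_uM)
  }
  start <- if (free_intercept) list(Pmax = p_max0, KD = kd0, b0 = 0)
           else list(Pmax = p_max0, KD = kd0)
  lower <- if (free_intercept) c(1e-12, 1e-12, -Inf) else c(1e-12, 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(K_D = NA_real_, P_max = NA_real_,
                          r_squared = NA_real_, converged = FALSE),
                     class = "fp_fit"))
  }
  cf <- coef(fit)
  resid <- df$P_mP - predict(fit)
  r2 <- 1 - sum(resid^2) / sum((df$P_mP - mean(df$P_mP))^2)
  structure(list(K_D = as.numeric(cf[["KD"]]),
                 P_max = as.numeric(cf[["Pmax"]]),
                 intercept = if (free_intercept) as.numeric(cf[["b0"]])
                             else NULL,
                 r_squared = r2, converged = TRUE),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat(sprintf("<fp_fit> K_D=%.3f uM, P_max=%.2f mP, R^2=%.4f%s\n",
              x$K_D, x$P_max, x$r_squared,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Melting temperature from a thermal melt curve
#'
#' Computes the fluorescence ratio I350/I330 (or uses a precomputed
#' `ratio` column), smooths it with a local quadratic (Savitzky-Golay)
#' filter over a ~`smooth_window_degC` window, differentiates numerically
#' and locates the extremum of largest magnitude of the first derivative;
#' the melting temperature is refined by parabolic interpolation around
#' the extremal grid point. Using the largest-magnitude extremum (rather
#' than the minimum) keeps the extractor robust to the orientation of the
#' plotted ratio.
#'
#' @param curve A `melt_curve`: data frame with `temp_C` and either
#'   `ratio` or both `I330` and `I350`.
#' @param smooth_window_degC Smoothing window, deg C (default 1).
#' @return A list with `T_m` (deg C) and `dFIR` (the smoothed derivative,
#'   same length as the grid). A flat curve (derivative indistinguishable
#'   from its noise floor) raises a no-transition error.
#' @export
melt_tm <- function(curve, smooth_window_degC = 1.0) {
  df <- as.data.frame(curve)
  if (!"temp_C" %in% names(df)) {
    stop("curve must have a `temp_C` column", call. = FALSE)
  }
  if (!"ratio" %in% names(df)) {
    if (!all(c("I330", "I350") %in% names(df))) {
      stop("curve must have `ratio` or both `I330` and `I350`",
           call. = FALSE)
    }
    if (any(df$I330 <= 0)) stop("I330 must be positive", call. = FALSE)
    df$ratio <- df$I350 / df$I330
  }
  tt <- df$temp_C
  if (length(tt) < 20L) {
    stop("need at least 20 grid points covering the transition",
         call. = FALSE)
  }
  if (any(diff(tt) <= 0)) {
    stop("temperature grid must be strictly increasing", call. = FALSE)
  }
  dT <- median(diff(tt))
  odd_win <- function(w_degC) {
    w <- max(5L, 2L * floor(w_degC / (2 * dT)) + 1L)
    if (w >= length(tt)) w <- ((length(tt) - 1L) %/% 2L) * 2L - 1L
    max(w, 5L)
  }
  # local-quadratic (Savitzky-Golay) first derivative over the window
  win <- odd_win(smooth_window_degC)
  d <- signal::sgolayfilt(df$ratio, p = 2, n = win, m = 1, ts = dT)
  # peak localization uses a wider second smoothing pass, matched to the
  # few-degC width of a typical melting-transition derivative peak; a
  # symmetric smoother does not displace a symmetric peak
  d_loc <- signal::sgolayfilt(d, p = 2, n = odd_win(5 * smooth_window_degC))
  # no-transition guard: peak derivative must stand out from the typical
  # derivative magnitude (a pure trend or flat noise fails this)
  mag <- abs(d_loc)
  i <- which.max(mag)
  floor_est <- median(mag, na.rm = TRUE)
  if (!is.finite(mag[i]) || mag[i] < 3 * floor_est + 1e-15 ||
      mag[i] < 1e-12) {
    stop("no melting transition detected: derivative is flat",
         call. = FALSE)
  }
  # parabolic refinement around the extremal grid point
  tm <- tt[i]
  if (i > 1L && i < length(tt)) {
    y1 <- mag[i - 1L]; y2 <- mag[i]; y3 <- mag[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (is.finite(denom) && abs(denom) > 1e-15) {
      delta <- 0.5 * (y1 - y3) / denom
      delta <- max(min(delta, 0.5), -0.5)
      tm <- tt[i] + delta * dT
    }
  }
  list(T_m = tm, dFIR = d)
}

#' Two-point CPMG transverse relaxation rate
#'
#' Converts a pair of spin-echo intensities recorded at two transverse
#' delay times into the relaxation rate
#' `R2 = ln(I_short / I_long) / (t_long - t_short)`. An intensity that
#' grows with delay (unphysical) yields a negative R2 with a warning.
#'
#' @param pair A `cpmg_pair` (fields `I_short`, `I_long`, `t_short`,
#'   `t_long`).
#' @return R2 in 1/s.
#' @export
cpmg_r2 <- function(pair) {
  stopifnot(inherits(pair, "cpmg_pair") ||
              all(c("I_short", "I_long", "t_short", "t_long") %in%
                    names(pair)))
  if (pair$I_short <= 0 || pair$I_long <= 0) {
    stop("intensities must be positive", call. = FALSE)
  }
  if (pair$t_long <= pair$t_short) {
    stop("need t_long > t_short", call. = FALSE)
  }
  r2 <- log(pair$I_short / pair$I_long) / (pair$t_long - pair$t_short)
  if (r2 < 0) {
    warning("I_long >= I_short: signal growth with delay is unphysical; ",
            "returning negative R2")
  }
  r2
}
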