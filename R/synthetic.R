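#' Simulation configuration for a trapping trace
#'
#' Bundles the kinetic, signal and acquisition parameters used by
#' [render_trace()]. The defaults reproduce the study conditions of the
#' PR65 / ATUX-8385 trapping experiments: mean bound dwell 0.40 s
#' (`k_off = 2.5` 1/s), mean unbound dwell 0.37 s at 20 uM ligand, a bound
#' level 1% above the unbound level, state-dependent Gaussian noise
#' (sigma 0.002 V unbound, 0.004 V bound) and 100 kHz sampling.
#'
#' @param k_off Bound-state exit rate, 1/s.
#' @param k_on Association rate constant, 1/(s uM). The unbound-state exit
#'   rate is `k_on * L_free`; when `L_free` is not supplied it is obtained
#'   from the depletion quadratic at `P_total`/`L_total`.
#' @param P_total,L_total Total protein and ligand concentrations, uM.
#' @param mu_unbound Unbound transmission level, V (baseline; arbitrary
#'   units of the photodetector).
#' @param contrast Bound/unbound level ratio (> 1: the bound, extended
#'   conformation scatters more).
#' @param sigma_unbound,sigma_bound Per-state noise standard deviations, V.
#' @param fs Sampling rate, Hz.
#' @param duration_s Trace duration, s.
#' @param drift_slope Linear baseline drift, V/s.
#' @param temperature Sample temperature, K.
#' @param seed Integer seed; dwell sampling uses `seed`, the noise stream
#'   uses `seed + 7919` so the two are independently reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(k_off = 2.5, k_on = 1 / (0.37 * 14.805),
                       P_total = 10, L_total = 20,
                       mu_unbound = 1.0, contrast = 1.01,
                       sigma_unbound = 0.002, sigma_bound = 0.004,
                       fs = 1e5, duration_s = 100, drift_slope = 0,
                       temperature = 308.15, seed = 1L) {
  .check_positive(k_off, "k_off")
  .check_positive(k_on, "k_on")
  .check_positive(P_total, "P_total")
  .check_positive(L_total, "L_total")
  .check_positive(fs, "fs")
  .check_positive(duration_s, "duration_s")
  .check_positive(mu_unbound, "mu_unbound")
  if (contrast <= 1) {
    stop("`contrast` must exceed 1: the bound state scatters more",
         call. = FALSE)
  }
  .check_nonneg(sigma_unbound, "sigma_unbound")
  .check_nonneg(sigma_bound, "sigma_bound")
  structure(list(
    k_off = k_off, k_on = k_on, P_total = P_total, L_total = L_total,
    mu_unbound = mu_unbound, contrast = contrast,
    sigma_unbound = sigma_unbound, sigma_bound = sigma_bound,
    fs = fs, duration_s = duration_s, drift_slope = drift_slope,
    temperature = temperature, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate an alternating bound/unbound event sequence
#'
#' Continuous-time realization of the reversible 1:1 scheme
#' P + L <-> PL: residence times are independent exponentials, with exit
#' rate `k_off` from the bound state and pseudo-first-order rate
#' `k_on_eff = k_on * [L]free` from the unbound state. The final dwell is
#' truncated at `duration_s` and flagged as censored.
#'
#' @param k_off Bound-state exit rate, 1/s.
#' @param k_on_eff Unbound-state exit rate `k_on * [L]free`, 1/s.
#' @param duration_s Total duration, s.
#' @param initial_state 0 (unbound) or 1 (bound).
#' @param seed Integer seed.
#' @return An `event_sequence` with fields `state_at_start`,
#'   `dwell_durations_s` (alternating states), `total_duration_s` and
#'   `censored_last`.
#' @examples
#' ev <- simulate_event_sequence(2.5, 1 / 0.37, duration_s = 50, seed = 1)
#' mean(dwell_states(ev) == 1)  # fraction of dwells that are bound
#' @export
simulate_event_sequence <- function(k_off, k_on_eff, duration_s,
                                    initial_state = 0L, seed = 1L) {
  .check_positive(k_off, "k_off")
  .check_positive(k_on_eff, "k_on_eff")
  .check_positive(duration_s, "duration_s")
  if (!initial_state %in% c(0L, 1L)) {
    stop("`initial_state` must be 0 (unbound) or 1 (bound)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  # draw dwells in blocks until the target duration is covered
  dwells <- numeric(0)
  state0 <- as.integer(initial_state)
  expected_n <- ceiling(duration_s * (k_off + k_on_eff)) + 10L
  repeat {
    n_have <- length(dwells)
    # continue the alternation from where the previous block stopped
    states <- (state0 + n_have + seq_len(expected_n) - 1L) %% 2L
    block <- rexp(expected_n, rate = ifelse(states == 1L, k_off, k_on_eff))
    dwells <- c(dwells, block)
    if (sum(dwells) >= duration_s) break
  }
  cs <- cumsum(dwells)
  n_keep <- which(cs >= duration_s)[1L]
  dwells <- dwells[seq_len(n_keep)]
  dwells[n_keep] <- duration_s - if (n_keep > 1L) cs[n_keep - 1L] else 0
  structure(list(
    state_at_start = state0,
    dwell_durations_s = dwells,
    total_duration_s = duration_s,
    censored_last = TRUE
  ), class = "event_sequence")
}

#' Per-dwell states of an event sequence
#' @param events An `event_sequence`.
#' @return Integer vector (0/1), one entry per dwell.
#' @export
dwell_states <- function(events) {
  stopifnot(inherits(events, "event_sequence"))
  (events$state_at_start + seq_along(events$dwell_durations_s) - 1L) %% 2L
}

#' Render an event sequence into a sampled transmission trace
#'
#' Each sample takes the level of its state (`mu_unbound` or
#' `mu_unbound * contrast`), plus optional linear drift and per-state white
#' Gaussian noise. The true per-sample state labels are carried along for
#' accuracy scoring of the downstream inference.
#'
#' @param events An `event_sequence`.
#' @param cfg A [sim_config()].
#' @return A `trap_trace` with `values`, `fs`, `t0`, `metadata`
#'   (concentrations, temperature, seed) and `true_state`.
#' @export
render_trace <- function(events, cfg) {
  stopifnot(inherits(events, "event_sequence"), inherits(cfg, "sim_config"))
  if (length(events$dwell_durations_s) == 0L) {
    stop("empty event sequence", call. = FALSE)
  }
  n <- floor(cfg$fs * events$total_duration_s)
  if (n < 2L) stop("trace must contain at least 2 samples", call. = FALSE)
  t <- (seq_len(n) - 1) / cfg$fs
  edges <- cumsum(events$dwell_durations_s)
  idx <- findInterval(t, edges, left.open = FALSE) + 1L
  idx[idx > length(edges)] <- length(edges)
  state <- dwell_states(events)[idx]
  mu_b <- cfg$mu_unbound * cfg$contrast
  level <- ifelse(state == 1L, mu_b, cfg$mu_unbound)
  sigma <- ifelse(state == 1L, cfg$sigma_bound, cfg$sigma_unbound)
  set.seed(cfg$seed + 7919L)  # independent noise stream
  values <- level + cfg$drift_slope * t + rnorm(n, 0, 1) * sigma
  trap_trace(values, fs = cfg$fs,
             metadata = list(P_total = cfg$P_total, L_total = cfg$L_total,
                             temperature = cfg$temperature,
                             label = "synthetic", seed = cfg$seed),
             true_state = as.integer(state))
}

#' Construct a trapping trace object
#'
#' @param values Transmission samples, V.
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @param metadata Named list; `P_total`, `L_total` (uM) and `temperature`
#'   (K) are consumed by the kinetics stage.
#' @param true_state Optional 0/1 vector of ground-truth labels, same
#'   length as `values`.
#' @return A `trap_trace`.
#' @export
trap_trace <- function(values, fs, t0 = 0, metadata = list(),
                       true_state = NULL) {
  .check_positive(fs, "fs")
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("`values` must be finite numeric", call. = FALSE)
  }
  if (!is.null(true_state) && length(true_state) != length(values)) {
    stop("`true_state` must match `values` in length", call. = FALSE)
  }
  structure(list(values = as.numeric(values), fs = fs, t0 = t0,
                 metadata = metadata,
                 true_state = if (is.null(true_state)) NULL
                              else as.integer(true_state)),
            class = "trap_trace")
}

#' @export
print.trap_trace <- function(x, ...) {
  cat(sprintf("<%s> %d samples @ %g Hz (%.3f s)%s\n",
              paste(class(x), collapse = "/"),
              length(x$values), x$fs, length(x$values) / x$fs,
              if (is.null(x$true_state)) "" else ", with true labels"))
  invisible(x)
}

#' Simulate a one-site fluorescence-polarization titration
#'
#' Noiseless values follow the one-site binding isotherm
#' `P(C) = P_max * C / (K_D + C)`; Gaussian noise of standard deviation
#' `noise_sd` (mP) is added on top.
#'
#' @param K_D Dissociation constant, uM.
#' @param P_max Plateau polarization, mP.
#' @param concentrations Titrated protein concentrations, uM (>= 0).
#' @param noise_sd Measurement noise, mP.
#' @param seed Integer seed.
#' @return An `fp_curve` data frame with columns `conc_uM` and `P_mP`.
#' @export
simulate_fp_titration <- function(K_D, P_max, concentrations,
                                  noise_sd = 0, seed = 1L) {
  .check_positive(K_D, "K_D")
  .check_positive(P_max, "P_max")
  .check_nonneg(concentrations, "concentrations")
  .check_nonneg(noise_sd, "noise_sd")
  set.seed(as.integer(seed))
  p <- P_max * concentrations / (K_D + concentrations)
  if (noise_sd > 0) p <- p + rnorm(length(p), 0, noise_sd)
  structure(data.frame(conc_uM = concentrations, P_mP = p),
            class = c("fp_curve", "data.frame"))
}

#' Simulate a two-state thermal melt curve
#'
#' The fluorescence ratio follows a logistic transition
#' `ratio(T) = ratio_low + (ratio_high - ratio_low) / (1 + exp((T_m - T)/width))`
#' whose first-derivative extremum sits exactly at `T_m`.
#'
#' @param T_m Transition midpoint, deg C.
#' @param width Transition width, deg C.
#' @param ratio_low,ratio_high Pre-/post-transition I350/I330 ratios.
#' @param T_grid Strictly increasing temperature grid, deg C (>= 5 points).
#' @param noise_sd Noise level; standard deviation in ratio units
#'   (`noise_mode = "additive"`) or as a fraction of the noiseless ratio
#'   (`noise_mode = "relative"`).
#' @param seed Integer seed.
#' @param noise_mode `"additive"` or `"relative"`.
#' @return A `melt_curve` data frame with columns `temp_C` and `ratio`.
#' @export
simulate_melt_curve <- function(T_m, width, ratio_low = 0.8,
                                ratio_high = 1.1, T_grid,
                                noise_sd = 0, seed = 1L,
                                noise_mode = c("additive", "relative")) {
  noise_mode <- match.arg(noise_mode)
  .check_positive(width, "width")
  .check_nonneg(noise_sd, "noise_sd")
  if (length(T_grid) < 5L) {
    stop("`T_grid` must contain at least 5 points", call. = FALSE)
  }
  if (any(diff(T_grid) <= 0)) {
    stop("`T_grid` must be strictly increasing", call. = FALSE)
  }
  r <- ratio_low + (ratio_high - ratio_low) / (1 + exp((T_m - T_grid) / width))
  set.seed(as.integer(seed))
  if (noise_sd > 0) {
    eps <- rnorm(length(r), 0, noise_sd)
    r <- if (noise_mode == "relative") r * (1 + eps) else r + eps
  }
  structure(data.frame(temp_C = T_grid, ratio = r),
            class = c("melt_curve", "data.frame"))
}

#' Simulate a two-delay CPMG intensity pair
#'
#' Intensities decay as `I(t) = I0 * exp(-R2 * t)` plus optional Gaussian
#' noise. Default delays are the 2 ms / 102 ms transverse periods of the
#' paired spin-echo experiments.
#'
#' @param R2 Transverse relaxation rate, 1/s (>= 0).
#' @param I0 Intensity at zero delay, a.u. (> 0).
#' @param t_short,t_long Transverse delay times, s (`t_long > t_short >= 0`).
#' @param noise_sd Intensity noise, a.u.
#' @param seed Integer seed.
#' @return A `cpmg_pair` list with `I_short`, `I_long`, `t_short`, `t_long`.
#' @export
simulate_cpmg_pair <- function(R2, I0, t_short = 0.002, t_long = 0.102,
                               noise_sd = 0, seed = 1L) {
  if (!is.numeric(R2) || R2 < 0) stop("`R2` must be >= 0", call. = FALSE)
  .check_positive(I0, "I0")
  if (t_short < 0 || t_long <= t_short) {
    stop("need t_long > t_short >= 0", call. = FALSE)
  }
  set.seed(as.integer(seed))
  i_s <- I0 * exp(-R2 * t_short)
  i_l <- I0 * exp(-R2 * t_long)
  if (noise_sd > 0) {
    i_s <- i_s + rnorm(1, 0, noise_sd)
    i_l <- i_l + rnorm(1, 0, noise_sd)
  }
  structure(list(I_short = i_s, I_long = i_l,
                 t_short = t_short, t_long = t_long),
            class = "cpmg_pair")
}
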