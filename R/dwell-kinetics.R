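#' Extract residence times from a decoded state path
#'
#' Run-length encodes the 0/1 label sequence into bound and unbound dwell
#' durations. The first and last dwell of a segment are censored (their
#' start/end was not observed) and are dropped by default, with the count
#' recorded.
#'
#' @param path A `state_path`.
#' @param effective_fs Sampling rate of the labels, Hz; defaults to the
#'   rate recorded on the path.
#' @param drop_edges Drop the leading and trailing (censored) dwells.
#' @param segment_id Identifier stored with the dwells.
#' @return A `dwell_set` with `bound_s`, `unbound_s`, `censored_count` and
#'   `source_segments`. With `drop_edges` and fewer than 3 dwells an empty
#'   set is returned with a warning.
#' @export
extract_dwells <- function(path, effective_fs = NULL, drop_edges = TRUE,
                           segment_id = "seg1") {
  stopifnot(inherits(path, "state_path"))
  fs <- if (is.null(effective_fs)) path$effective_fs else effective_fs
  .check_positive(fs, "effective_fs")
  r <- rle(path$labels)
  states <- r$values
  dur <- r$lengths / fs
  censored <- 0L
  if (drop_edges) {
    if (length(dur) < 3L) {
      warning("fewer than 3 dwells: all are edge-censored, returning empty")
      return(.dwell_set(numeric(0), numeric(0), length(dur), segment_id))
    }
    keep <- seq(2L, length(dur) - 1L)
    censored <- 2L
    states <- states[keep]
    dur <- dur[keep]
  }
  .dwell_set(dur[states == 1L], dur[states == 0L], censored, segment_id)
}

.dwell_set <- function(bound_s, unbound_s, censored_count, segments) {
  structure(list(bound_s = bound_s, unbound_s = unbound_s,
                 censored_count = as.integer(censored_count),
                 source_segments = segments),
            class = "dwell_set")
}

#' Pool dwell sets from several segments
#' @param ... `dwell_set` objects (or a single list of them).
#' @return One pooled `dwell_set`.
#' @export
pool_dwells <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "dwell_set")) {
    sets <- sets[[1L]]
  }
  stopifnot(all(vapply(sets, inherits, logical(1), "dwell_set")))
  .dwell_set(unlist(lapply(sets, `[[`, "bound_s")),
             unlist(lapply(sets, `[[`, "unbound_s")),
             sum(vapply(sets, `[[`, integer(1), "censored_count")),
             unlist(lapply(sets, `[[`, "source_segments")))
}

#' @export
print.dwell_set <- function(x, ...) {
  cat(sprintf(
    "<dwell_set> %d bound (mean %.3f s), %d unbound (mean %.3f s), %d censored dropped\n",
    length(x$bound_s), mean(x$bound_s),
    length(x$unbound_s), mean(x$unbound_s), x$censored_count))
  invisible(x)
}

#' Fit a single-exponential CDF to residence times
#'
#' The empirical CDF is evaluated at the sorted durations with plotting
#' positions `(i - 0.5)/n` and fit by unweighted nonlinear least squares to
#' `1 - exp(-x / tau)`, with `tau` initialized at the sample mean. The
#' maximum-likelihood estimate (the sample mean, for exponential data) is
#' computed alongside as a cross-check; if the least-squares fit fails to
#' converge the MLE is returned with a flag.
#'
#' @param durations Positive residence times, s.
#' @param min_events Minimum number of events required (default 5).
#' @return An `exp_fit` with `tau` (s), `r_squared`, `n_events`, `method`
#'   (`"cdf-least-squares"` or `"mle"`) and `tau_mle`.
#' @export
fit_exponential_cdf <- function(durations, min_events = 5L) {
  durations <- as.numeric(durations)
  if (length(durations) < min_events) {
    stop("need at least ", min_events, " events to fit a dwell CDF",
         call. = FALSE)
  }
  if (any(durations <= 0)) {
    stop("durations must be positive", call. = FALSE)
  }
  x <- sort(durations)
  n <- length(x)
  p <- (seq_len(n) - 0.5) / n
  tau_mle <- mean(x)
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ 1 - exp(-x / tau),
                      data = data.frame(x = x, p = p),
                      start = list(tau = tau_mle),
                      lower = .Machine$double.eps,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(tau = tau_mle, r_squared = NA_real_,
                          n_events = n, method = "mle",
                          tau_mle = tau_mle, converged = FALSE),
                     class = "exp_fit"))
  }
  tau <- as.numeric(coef(fit)[["tau"]])
  resid <- p - (1 - exp(-x / tau))
  r2 <- 1 - sum(resid^2) / sum((p - mean(p))^2)
  structure(list(tau = tau, r_squared = r2, n_events = n,
                 method = "cdf-least-squares", tau_mle = tau_mle,
                 converged = TRUE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> tau=%.4f s (MLE %.4f), R^2=%.4f, n=%d [%s]\n",
              x$tau, x$tau_mle, x$r_squared, x$n_events, x$method))
  invisible(x)
}

#' Equilibrium complex concentration under ligand depletion
#'
#' At comparable protein and ligand concentrations, complex formation
#' depletes free ligand, so `[L]free != [L]total`. Writing
#' `tau* = tau_on / tau_off`, mass balance gives the quadratic
#' `(1 + tau*) [PL]^2 - ([P]t + (1 + tau*) [L]t) [PL] + [P]t [L]t = 0`,
#' whose smaller root is the physical complex concentration
#' `0 <= [PL] <= min([P]t, [L]t)`. The root is computed with the
#' numerically stable form of the quadratic formula.
#'
#' @param P_total,L_total Total protein and ligand concentrations, uM.
#' @param tau_star Ratio of mean unbound to mean bound residence time.
#' @return `[PL]` in uM.
#' @examples
#' solve_complex_concentration(10, 20, 0.37 / 0.40)  # ~5.19 uM
#' @export
solve_complex_concentration <- function(P_total, L_total, tau_star) {
  .check_positive(P_total, "P_total")
  .check_positive(L_total, "L_total")
  .check_positive(tau_star, "tau_star")
  a <- 1 + tau_star
  b <- -(P_total + (1 + tau_star) * L_total)
  cc <- P_total * L_total
  disc <- b * b - 4 * a * cc
  if (disc < 0) {
    stop("depletion quadratic has no real root; inputs inconsistent",
         call. = FALSE)
  }
  # b < 0 always, so the stable intermediate is q = -(b - sqrt(disc))/2
  q <- -(b - sqrt(disc)) / 2
  roots <- sort(c(q / a, cc / q))
  pl <- roots[1]
  if (pl < -1e-9 || pl > min(P_total, L_total) * (1 + 1e-9)) {
    stop("no root of the depletion quadratic lies in the physical interval",
         call. = FALSE)
  }
  min(max(pl, 0), min(P_total, L_total))
}

#' Rate constants and thermodynamics from fitted dwell times
#'
#' Converts mean residence times into mass-action rate constants with the
#' ligand-depletion correction: `k_off = 1 / tau_off`,
#' `tau* = tau_on / tau_off`, `[PL]` from the mass-balance quadratic,
#' `[L]free = [L]t - [PL]`, `k_on = 1 / (tau_on * [L]free)`,
#' `K_D = tau* * [L]free` and `dG0 = R T ln(K_D)` with `K_D` expressed in
#' molar (R = 1.987e-3 kcal/(mol K)).
#'
#' @param tau_on_fit Unbound-state `exp_fit` (or a bare numeric tau, s).
#' @param tau_off_fit Bound-state `exp_fit` (or a bare numeric tau, s).
#' @param P_total,L_total Total concentrations, uM.
#' @param temperature Temperature, K (default 308.15, ~35 C in the trap).
#' @return A `kinetics_result` with `tau_on`, `tau_off`, `tau_star`,
#'   `PL`, `L_free` (uM), `k_on` (1/(s uM)), `k_off` (1/s), `K_D` (uM),
#'   `delta_G` (kcal/mol) and the inputs used.
#' @examples
#' compute_kinetics(0.37, 0.40, P_total = 10, L_total = 20)
#' @export
compute_kinetics <- function(tau_on_fit, tau_off_fit, P_total, L_total,
                             temperature = 308.15) {
  tau_on <- if (inherits(tau_on_fit, "exp_fit")) tau_on_fit$tau
            else as.numeric(tau_on_fit)
  tau_off <- if (inherits(tau_off_fit, "exp_fit")) tau_off_fit$tau
             else as.numeric(tau_off_fit)
  .check_positive(tau_on, "tau_on")
  .check_positive(tau_off, "tau_off")
  .check_positive(temperature, "temperature")
  tau_star <- tau_on / tau_off
  pl <- solve_complex_concentration(P_total, L_total, tau_star)
  l_free <- L_total - pl
  if (l_free <= 0) {
    stop("free ligand concentration is non-positive", call. = FALSE)
  }
  k_off <- 1 / tau_off
  k_on <- 1 / (tau_on * l_free)
  kd <- tau_star * l_free
  dg <- .R_KCAL * temperature * log(kd * 1e-6)  # K_D in molar
  structure(list(tau_on = tau_on, tau_off = tau_off, tau_star = tau_star,
                 P_total = P_total, L_total = L_total,
                 PL = pl, L_free = l_free,
                 k_on = k_on, k_off = k_off, K_D = kd, delta_G = dg,
                 temperature = temperature),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf(
    paste0("<kinetics_result>\n",
           "  tau_off = %.3f s   tau_on = %.3f s   tau* = %.4f\n",
           "  [PL] = %.3f uM   [L]free = %.3f uM (of %.3g uM total)\n",
           "  k_off = %.3f 1/s   k_on = %.4f 1/(s uM)\n",
           "  K_D = %.2f uM   dG0 = %.2f kcal/mol @ %.2f K\n"),
    x$tau_off, x$tau_on, x$tau_star, x$PL, x$L_free, x$L_total,
    x$k_off, x$k_on, x$K_D, x$delta_G, x$temperature))
  invisible(x)
}
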