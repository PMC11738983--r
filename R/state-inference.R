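#' Two-state Gaussian-emission HMM state inference
#'
#' Assigns each filtered sample to the bound or unbound state with a
#' two-state hidden Markov model with Gaussian emissions, trained by
#' expectation-maximization from `n_restarts` randomized initializations
#' (the best log-likelihood wins) and decoded with the most-probable-path
#' (Viterbi) algorithm, which yields the step-function fit without label
#' chatter. States are relabelled so that bound = higher emission mean.
#'
#' Restart means are drawn from the 25th/75th signal quantiles with
#' jitter; the transition matrix is initialized consistent with ~0.4 s
#' dwells at the effective sampling rate. Convergence is a relative
#' log-likelihood change below `tol` or `max_iter` iterations.
#'
#' @param segment A `filtered_trace` with >= 100 samples.
#' @param n_restarts Number of randomized EM restarts (default 20).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Integer seed controlling the restart initializations.
#' @param sigma_cap_frac Upper bound on each emission width as a fraction
#'   of the fitted level separation (default 0.15). Low-pass filtering
#'   leaves ramp samples between the two levels that a free maximum
#'   likelihood fit absorbs into one artificially broad component, biasing
#'   its mean; the cap keeps both emission widths tied to the level
#'   separation. Set to 0 to disable.
#' @return A `state_path` with 0/1 `labels` aligned to the segment,
#'   emission parameters `mu_U`, `mu_B`, `sigma_U`, `sigma_B`,
#'   `log_likelihood`, `n_restarts_used` and a `single_state` flag (raised
#'   when the fitted levels are closer than half the pooled sigma; such
#'   segments are excluded from kinetics).
#' @export
fit_two_state_hmm <- function(segment, n_restarts = 20L, tol = 1e-8,
                              max_iter = 500L, seed = 1L,
                              sigma_cap_frac = 0.15) {
  stopifnot(inherits(segment, "trap_trace"))
  y <- segment$values
  if (length(y) < 100L) {
    stop("segment must contain at least 100 samples", call. = FALSE)
  }
  fs_eff <- if (!is.null(segment$effective_fs)) segment$effective_fs
            else segment$fs
  sdy <- sd(y)
  sigma_floor <- max(1e-12, 1e-6 * sdy, 1e-6 * abs(mean(y)) * 1e-3)
  q <- quantile(y, c(0.25, 0.75), names = FALSE)
  iqr <- max(q[2] - q[1], sigma_floor)
  # stay probability consistent with ~0.4 s dwells
  p_stay <- max(0.5, 1 - 1 / (0.4 * fs_eff))
  A0 <- matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay), 2, 2, byrow = TRUE)

  set.seed(as.integer(seed))
  best <- NULL
  n_used <- 0L
  for (r in seq_len(n_restarts)) {
    jit <- if (r == 1L) c(0, 0) else runif(2, -0.25, 0.25) * iqr
    mu0 <- sort(c(q[1] + jit[1], q[2] + jit[2]))
    if (diff(mu0) < sigma_floor) mu0 <- mu0 + c(-1, 1) * iqr / 4
    s0 <- rep(max(sdy / 2, sigma_floor), 2)
    fit <- hmm_em_cpp(y, mu0, s0, A0, c(0.5, 0.5),
                      as.integer(max_iter), tol, sigma_floor,
                      sigma_cap_frac)
    n_used <- n_used + 1L
    if (!isTRUE(fit$ok)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("all HMM restarts failed to produce a finite likelihood",
         call. = FALSE)
  }
  ord <- order(best$mu)  # state 1 = unbound (low), state 2 = bound (high)
  mu <- best$mu[ord]
  sig <- best$sigma[ord]
  A <- best$A[ord, ord, drop = FALSE]
  pi <- best$pi[ord]
  vit <- hmm_viterbi_cpp(y, mu, sig, A, pi)  # 0-based in ordered states
  labels <- as.integer(vit)                  # 0 = unbound, 1 = bound
  single <- .is_single_state(y, labels, mu, sigma_floor)
  structure(list(labels = labels,
                 mu_U = mu[1], mu_B = mu[2],
                 sigma_U = sig[1], sigma_B = sig[2],
                 transition = A,
                 log_likelihood = best$loglik,
                 n_restarts_used = n_used,
                 effective_fs = fs_eff,
                 single_state = single),
            class = "state_path")
}

# Degenerate-segment detection: a segment with no real level structure
# (constant signal plus noise) must not feed dwells into the kinetics.
# Compare a two-component description (decoded levels, empirical
# within-state spreads) to a single Gaussian by BIC; also flag paths whose
# level separation is below half the pooled empirical within-state spread.
.is_single_state <- function(y, labels, mu, sigma_floor) {
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  if (n0 < 2L || n1 < 2L) return(TRUE)
  s0 <- max(sd(y[labels == 0L]), sigma_floor)
  s1 <- max(sd(y[labels == 1L]), sigma_floor)
  pooled <- sqrt((s0^2 + s1^2) / 2)
  if ((mu[2] - mu[1]) < 0.5 * pooled) return(TRUE)
  w <- n1 / length(y)
  ll2 <- sum(log((1 - w) * dnorm(y, mu[1], s0) + w * dnorm(y, mu[2], s1) +
                   1e-300))
  ll1 <- sum(dnorm(y, mean(y), max(sd(y), sigma_floor), log = TRUE))
  bic2 <- -2 * ll2 + 5 * log(length(y))
  bic1 <- -2 * ll1 + 2 * log(length(y))
  bic1 <= bic2
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf(
    "<state_path> %d samples @ %g Hz | mu_U=%.5f mu_B=%.5f | logL=%.1f%s\n",
    length(x$labels), x$effective_fs, x$mu_U, x$mu_B, x$log_likelihood,
    if (isTRUE(x$single_state)) " [single state]" else ""))
  invisible(x)
}

#' Remove noise-induced spurious state transitions
#'
#' Scans the decoded state path left to right and examines every dwell of
#' duration at most `min_dwell_s` (0.05 s by default, inclusive). The mean
#' filtered-signal value over the dwell is compared to the midpoint
#' `m = (mu_B + mu_U) / 2` between the two levels; if it deviates from the
#' midpoint by less than `midpoint_frac` of the level separation
#' `mu_B - mu_U` (default 10%), the excursion is judged noise and the
#' dwell's labels are reverted to the preceding dwell's state, merging
#' three dwells into one. Passes repeat until a fixpoint or `max_passes`.
#' Total labelled duration is conserved exactly and no new transition is
#' ever created.
#'
#' A candidate first dwell (which has no predecessor) is reverted to the
#' following dwell's state. With `midpoint_mode = "absolute"` the deviation
#' is instead measured against `midpoint_frac` of the midpoint's absolute
#' value, an alternative reading of the rule that ties it to the baseline
#' offset.
#'
#' @param path A `state_path`.
#' @param segment The `filtered_trace` the path was fitted to.
#' @param min_dwell_s Duration threshold, s (>= one sample period).
#' @param midpoint_frac Deviation threshold as a fraction (default 0.10).
#' @param max_passes Maximum correction sweeps.
#' @param midpoint_mode `"separation"` (default) or `"absolute"`.
#' @return The corrected `state_path` (also records `n_reverted`).
#' @export
correct_spurious_transitions <- function(path, segment,
                                         min_dwell_s = 0.05,
                                         midpoint_frac = 0.10,
                                         max_passes = 10L,
                                         midpoint_mode = c("separation",
                                                           "absolute")) {
  midpoint_mode <- match.arg(midpoint_mode)
  stopifnot(inherits(path, "state_path"), inherits(segment, "trap_trace"))
  y <- segment$values
  if (length(y) != length(path$labels)) {
    stop("path and segment are not aligned", call. = FALSE)
  }
  fs <- path$effective_fs
  if (min_dwell_s < 1 / fs) {
    stop("`min_dwell_s` must be at least one sample period", call. = FALSE)
  }
  labels <- path$labels
  m <- (path$mu_B + path$mu_U) / 2
  sep <- path$mu_B - path$mu_U
  thr_dev <- if (midpoint_mode == "separation") midpoint_frac * sep
             else midpoint_frac * abs(m)
  n_reverted <- 0L

  for (pass in seq_len(max_passes)) {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) break
    changed <- FALSE
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      dur <- r$lengths[i] / fs
      if (dur > min_dwell_s) next
      seg_mean <- mean(y[starts[i]:ends[i]])
      if (abs(seg_mean - m) < thr_dev) {
        target <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
        if (r$values[i] != target) {
          labels[starts[i]:ends[i]] <- target
          n_reverted <- n_reverted + 1L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  path$labels <- labels
  path$n_reverted <- n_reverted
  path
}
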