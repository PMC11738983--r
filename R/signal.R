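#' Zero-phase low-pass filter and decimation of a trapping trace
#'
#' Conditions a raw transmission trace the way the kinetics analysis
#' expects: a 4th-order Butterworth low-pass applied forward and backward
#' (zero phase, so dwell boundaries are not displaced; unit gain at DC),
#' followed by decimation to `decimate_to_hz`. Because the cutoff sits
#' orders of magnitude below a 100 kHz Nyquist frequency, the filter is
#' staged for numerical stability: an exact block-average pre-decimation to
#' roughly twenty times the output rate, the Butterworth pass there, then
#' integer subsampling. The block average has unit DC gain and a delay of
#' half an intermediate sample, far below one output sample period.
#'
#' Ground-truth labels, when present, are carried through by sampling the
#' label at each output sample time.
#'
#' @param trace A `trap_trace`.
#' @param cutoff_hz Low-pass cutoff, Hz (default 3, must be < `fs/2`).
#' @param decimate_to_hz Output sampling rate, Hz (>= `2 * cutoff_hz`);
#'   `NULL` keeps the input rate.
#' @return A `filtered_trace` (also a `trap_trace`) with `cutoff_hz` and
#'   `effective_fs` fields.
#' @export
lowpass_filter <- function(trace, cutoff_hz = 3, decimate_to_hz = 100) {
  stopifnot(inherits(trace, "trap_trace"))
  .check_positive(cutoff_hz, "cutoff_hz")
  if (cutoff_hz >= trace$fs / 2) {
    stop("`cutoff_hz` must be below the Nyquist frequency fs/2",
         call. = FALSE)
  }
  if (is.null(decimate_to_hz)) decimate_to_hz <- trace$fs
  if (decimate_to_hz < 2 * cutoff_hz) {
    stop("`decimate_to_hz` must be at least 2 * cutoff_hz", call. = FALSE)
  }
  x <- trace$values
  fs <- trace$fs
  n <- length(x)

  # stage 1: exact block-average pre-decimation towards ~20x the output rate
  fac1 <- max(1L, floor(fs / (20 * decimate_to_hz)))
  if (fac1 > 1L) {
    n1 <- floor(n / fac1)
    x <- colMeans(matrix(x[seq_len(n1 * fac1)], nrow = fac1))
    fs1 <- fs / fac1
  } else {
    fs1 <- fs
  }

  # stage 2: zero-phase Butterworth at the intermediate rate
  if (cutoff_hz < fs1 / 2) {
    x <- .zerophase_lowpass(x, fs1, cutoff_hz)
  }

  # stage 3: integer subsampling to the output rate
  fac2 <- max(1L, round(fs1 / decimate_to_hz))
  if (fac2 > 1L) {
    keep <- seq.int(1L, length(x), by = fac2)
    x <- x[keep]
  }
  eff_fs <- fs1 / fac2

  true_state <- NULL
  if (!is.null(trace$true_state)) {
    idx <- pmin(n, pmax(1L, round((seq_along(x) - 0.5) * fs / eff_fs)))
    true_state <- trace$true_state[idx]
  }
  out <- trap_trace(x, fs = trace$fs, t0 = trace$t0,
                    metadata = trace$metadata, true_state = true_state)
  out$cutoff_hz <- cutoff_hz
  out$effective_fs <- eff_fs
  class(out) <- c("filtered_trace", class(out))
  out
}

# 4th-order Butterworth low-pass as two cascaded biquads (second-order
# sections; numerically stable at cutoffs far below Nyquist, where the
# direct-form polynomial is ill-conditioned), applied forward-backward for
# zero phase, with odd-extension padding to suppress start-up transients.
.butter_sos <- function(cutoff_hz, fs) {
  K <- tan(pi * cutoff_hz / fs)
  lapply(c(cos(pi / 8), cos(3 * pi / 8)), function(zeta) {
    norm <- 1 / (1 + 2 * zeta * K + K * K)
    list(b = c(K * K, 2 * K * K, K * K) * norm,
         a = c(1, 2 * (K * K - 1) * norm, (1 - 2 * zeta * K + K * K) * norm))
  })
}

.sos_filter <- function(sos, x) {
  for (sec in sos) {
    x <- as.numeric(signal::filter(sec$b, sec$a, x))
  }
  x
}

.zerophase_lowpass <- function(x, fs, cutoff_hz) {
  n <- length(x)
  sos <- .butter_sos(cutoff_hz, fs)
  # the slowest pole pair decays at ~7.2/s per pass for a 3 Hz cutoff;
  # 10 time constants of padding make the edge transient negligible
  pad <- min(n - 1L, ceiling(10 * fs / cutoff_hz))
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- c(left, x, right)
  y <- .sos_filter(sos, y)           # forward
  y <- rev(.sos_filter(sos, rev(y))) # backward
  y[(pad + 1L):(pad + n)]
}

#' Split a filtered trace into consecutive analysis segments
#'
#' Long traces are processed in ~30 s sections. Segments are
#' non-overlapping and consecutive; a final remainder shorter than
#' `min_remainder_s` is dropped (too short for reliable dwell-CDF
#' fitting), otherwise kept as a shorter segment.
#'
#' @param trace A `filtered_trace`.
#' @param segment_s Segment length, s (default 30).
#' @param min_remainder_s Minimum length of a kept trailing remainder, s.
#' @return A list of `filtered_trace` segments. A trace shorter than
#'   `min_remainder_s` is passed through as a single segment with a warning.
#' @export
segment_trace <- function(trace, segment_s = 30, min_remainder_s = 10) {
  stopifnot(inherits(trace, "filtered_trace"))
  .check_positive(segment_s, "segment_s")
  fs <- trace$effective_fs
  n <- length(trace$values)
  dur <- n / fs
  if (dur < min_remainder_s) {
    warning("trace shorter than ", min_remainder_s,
            " s: returned as a single segment")
    return(list(trace))
  }
  per <- floor(segment_s * fs)
  starts <- seq.int(1L, n, by = per)
  segs <- lapply(starts, function(s) {
    e <- min(n, s + per - 1L)
    sub <- trace
    sub$values <- trace$values[s:e]
    sub$true_state <- if (is.null(trace$true_state)) NULL
                      else trace$true_state[s:e]
    sub$t0 <- trace$t0 + (s - 1L) / fs
    sub
  })
  keep <- vapply(segs, function(s) length(s$values) / fs >= min_remainder_s,
                 logical(1))
  segs[keep]
}

#' Fit a two-Gaussian mixture to the filtered-signal PDF
#'
#' Least-squares fit of the sum of two Gaussian components to the density
#' histogram of the filtered values (Freedman-Diaconis binning). The
#' component with the higher mean is labelled bound: complex formation
#' increases scattering and therefore the transmission level. Component
#' areas integrate the fitted densities, so they sum to ~1 on a converged
#' fit.
#'
#' @param trace A `filtered_trace` (or any `trap_trace`) with >= 1000
#'   samples.
#' @param n_restarts Number of jittered restarts of the nonlinear fit.
#' @param seed Integer seed for the restart jitter (the fit is
#'   deterministic given the trace and seed).
#' @return A `mixture_fit` with `A_B`, `A_U` (areas), `mu_B`, `mu_U`,
#'   `sigma_B`, `sigma_U`, `converged` and `single_state` flags. Components
#'   whose means are closer than one pooled sigma raise the
#'   `single_state` flag; non-convergence is flagged, not thrown.
#' @export
fit_two_gaussian_pdf <- function(trace, n_restarts = 10L, seed = 1L) {
  stopifnot(inherits(trace, "trap_trace"))
  set.seed(as.integer(seed))
  x <- trace$values
  if (length(x) < 1000L) {
    stop("need at least 1000 samples for a PDF fit", call. = FALSE)
  }
  # Freedman-Diaconis bin width
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (bw <= 0) bw <- diff(range(x)) / 50
  if (bw <= 0) {
    return(.mixture_fit(NA, NA, mean(x), mean(x), NA, NA,
                        converged = FALSE, single_state = TRUE))
  }
  breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, dens = h$density)

  km <- suppressWarnings(kmeans(x, centers = 2, nstart = 3))
  ord <- order(km$centers)
  mu0 <- as.numeric(km$centers[ord])
  w0 <- as.numeric(table(factor(km$cluster, levels = ord)) / length(x))
  s0 <- vapply(ord, function(k) {
    v <- sd(x[km$cluster == k])
    if (!is.finite(v) || v <= 0) bw else v
  }, numeric(1))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    jit <- if (r == 1L) c(0, 0) else rnorm(2, 0, 0.2)
    start <- list(aU = w0[1], aB = w0[2],
                  muU = mu0[1] + jit[1] * s0[1],
                  muB = mu0[2] + jit[2] * s0[2],
                  sU = s0[1], sB = s0[2])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        dens ~ aU * dnorm(mid, muU, sU) + aB * dnorm(mid, muB, sB),
        data = df, start = start,
        lower = c(0, 0, min(x), min(x), bw / 10, bw / 10),
        upper = c(2, 2, max(x), max(x), diff(range(x)), diff(range(x))),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(.mixture_fit(w0[2], w0[1], mu0[2], mu0[1], s0[2], s0[1],
                        converged = FALSE, single_state = FALSE))
  }
  p <- as.list(coef(best$fit))
  # label by mean: higher mean = bound
  if (p$muB < p$muU) {
    p <- list(aU = p$aB, aB = p$aU, muU = p$muB, muB = p$muU,
              sU = p$sB, sB = p$sU)
  }
  pooled <- sqrt((p$sU^2 + p$sB^2) / 2)
  .mixture_fit(p$aB, p$aU, p$muB, p$muU, p$sB, p$sU,
               converged = TRUE,
               single_state = abs(p$muB - p$muU) < pooled)
}

.mixture_fit <- function(A_B, A_U, mu_B, mu_U, sigma_B, sigma_U,
                         converged, single_state) {
  structure(list(A_B = A_B, A_U = A_U, mu_B = mu_B, mu_U = mu_U,
                 sigma_B = sigma_B, sigma_U = sigma_U,
                 converged = converged, single_state = single_state),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> bound: A=%.3f mu=%.5f sd=%.5f | unbound: A=%.3f mu=%.5f sd=%.5f%s%s\n",
    x$A_B, x$mu_B, x$sigma_B, x$A_U, x$mu_U, x$sigma_U,
    if (isTRUE(x$converged)) "" else " [not converged]",
    if (isTRUE(x$single_state)) " [single state]" else ""))
  invisible(x)
}

#' Bound transmission level normalized to the unbound level
#'
#' Returns `100 * mu_B / mu_U` in percent, the level contrast the
#' two-Gaussian PDF fit reports for a trapped protein toggling between the
#' ligand-free and ligand-bound conformation.
#'
#' @param fit A converged two-state `mixture_fit`.
#' @return Percent (numeric scalar).
#' @export
normalized_bound_intensity <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!isTRUE(fit$converged)) {
    stop("mixture fit did not converge", call. = FALSE)
  }
  if (isTRUE(fit$single_state)) {
    stop("single-state fit: no distinct bound level", call. = FALSE)
  }
  if (!is.finite(fit$mu_U) || fit$mu_U <= 0) {
    stop("unbound level must be positive", call. = FALSE)
  }
  100 * fit$mu_B / fit$mu_U
}
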