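#' Write a trapping trace to CSV
#'
#' The dialect is plain CSV with `#`-prefixed header comment lines
#' carrying acquisition metadata (`# fs_hz`, `# P_total_uM`,
#' `# L_total_uM`, `# temperature_K`, `# seed`) followed by columns
#' `time_s,transmission_V[,true_state]`.
#'
#' @param trace A `trap_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trap_trace"))
  md <- trace$metadata
  hdr <- c(sprintf("# fs_hz %.10g", trace$fs))
  for (key in c("P_total", "L_total", "temperature", "seed")) {
    if (!is.null(md[[key]])) {
      name <- switch(key, P_total = "P_total_uM", L_total = "L_total_uM",
                     temperature = "temperature_K", seed = "seed")
      hdr <- c(hdr, sprintf("# %s %.10g", name, md[[key]]))
    }
  }
  t <- trace$t0 + (seq_along(trace$values) - 1) / trace$fs
  df <- data.frame(time_s = t, transmission_V = trace$values)
  if (!is.null(trace$true_state)) df$true_state <- trace$true_state
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trapping trace from CSV
#'
#' Parses the dialect written by [write_trace()]. The `# fs_hz` header is
#' mandatory; concentration and temperature headers populate the metadata
#' when present (the kinetics stage errors with guidance when they are
#' missing). The time column must be monotonically increasing.
#'
#' @param path CSV file path.
#' @return A `trap_trace`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    parts <- strsplit(sub("^#\\s*", "", h), "\\s+")[[1L]]
    if (length(parts) >= 2L) meta[[parts[1L]]] <- as.numeric(parts[2L])
  }
  if (is.null(meta$fs_hz) || !is.finite(meta$fs_hz)) {
    stop("trace format error: missing `# fs_hz` header line", call. = FALSE)
  }
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "transmission_V") %in% names(df))) {
    stop("trace format error: need columns time_s and transmission_V",
         call. = FALSE)
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("trace format error: time column must be strictly increasing",
         call. = FALSE)
  }
  trap_trace(df$transmission_V, fs = meta$fs_hz,
             t0 = df$time_s[1L],
             metadata = list(P_total = meta$P_total_uM,
                             L_total = meta$L_total_uM,
                             temperature = meta$temperature_K,
                             seed = meta$seed),
             true_state = if ("true_state" %in% names(df)) df$true_state
                          else NULL)
}

#' Run the full single-molecule kinetics analysis on one trace
#'
#' Executes the stages in order: zero-phase low-pass filter (with
#' decimation), ~30 s segmentation, two-state HMM fit with restarts per
#' segment, spurious-transition correction, edge-censored dwell
#' extraction pooled across segments, single-exponential CDF fits of the
#' bound and unbound residence times, and depletion-corrected rate
#' constants. A two-Gaussian PDF fit of the pooled filtered signal is run
#' alongside for the level-contrast diagnostic. Deterministic given the
#' trace and config.
#'
#' @param trace A `trap_trace` whose metadata (or the arguments below)
#'   supply `P_total` and `L_total` in uM.
#' @param cutoff_hz,decimate_to_hz,segment_s Signal-conditioning
#'   parameters (defaults 3 Hz, 100 Hz, 30 s).
#' @param n_restarts HMM restarts per segment (default 20).
#' @param min_dwell_s,midpoint_frac Spurious-transition correction rule
#'   (defaults 0.05 s and 10% of the level separation).
#' @param sigma_cap_frac Emission-width cap passed to
#'   [fit_two_state_hmm()].
#' @param P_total,L_total,temperature Override the trace metadata.
#' @param seed Base seed for the HMM restarts (per-segment seeds are
#'   `seed + segment index`).
#' @return An `analysis_report` list: `config`, per-segment summaries,
#'   `mixture_fit`, pooled `dwells`, `fit_on`, `fit_off`, `kinetics`.
#' @export
run_analysis <- function(trace, cutoff_hz = 3, decimate_to_hz = 100,
                         segment_s = 30, n_restarts = 20L,
                         min_dwell_s = 0.05, midpoint_frac = 0.10,
                         sigma_cap_frac = 0.15,
                         P_total = NULL, L_total = NULL,
                         temperature = NULL, seed = 1L) {
  stopifnot(inherits(trace, "trap_trace"))
  md <- trace$metadata
  P_total <- if (!is.null(P_total)) P_total else md$P_total
  L_total <- if (!is.null(L_total)) L_total else md$L_total
  temperature <- if (!is.null(temperature)) temperature
                 else if (!is.null(md$temperature)) md$temperature
                 else 308.15
  if (is.null(P_total) || is.null(L_total) ||
      !is.finite(P_total) || !is.finite(L_total)) {
    stop("configuration error: total protein and ligand concentrations ",
         "(uM) are required; supply `P_total`/`L_total` or trace metadata",
         call. = FALSE)
  }

  filtered <- lowpass_filter(trace, cutoff_hz = cutoff_hz,
                             decimate_to_hz = decimate_to_hz)
  segments <- segment_trace(filtered, segment_s = segment_s)
  mix <- fit_two_gaussian_pdf(filtered)

  seg_summaries <- list()
  dwell_sets <- list()
  for (i in seq_along(segments)) {
    path <- fit_two_state_hmm(segments[[i]], n_restarts = n_restarts,
                              seed = seed + i,
                              sigma_cap_frac = sigma_cap_frac)
    if (isTRUE(path$single_state)) {
      seg_summaries[[i]] <- list(index = i, single_state = TRUE)
      next
    }
    path <- correct_spurious_transitions(path, segments[[i]],
                                         min_dwell_s = min_dwell_s,
                                         midpoint_frac = midpoint_frac)
    dw <- extract_dwells(path, segment_id = paste0("seg", i))
    dwell_sets[[length(dwell_sets) + 1L]] <- dw
    seg_summaries[[i]] <- list(
      index = i, single_state = FALSE,
      mu_U = path$mu_U, mu_B = path$mu_B,
      sigma_U = path$sigma_U, sigma_B = path$sigma_B,
      log_likelihood = path$log_likelihood,
      n_reverted = path$n_reverted,
      n_bound = length(dw$bound_s), n_unbound = length(dw$unbound_s))
  }
  if (length(dwell_sets) == 0L) {
    stop("fit failure: no segment produced a usable two-state path",
         call. = FALSE)
  }
  dwells <- pool_dwells(dwell_sets)
  fit_off <- fit_exponential_cdf(dwells$bound_s)
  fit_on <- fit_exponential_cdf(dwells$unbound_s)
  kin <- compute_kinetics(fit_on, fit_off, P_total = P_total,
                          L_total = L_total, temperature = temperature)
  structure(list(
    config = list(cutoff_hz = cutoff_hz, decimate_to_hz = decimate_to_hz,
                  segment_s = segment_s, n_restarts = n_restarts,
                  min_dwell_s = min_dwell_s, midpoint_frac = midpoint_frac,
                  P_total = P_total, L_total = L_total,
                  temperature = temperature, seed = seed,
                  version = as.character(utils::packageVersion("trapkin"))),
    n_segments = length(segments),
    segments = seg_summaries,
    mixture_fit = mix,
    dwells = dwells,
    fit_on = fit_on,
    fit_off = fit_off,
    kinetics = kin), class = "analysis_report")
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to file).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  strip <- function(v) {
    if (is.list(v)) lapply(unclass(v), strip) else unclass(v)
  }
  x <- strip(report)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d segment(s)\n", x$n_segments))
  print(x$mixture_fit)
  print(x$dwells)
  cat(sprintf("  unbound: "))
  print(x$fit_on)
  cat(sprintf("  bound:   "))
  print(x$fit_off)
  print(x$kinetics)
  invisible(x)
}
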