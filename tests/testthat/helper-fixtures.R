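# shared fixtures built in code; no stored data

# telegraph trace at the study kinetics (bound dwell 1/2.52 s, unbound
# 0.37 s, 1% contrast, state-dependent noise); fs defaults to 10 kHz to
# keep the suite fast -- the noise bandwidth ratio at the 3 Hz filter is
# already >3 orders of magnitude there
make_study_trace <- function(duration_s = 40, fs = 1e4, seed = 1L,
                             k_off = 2.52, k_on_eff = 1 / 0.37) {
  cfg <- sim_config(k_off = k_off, fs = fs, duration_s = duration_s,
                    seed = seed)
  ev <- simulate_event_sequence(k_off, k_on_eff, duration_s = duration_s,
                                seed = seed)
  render_trace(ev, cfg)
}

# wrap a plain numeric vector as an already-filtered trace
make_filtered <- function(values, fs = 100, true_state = NULL) {
  tr <- trap_trace(values, fs = fs, true_state = true_state)
  tr$effective_fs <- fs
  tr$cutoff_hz <- 3
  class(tr) <- c("filtered_trace", class(tr))
  tr
}

# state path with known levels, for exercising the correction rule
make_state_path <- function(labels, mu_U = 1.0, mu_B = 1.01, fs = 100) {
  structure(list(labels = as.integer(labels), mu_U = mu_U, mu_B = mu_B,
                 sigma_U = 1e-3, sigma_B = 1e-3, effective_fs = fs,
                 log_likelihood = 0, single_state = FALSE),
            class = "state_path")
}

n_transitions <- function(labels) sum(diff(labels) != 0)
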