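# trapkin

Single-molecule binding kinetics from nanoaperture optical-trap
transmission traces.

A protein held in a nanoaperture optical trap (e.g. a double-nanohole
aperture in a gold film) modulates the transmitted light in proportion to
its polarizability. When a small-molecule ligand binds and the protein
changes conformation, the photodetector voltage toggles between two levels
~1% apart: a label-free, single-molecule readout of reversible 1:1 binding

    P + L  <==[k_on / k_off]==>  PL

that works in the micromolar-affinity regime where fluorescence-based
single-molecule methods are blinded by background. `trapkin` is for
biophysicists who have such traces (or want to simulate them) and need
rate constants out the other end. It implements the complete analysis
chain:

- **Signal conditioning** — zero-phase 3 Hz Butterworth low-pass with
  decimation (`lowpass_filter()`), ~30 s segmentation (`segment_trace()`),
  and a two-Gaussian fit of the filtered-signal PDF
  (`fit_two_gaussian_pdf()`, `normalized_bound_intensity()`).
- **State inference** — two-state Gaussian-emission HMM trained by EM with
  20 randomized restarts, Viterbi decoding (`fit_two_state_hmm()`), and a
  duration/midpoint spurious-transition correction
  (`correct_spurious_transitions()`): dwells ≤ 0.05 s whose mean sits
  within 10% of the level midpoint are reverted as noise.
- **Kinetics** — residence-time extraction with edge censoring
  (`extract_dwells()`), single-exponential CDF fits of
  `1 − exp(−x/τ)` (`fit_exponential_cdf()`), and rate constants with an
  explicit ligand-depletion correction: the free-ligand concentration
  comes from the mass-balance quadratic rather than the
  `[L]free ≈ [L]total` approximation (`solve_complex_concentration()`,
  `compute_kinetics()`), giving `k_on`, `k_off`, `K_D = τ*·[L]free` and
  `ΔG° = RT ln K_D`.
- **Ensemble assays** — one-site fluorescence-polarization fits
  (`polarization()`, `fit_one_site_fp()`), melt-curve Tm extraction from
  the derivative of the I350/I330 ratio (`melt_tm()`), and two-point CPMG
  transverse relaxation rates (`cpmg_r2()`).
- **Synthetic data** — a telegraph-signal generator with exponential
  dwells, state-dependent Gaussian noise and optional drift
  (`simulate_event_sequence()`, `render_trace()`, `sim_config()`), plus
  FP/melt/CPMG generators, so the whole chain is testable against known
  ground truth.

## Worked example

Rate constants from measured mean dwell times (0.37 s unbound, 0.40 s
bound) at 10 µM protein and 20 µM ligand:

```r
library(trapkin)
compute_kinetics(0.37, 0.40, P_total = 10, L_total = 20)
#> <kinetics_result>
#>   tau_off = 0.400 s   tau_on = 0.370 s   tau* = 0.9250
#>   [PL] = 5.195 uM   [L]free = 14.805 uM (of 20 uM total)
#>   k_off = 2.500 1/s   k_on = 0.1826 1/(s uM)
#>   K_D = 13.69 uM   dG0 = -6.86 kcal/mol @ 308.15 K
```

The depletion quadratic puts 5.2 µM of the 20 µM ligand into complex, so
the free-ligand concentration is 14.8 µM — a quarter below the total, which
is exactly the error the correction removes from `k_on` and `K_D`.

End to end on a synthetic trace generated at those kinetics (1% level
contrast, state noise 0.002/0.004 V):

```r
cfg <- sim_config(k_off = 2.52, fs = 1e4, duration_s = 120, seed = 23)
ev  <- simulate_event_sequence(2.52, 1 / 0.37, duration_s = 120, seed = 23)
tr  <- render_trace(ev, cfg)
run_analysis(tr, seed = 1)
#> <analysis_report> 4 segment(s)
#> <mixture_fit> bound: A=0.401 mu=1.01008 sd=0.00051 | unbound: A=0.310 mu=0.99983 sd=0.00053
#> <dwell_set> 102 bound (mean 0.594 s), 103 unbound (mean 0.532 s), 8 censored dropped
#>   unbound: <exp_fit> tau=0.5926 s (MLE 0.5317), R^2=0.9118, n=103 [cdf-least-squares]
#>   bound:   <exp_fit> tau=0.6169 s (MLE 0.5944), R^2=0.9306, n=102 [cdf-least-squares]
#> <kinetics_result>
#>   tau_off = 0.617 s   tau_on = 0.593 s   tau* = 0.9605
#>   [PL] = 5.101 uM   [L]free = 14.899 uM (of 20 uM total)
#>   k_off = 1.621 1/s   k_on = 0.1133 1/(s uM)
#>   K_D = 14.31 uM   dG0 = -6.83 kcal/mol @ 308.15 K
```

Both fitted dwell means are inflated relative to the generator truth (the
3 Hz filter merges sub-0.1 s events into their neighbors), but the
inflation largely cancels in the ratio τ\* = τ_on/τ_off, so `K_D` comes
back within ~5% here (14.3 vs 13.7 µM) even though the individual rate
constants do not. The level contrast diagnostic recovers the configured
101.0% from the mixture-fit means. See the methods vignette
(`vignettes/trapkin-methods.Rmd`) for the model, the numerical choices and
the limitations of the synthetic signal model.

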