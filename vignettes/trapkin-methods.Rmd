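---
title: "Methods: single-molecule binding kinetics from optical-trap transmission traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule binding kinetics from optical-trap transmission traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapkin)
```

## The measurement and the model

A protein held in a nanoaperture optical trap modulates the light
transmitted through the aperture in proportion to its polarizability. When
a small-molecule ligand binds and the protein changes conformation (here:
elongation of a HEAT-repeat scaffold on activator binding), the scattering
level shifts by a small amount — on the order of 1% of the baseline — and
the photodetector voltage toggles between two closely spaced levels. The
trace is therefore a two-level telegraph process observed in noise, and
reversible 1:1 binding

$$\mathrm{P} + \mathrm{L}
  \underset{k_{\mathrm{off}}}{\overset{k_{\mathrm{on}}}{\rightleftharpoons}}
  \mathrm{PL}$$

makes the residence (dwell) times in each level independent exponentials:
the bound state empties at rate $k_{\mathrm{off}} = 1/\tau_{\mathrm{off}}$
and the unbound state at the pseudo-first-order rate
$k_{\mathrm{on}}[\mathrm{L}]_{\mathrm{free}} = 1/\tau_{\mathrm{on}}$.

Because the experiment runs at comparable protein and ligand
concentrations (tens of micromolar), complex formation depletes free
ligand and $[\mathrm{L}]_{\mathrm{free}} \neq [\mathrm{L}]_t$. Writing
$\tau^* = \tau_{\mathrm{on}}/\tau_{\mathrm{off}}$, mass balance gives the
quadratic

$$(1+\tau^*)[\mathrm{PL}]^2
  - \bigl([\mathrm{P}]_t + (1+\tau^*)[\mathrm{L}]_t\bigr)[\mathrm{PL}]
  + [\mathrm{P}]_t[\mathrm{L}]_t = 0,$$

whose smaller root is the physical complex concentration. From it,

$$[\mathrm{L}]_{\mathrm{free}} = [\mathrm{L}]_t - [\mathrm{PL}], \qquad
  k_{\mathrm{on}} = \frac{1}{\tau_{\mathrm{on}}[\mathrm{L}]_{\mathrm{free}}}, \qquad
  K_D = \tau^*\,[\mathrm{L}]_{\mathrm{free}}, \qquad
  \Delta G^\circ = RT\ln K_D,$$

with $K_D$ expressed in molar inside the logarithm and
$R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$.
`solve_complex_concentration()` evaluates the root with the numerically
stable form of the quadratic formula (no subtraction of nearly equal
quantities), and `compute_kinetics()` assembles the constants. The
identity $K_D = k_{\mathrm{off}}/k_{\mathrm{on}}$ then holds by
construction and is asserted in the tests.

With the study inputs — $\tau_{\mathrm{on}} = 0.37$ s,
$\tau_{\mathrm{off}} = 0.40$ s, $[\mathrm{P}]_t = 10\ \mu M$,
$[\mathrm{L}]_t = 20\ \mu M$ — the chain gives
$[\mathrm{PL}] \approx 5.19\ \mu M$,
$[\mathrm{L}]_{\mathrm{free}} \approx 14.8\ \mu M$ and
$K_D \approx 13.7\ \mu M$:

```{r}
compute_kinetics(0.37, 0.40, P_total = 10, L_total = 20)
```

## Signal conditioning

**Low-pass filter.** `lowpass_filter()` applies a 3 Hz (default) 4th-order
Butterworth low-pass forward and backward, so the magnitude response is
applied twice and the phase is exactly zero — dwell boundaries are not
displaced, which matters because dwell durations are the measurand. Two
numerical choices sit behind the clean contract:

* *Staging.* A 3 Hz corner at a 100 kHz sampling rate puts the normalized
  cutoff at $6\times10^{-5}$, where a direct-form IIR filter is unusable
  in double precision. The filter therefore runs in stages: an exact
  block-average pre-decimation to roughly 20 times the output rate
  (unit DC gain; delay of half an intermediate sample, far below one
  output sample), the Butterworth pass at that intermediate rate
  implemented as two cascaded second-order sections (the numerically
  well-conditioned biquad form), and integer subsampling to the output
  rate.
* *Edge padding.* Forward–backward filtering with zero initial conditions
  leaves settling transients at both ends. The signal is extended by odd
  reflection over ten time constants of the slowest pole pair before
  filtering and trimmed afterwards; the residual DC error is below
  $10^{-6}$ of the signal level (asserted in the tests).

The default output rate of 100 Hz keeps the 0.05 s spurious-transition
threshold at an integer five samples and reduces the strong sample-to-sample
correlation a 3 Hz-filtered 100 kHz record would have.

**Segmentation.** Long traces are processed in 30 s sections
(`segment_trace()`). A trailing remainder shorter than 10 s is dropped:
segments much shorter than that contain too few dwells for a stable CDF
fit.

**Level diagnostics.** `fit_two_gaussian_pdf()` fits the sum of two
Gaussians to the density histogram of the filtered values
(Freedman–Diaconis binning, Levenberg–Marquardt least squares with
jittered restarts) and labels the higher-mean component as bound, since
complex formation increases scattering. `normalized_bound_intensity()`
reports $100\,\mu_B/\mu_U$, the percent level contrast.

## State inference

`fit_two_state_hmm()` fits a two-state hidden Markov model with Gaussian
emissions by expectation–maximization (Baum–Welch, scaled forward–backward
in compiled code), using 20 randomized restarts by default and keeping the
best log-likelihood. Restart means are drawn from the 25th/75th signal
quantiles with jitter; the transition matrix is initialized consistent
with ~0.4 s dwells at the effective rate. Decoding uses the
most-probable-path (Viterbi) algorithm rather than per-sample posteriors,
which produces a clean step function without label chatter.

One guard deserves explanation. After low-pass filtering, the samples
recorded *during* a level transition lie between the two levels; they are
not drawn from either state's Gaussian. An unconstrained maximum
likelihood fit responds by inflating one component's width until it
swallows this ramp mass, which drags that component's mean toward the
middle and biases the decoding boundary — and therefore the dwell-time
ratio. `fit_two_state_hmm()` caps each emission width at a fraction
(`sigma_cap_frac`, default 0.15) of the fitted level separation, which
pins both components to their plateaus. The cap can be disabled for data
without filter ramps.

Degenerate segments (a single level plus noise) are detected by comparing
a two-component description of the decoded samples against a single
Gaussian by BIC, plus a minimum-separation rule; flagged segments are
excluded from kinetics rather than contributing meaningless dwells.

**Spurious-transition correction.** `correct_spurious_transitions()`
implements the duration/midpoint rule: every dwell no longer than 0.05 s
(inclusive) is a candidate; if the mean filtered value over the dwell
deviates from the midpoint between the two levels by less than 10% of the
level separation, the dwell is judged a noise excursion and reverted to
the preceding dwell's state, merging three dwells into one. Sweeps repeat
to a fixpoint (at most `max_passes`). The rule conserves total labelled
duration exactly and can only remove transitions. Two readings of "10%"
are possible — relative to the level separation or to the absolute
midpoint voltage; the package defaults to the separation reading, because
a rule keyed to the absolute voltage would change behavior under an
arbitrary baseline offset, and exposes `midpoint_mode = "absolute"` for
the alternative. A candidate *first* dwell has no predecessor and is
reverted to the following dwell's state.

## Dwell statistics and rate constants

`extract_dwells()` run-length encodes the corrected labels. The first and
last dwell of each segment are censored (their start or end was not
observed) and are dropped by default rather than survival-corrected; at
roughly a hundred events per segment the two censored dwells are a
negligible fraction, and dropping them avoids importing a censoring model
the measurement does not need.

`fit_exponential_cdf()` builds the empirical CDF at the sorted durations
with plotting positions $(i-0.5)/n$ and fits $1-\exp(-x/\tau)$ by
unweighted nonlinear least squares, $\tau$ initialized at the sample mean.
The maximum-likelihood estimate of an exponential mean is the sample mean
itself, so the MLE is carried alongside as an independent cross-check
(`tau_mle`); the tests require the two routes to agree within 5% on
exponential data of a few hundred events. If the least-squares step fails,
the MLE is returned with a flag.

`run_analysis()` composes the stages — filter, segment, HMM, correction,
dwell pooling across segments of a trapping event, CDF fits, kinetics —
deterministically given the trace and seed, and serializes a full
provenance block (every tunable plus seeds and package version) with the
result. This package is a library: its exported functions and this
document are the interface, and `scripts/acceptance.R` in the repository
shows the full pipeline driven non-interactively.

## The synthetic-data generator

`simulate_event_sequence()` realizes the continuous-time two-state chain:
alternating exponential dwells with bound-exit rate $k_{\mathrm{off}}$ and
unbound-exit rate $k_{\mathrm{on}}[\mathrm{L}]_{\mathrm{free}}$, the final
dwell truncated at the requested duration and flagged censored.
`render_trace()` samples it at the acquisition rate and adds the signal
model; `sim_config()` holds the defaults, which are the study conditions
throughout:

| parameter | default | why |
|---|---|---|
| bound dwell mean | 0.40 s ($k_{\mathrm{off}} = 2.5\ \mathrm{s}^{-1}$) | measured bound residence time |
| unbound dwell mean | 0.37 s | measured unbound residence time at 20 µM ligand |
| $[\mathrm{P}]_t$, $[\mathrm{L}]_t$ | 10, 20 µM | experiment concentrations |
| baseline $\mu_U$ | 1.0 V | arbitrary detector scale; no absolute voltage is defined by the measurement |
| contrast $\mu_B/\mu_U$ | 1.01 | the ~101% bound/unbound intensity ratio |
| state noise $\sigma_U$, $\sigma_B$ | 0.002, 0.004 V | two-Gaussian widths of the filtered-signal PDF; the bound (extended) form is noisier |
| sampling rate | 100 kHz | acquisition rate |
| drift | linear slope, default 0 | drift is discussed only qualitatively in trapping work; a slope is the minimal model |
| temperature | 308.15 K | trap operates near 35 °C |

Noise is white Gaussian per state. The generator starts inside the trapped
regime: the trapping-onset step is not simulated because the analysis
operates only on post-trapping signal. One seed drives each generator
call; `render_trace()` derives its noise stream from `seed + 7919` so that
the dwell structure and the noise are independently reproducible.

What the generator does *not* emulate: 1/f or shot noise, slow nonlinear
baseline wander, multi-protein trapping events, and the detector's
absolute scale. Passing tests therefore demonstrate correctness of the
inference chain under the stated signal model, not robustness to every
instrumental artifact of a real recording.

The ensemble-assay generators are direct inversions of their fitters: the
one-site isotherm $P = P_{\max} C/(K_D + C)$ for fluorescence
polarization, a logistic $I_{350}/I_{330}$ ratio whose derivative extremum
sits exactly at $T_m$ for thermal melts, and a two-point exponential decay
for CPMG. Noiseless round-trips through `fit_one_site_fp()`, `melt_tm()`
and `cpmg_r2()` are exact and are asserted in the tests.

## Ensemble assays: choices that matter

* **FP.** The isotherm has zero intercept ($P = 0$ at $C = 0$); a free
  intercept is available but off by default. Control-well background is an
  optional scalar subtracted before fitting. $K_D$ initializes at the
  concentration of half-maximal observed polarization, $P_{\max}$ at 1.2
  times the observed maximum; parameters are constrained positive.
* **Melt $T_m$.** The ratio is differentiated with a local-quadratic
  (Savitzky–Golay) filter over a ~1 °C window. Peak *localization* uses a
  second smoothing pass over ~5 windows, comparable to the few-degree
  width of a melting-transition derivative peak — a symmetric smoother
  does not displace a symmetric peak, so this buys noise robustness
  without biasing $T_m$ — followed by parabolic interpolation around the
  extremal grid point. The extremum of largest magnitude is used rather
  than the minimum so the extractor is indifferent to the orientation of
  the plotted ratio. A derivative that does not stand out from its own
  median magnitude raises a no-transition error (flat or purely linear
  curves).
* **CPMG.** $R_2 = \ln(I_{\mathrm{short}}/I_{\mathrm{long}})/(t_{\mathrm{long}}-t_{\mathrm{short}})$,
  exact for any delay pair; default delays are the 2 ms / 102 ms
  transverse periods. Intensity growth with delay is unphysical and yields
  a negative $R_2$ with a warning rather than an error, so batch
  processing can flag rather than halt.

## Known limitations and honest numbers

The 3 Hz filter merges dwells shorter than roughly 0.1 s into their
neighbors (about a quarter of all events at the study rates), so both
fitted dwell means come out inflated relative to the generator truth —
roughly 0.6 s where the underlying means are 0.37–0.40 s. The analysis
survives this because the *ratio* $\tau^*$ enters $K_D$ and both dwell
classes inflate nearly together; a small residual asymmetry remains, and
on 400 s synthetic traces the recovered $K_D$ lands within about 10% of
the truth (asserted in the acceptance tests), while per-sample label
accuracy against ground truth sits around 96–98%. Observed event counts
per 100 s are likewise somewhat below the thermodynamic expectation, which
is consistent with filter-induced merging and is checked only as an
order-of-magnitude property.

The temperature entering $\Delta G^\circ$ defaults to 308.15 K (the ~35 °C
trap). At micromolar $K_D$ a few-kelvin ambiguity moves $\Delta G^\circ$
by ~0.1 kcal/mol, which is why $\Delta G^\circ$ is reported but not used
as a recovery benchmark anywhere in the tests.

Test problem sizes are chosen to keep the suite quick while leaving
sampling error well inside the asserted tolerances: $10^4$ dwells for
estimator checks (sampling error of an exponential mean ~1%), 60–120 s
traces for inference tests, 400 s for the end-to-end $K_D$ recovery, and
100 s at the full 100 kHz for the level-contrast recovery.
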