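---
title: "Methods: spike-train analysis of excitation-inhibition balance across learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train analysis of excitation-inhibition balance across learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikecohort)
```

## Scope and data model

`spikecohort` analyses cohorts of sorted extracellular units recorded
during a delayed whisker-detection task: a visual cue marks trial onset, a
brief whisker deflection follows 1 s later on half of the trials, and an
auditory cue 2 s after the visual cue opens a 1-s response window. Trial
outcomes are hit/miss (whisker trials) and correct rejection/false alarm
(no-whisker trials); early-lick trials are aborted during the task and are
excluded from every analysis here. Sessions are stored as plain-text CSV
tables (units, spikes, trials, waveforms, optional light pulses) with
times written as decimal seconds at microsecond precision; all analysis
windows are half-open `[start, end)` so a spike on a bin edge is counted
exactly once.

## Unit classification

Spike width is measured on the average waveform of the probe site with the
largest peak-to-trough amplitude (ties go to the lowest site index), as
the time from the trough to the first return of the voltage to baseline.
Two numerical choices are ours, because "baseline level" has no standard
numeric definition for an average waveform:

* baseline = mean of the first 25% of samples (a pre-trough reference
  segment);
* the return time is linearly interpolated between the two samples
  bracketing the crossing. At 30 kHz the classification thresholds are
  only one to two samples apart, so sub-sample interpolation materially
  reduces quantisation error.

Units with width < 0.26 ms are FS, > 0.34 ms RS, and anything in between
is excluded. Baseline firing rates (spike count over a 2-s pre-visual
window, averaged over trials) are summarised by a maximum-likelihood
normal fit to the log rate; zero-rate units cannot enter the log and are
excluded with their count reported.

## Permutation machinery

All rate comparisons use nonparametric permutation tests. Per-neuron
response-versus-baseline comparisons resample per-trial differences by
sign-flips; group comparisons shuffle unit labels. When the permutation
group is small enough (`2^n` sign patterns or `choose(n, n_a)` labelings
not exceeding `n_perm`, default 10,000) the null distribution is
enumerated exhaustively and the p-value is the exact tail proportion;
otherwise Monte Carlo draws use the add-one formula
`(1 + hits)/(1 + n_perm)`, which cannot produce p = 0. One open reading we
had to fix: whether per-neuron modulation permutes window labels within
trials or pools across trials. We resample the per-trial
(response − baseline) differences by sign-flip, which makes the paired
test exact per neuron. Directional "positively/negatively modulated" calls
are one-sided tests at 0.025 per direction (0.005 for the strict
modulated-fraction maps); both levels live in `default_window_config()`.

FDR correction is Benjamini–Hochberg (`fdr_adjust()` wraps the standard
step-up). Counts of modulated units or detected connections are compared
with a 2×2 chi-squared proportion test with Yates continuity correction —
the continuity-corrected test reproduces the published worked example on
3/1,077 versus 17/1,066 to two significant figures, whereas the
uncorrected statistic does not, so Yates is the default and only variant.

## Windows

Evoked responses are quantified in area-specific windows after whisker
onset (seconds): wS1/wS2 fast 0–0.050, wM1/wM2 0.010–0.090, tjM1
0.040–0.090, ALM delay 0.200–1.000, wS1/wS2 late 0.150–0.350, plus a
common 0–0.100 early window. Every baseline mirrors the duration of its
analysis window and ends at the whisker onset. All windows, smoothing
widths and significance levels are configurable through
`window_config()`; the defaults are the published constants.

## PSTHs and latency

PSTHs use 1-ms non-overlapping bins smoothed with a Gaussian kernel
(σ = 10 ms by default). The kernel is truncated at ±4σ and renormalised;
boundaries are handled by reflective padding, which conserves interior
spike mass (the suite checks conservation to a relative 10⁻⁶ for interior
spikes). Response latency is computed on the baseline-subtracted smoothed
PSTH of responsive units (permutation p < 0.05 for the post- versus
pre-stimulus window): the first time the trace reaches half of its
in-window maximum, or half minimum for suppressed units. Design choices
where the procedure is underdetermined:

* the baseline subtracted before the half-max search is the mean smoothed
  rate over the pre-stimulus comparison window;
* if the half-max level is already exceeded in the first bin the latency
  is the first bin centre and the result is flagged;
* ties in the extremum resolve to the earliest time; for suppressed units
  with a rebound, the first downward crossing wins.

Sensory areas (wS1/wS2) use the high-resolution variant: 100-ms window,
σ = 5 ms.

## Opto-tagging

The opto modulation index compares mean rates in the 100–500-ms window
after light-train onset against a −400–0-ms baseline; its significance is
a paired permutation test over trains. Fast-window metrics use the
half-open `[onset, onset + 10 ms)` window of each train onset (train
onsets, not the individual 100-Hz pulses within a train): fidelity (% of
trains with at least one spike), mean first-spike latency over spiking
trains, and jitter as the n−1 sample SD of those latencies. Tagging
requires all of fidelity > 20%, latency < 4.5 ms, jitter < 2 ms, as strict
inequalities; zero-fidelity units are never tagged.

## Connectivity

Pairwise coordination is measured three ways over simultaneously recorded
sensory→motor pairs (reference = sensory RS unit, target = motor RS or FS
unit):

1. **Pearson** correlation of trial-by-trial evoked responses (5–55 ms
   post-whisker for wS1/wS2, 10–90 ms for wM1/wM2); units at or below
   2.5 Hz in their window are flagged out.
2. **STTC** over a 1-s window centred on the whisker stimulus with
   Δt = 10 ms. Tiling proportions are clipped at the interval edges. If a
   half-term's denominator `1 − P·T` vanishes, that term is dropped and
   the value is the mean of the remaining term(s); if both degenerate the
   value is undefined and flagged.
3. **Jitter-corrected CCG.** The raw CCG is normalised by the triangular
   overlap correction `theta(tau) = N − |tau|` bins and by the two mean
   rates. We take λ in spikes per bin *measured within the analysis
   window*, which makes the expected CCG exactly 1 for independent
   stationary units — the normalisation the detection rule implicitly
   assumes. The jitter surrogate permutes the target unit's spikes across
   trials within each 25-ms slice (100 resamples, mean subtracted);
   permuting only the target halves the resampling variance relative to
   permuting both trains and leaves the expectation unchanged. Detection:
   corrected CCG at lags in `(0, 10]` ms above 6× the SD of the corrected
   flanks (|lag| 50–100 ms, both flanks pooled). The zero lag is excluded
   because a zero-lag peak carries no direction; the published description
   of the lag range leaves its lower edge open, and the bound is exposed
   as an argument. Zero-variance flanks mark the pair degenerate, never
   detected.

## Learning modulation index

`LMI = (ΔAP_E − ΔAP_N)/(|ΔAP_E| + |ΔAP_N|)` per area and cell class, where
each ΔAP is the grand-average evoked change across all units pooled over
mice; a per-mouse-weighted variant (`lmi_table_by_mouse()`) averages
within sessions first, for reporting styles that weight mice equally. The
index is antisymmetric under swapping groups, scale-invariant, bounded by
1 in magnitude, and reported to two decimals. E–I balance is
`LMI_RS − LMI_FS` per area.

## The synthetic generator

`generate_session()` draws each unit as an inhomogeneous Poisson process
with rate `max(0, baseline + active templates)`. Its defaults encode the
study conditions the analyses assume:

* **Baseline rates**: log-normal, RS median 2 Hz (σ_log 0.9), FS median
  6 Hz (σ_log 0.7) — FS units fire faster, and the log-rate histogram is
  normal.
* **Spike widths**: Gaussian mixture, FS 0.19 ± 0.02 ms, RS
  0.55 ± 0.06 ms. Both components put well under 0.1% of their mass inside
  the 0.26–0.34-ms exclusion zone, so ground-truth classes are recoverable
  exactly.
* **Evoked templates**: one difference-of-exponentials kernel per area ×
  class, onset-shifted by the area's latency, scaled so that its mean over
  the area's analysis window equals the configured amplitude; the
  amplitude sets are the published Novice and Expert group means (e.g.
  wM1-RS 1.8 Hz Novice vs 0.9 Hz Expert), so cohort-level indices have
  known targets. Suppression (tjM1) is a negative amplitude rectified at
  zero; ALM uses slow time constants that fill the 200–1,000-ms delay
  window. The kernel form is our choice — the published PSTH shapes
  prescribe no generative model — as the simplest form giving fast
  transients plus late components.
* **Sampling**: baseline-only segments are drawn directly as homogeneous
  Poisson; template-affected segments use thinning against the local rate
  bound, which is exact and simple to audit.
* **Couplings**: each pre-synaptic spike spawns a post-synaptic spike at
  `t + delay + N(0, jitter)` with probability `efficacy` — the ground
  truth for the CCG detection rule.
* **Opto sessions**: 50 trains of 600 ms; tagged (ground-truth GABAergic)
  units get an 8× rate elevation during light plus an explicit first spike
  at 2 ± 0.3 ms with 90% fidelity (any earlier background spike in the
  window is removed so the configured latency is the one observed);
  untagged units are suppressed to 0.3× baseline.
* **Seeds**: one master seed; per-unit substreams are derived by a
  counter, so enlarging a cohort leaves existing units' spike trains
  unchanged.

What the generator does **not** emulate: bursting and refractoriness
(trains are Poisson), waveform drift and sorting errors, behavioural
covariates such as licking and whisker movements, slow non-stationarities
across a session, and mouse-level heterogeneity beyond what independent
log-normal draws produce. Passing parameter-recovery tests therefore shows
the estimators are correct under the model the analyses assume, not that
real recordings satisfy that model.

## Problem sizes and numerical tolerances in the test suite

Stochastic checks in the suite run at sizes chosen to keep the whole run
around a minute while leaving Monte Carlo error well inside the asserted
bounds: 1,000 independent Poisson pairs for the STTC null, 10,000
simulated null corrected CCGs for the false-positive bound, 50 replicate
200-trial pairs for detection sensitivity at efficacy 0.2, 1,000 null
replicates for permutation-test calibration (exhaustive enumeration at
n = 10), 10,000 draws for log-normal parameter recovery within ±0.05, and
cohorts of 30–60 units for evoked-amplitude and latency recovery.
Stochastic assertions use three standard errors (binomial 99% CIs for
rates) so that a correct implementation fails only with negligible
probability under the fixed seeds.

## Known limitations

* The CCG machinery assumes 1-ms bins with at most a few spikes per bin;
  extremely high rates (> 300 Hz) would make the binomial-coincidence
  reading of the normalisation inaccurate.
* STTC with very dense trains (coverage near 1) approaches its degenerate
  denominator; the term-dropping rule keeps the value defined but such
  pairs deserve inspection.
* The latency estimator inherits the smoothing kernel's bias: a true step
  at t appears up to ~σ earlier once smoothed; the suite bounds this bias
  rather than correcting it, matching the published procedure.
* `run_pipeline()` is an orchestration convenience for synthetic cohorts;
  real-data studies will usually call the stage functions directly on
  their own session objects.
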