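---
title: "Methods: sleep, arousal and fan-shaped-body electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep, arousal and fan-shaped-body electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeparousal)
```

This package implements the analysis pipeline of a Drosophila
arousal-threshold study design: flies are tracked in glass tubes under a
12:12 light:dark cycle while trains of mechanical vibrations (five 0.2 s,
2.4 g pulses, 0.8 s apart, delivered hourly) probe behavioral
responsiveness, and dorsal fan-shaped-body (dFB) neurons — the fly's "sleep
switch" — are recorded intracellularly and with a local field potential
(LFP) electrode while being activated optogenetically. Because raw
recordings of this kind are rarely deposited, the package pairs every
analysis stage with a synthetic-data generator that plants known parameters,
so each estimator can be validated by parameter recovery.

## Behavioral metrics

**Speed and sleep.** Positions are sampled on a uniform grid (1 Hz by
default) and speed is the absolute frame-to-frame displacement per second.
Sleep is the standard fly criterion: a maximal run of immobility lasting at
least 5 minutes. "Immobility" needs a movement floor because real tracking
jitters; the floor `immobility_eps` defaults to 0.5 mm/s, roughly the scale
of tracking noise and well below walking speeds (~1–3 mm/s). Hourly sleep
(min/hr) is computed from unstimulated epochs only: the 15 minutes after
each stimulus (the response-analysis window) are removed from both the sleep
tally and the available time, and the hour is rescaled; an hour with no
usable time is missing, not zero. Bouts split proportionally at hour
boundaries, and all bins are half-open.

**Responsiveness.** The stimulus-locked mean speed, from 2 minutes before to
15 minutes after the train onset (the 4.2 s train is collapsed to its
onset), is fitted with a single-inactivation exponential

$$ y(t) = B + A\,(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}, \qquad t \ge 0, $$

with the baseline $B$ fixed at the pre-window mean. Peak responsiveness is
the fitted curve's analytic maximum above baseline, attained at
$t^* = \tau_r \log(1 + \tau_d/\tau_r)$. Whether the published peak is
baseline-subtracted is a convention we had to choose; this package subtracts
$B$. The least-squares problem is solved with a Levenberg–Marquardt
routine from two starting points — a data-driven start (decay from the tail
log-slope, rise solved from the observed peak time, amplitude from the
observed peak) and a generic one — keeping the lower-deviance solution;
this avoids a local minimum at vanishing rise time that a naive start falls
into on clean curves. Non-convergence is flagged and the peak falls back to
the smoothed-curve maximum.

**Responder calls and sleep intensity.** A fly responds to a stimulus if its
cumulative path length in the following minute reaches 3 mm (~3 body
lengths); path length, not net displacement, so a fly that walks out and
back has responded. A fly is immobile at the stimulus if it made no
supra-floor movement in the preceding minute; awake analyses keep only the
complement. Sleep intensity is the fraction of immobile flies responding
(lower = deeper sleep), overall and in half-open 5-minute bins of prior
immobility covering 0–30 min with a separate overflow bin. Calls whose
windows are truncated by the trace edge are excluded, never defaulted.

**Correlations.** Day is ZT 0–12. Per-fly sleep (min/hr) and per-fly fitted
peak responsiveness are correlated per circadian window with Pearson's R and
a two-tailed p (the published figures report "R" without naming the
method; Pearson is the declared choice), listwise-excluding flies missing
either value.

## The behavioral generator

Each fly follows a two-state (active/quiescent) semi-Markov chain on minute
boundaries with geometric dwell times and parameters switching at ZT0/ZT12 —
the simplest model that produces the day/night sleep architecture. Active
frames draw gamma speeds (mean 2 mm/s); quiescent frames carry only small
tracking jitter (SD 0.03 mm). Positions integrate speed with a random
direction each frame and fold back at the tube ends (65 mm), so derived
speeds equal the intended speeds except at rare fold frames.

Per-fly heterogeneity and the planted correlations work through latent
variables: one amplitude factor $v$ per fly and window-specific sleep
propensities $u_w = R_w v + \sqrt{1 - R_w^2}\,\varepsilon_w$, so
$\mathrm{cor}(u_w, v)$ equals the planted $R_w$ exactly. The fly's
stationary sleep fraction in window $w$ is a clipped linear map of $u_w$
(SD 0.16 around the population value), and its response-amplitude target is
a linear map of $v$ (mean 2, SD 0.6 mm/s, floored at 0.1).

Responses are state-dependent: awake flies respond with probability 0.95;
immobile flies respond with a probability read from a declining map over
5-min immobility bins (0.55, 0.40, 0.30, 0.22, 0.17, 0.13; 0.10 beyond 30
min). A responder gets the kernel
$a\,(1 - e^{-t/\tau_r}) e^{-t/\tau_d}$ (defaults $\tau_r = 5$ s,
$\tau_d = 120$ s) added to its speed. Two generator conventions matter for
testability:

* **Effective-amplitude normalisation.** The per-stimulus kernel amplitude
  is the fly's target divided by its realised responder fraction in that
  window. The fly's mean evoked response over all window trials — exactly
  what the curve fit measures — then equals the planted target. Without
  this, state-dependent response probability (sleepier flies respond less
  often) would confound the planted day correlation of zero with a spurious
  negative one.
* **Planted outcomes are the scored outcomes.** A sleeping fly that does not
  respond is held quiescent through the scored minute. Otherwise ~5% of
  sleeping non-responders would wake spontaneously inside the minute and be
  scored as responders, biasing every bin fraction upward relative to the
  planted probabilities. With this convention the responder call equals the
  planted Bernoulli outcome exactly, and per-bin fractions are calibrated.

With chronic-activation configurations the generator plants the published
correlation pattern directly (day 0 / night −0.372 for a wildtype-like
cohort of 225; −0.410 / −0.554 for an activated-like cohort of 51); acute
optogenetic configurations instead multiply the evoked amplitude by
`dfb_activation_factor` during light-on trials.

What the generator does **not** emulate: positional preferences and wall
interactions, circadian modulation finer than the ZT0/ZT12 switch,
stimulus habituation, sleep homeostasis (rebound), and any coupling between
electrophysiology and behavior. Passing recovery tests therefore shows the
estimators are correct for data of this structure, not that the biological
conclusions transfer to any particular real recording.

## Intracellular analysis

Recordings are current-clamp traces digitised at 10 kHz, resting potential
stabilised between −50 and −30 mV, with 1 min of baseline before a 2 min
light epoch. Spike detection finds peaks after the voltage slope exceeds
10 mV/ms with at least 5 mV prominence and a 2 ms refractory period; the
slope is measured over a 0.5 ms span of a 0.5 ms moving-averaged trace,
because the raw one-sample slope at 10 kHz has an SD of ~14 mV/ms under
1 mV recording noise and would swamp any threshold. Both thresholds are
declared package defaults.

Bursts are volleys whose inter-peak potential fails to return to rest; the
implementation requires the inter-peak minimum to stay more than 2 mV above
the resting estimate (median of the pre-light minute with ±5 ms around
spikes excised) as a noise-floor margin. Cells classify as burst,
single, single-and-burst, or — when no spikes appear despite current steps
of +10 pA up to +150 pA — non-spiking; without step data the label is
indeterminate and flagged. The intra-burst interval is the first-to-second
peak time.

Light-evoked changes are reported as ΔVm, never absolute potential: window
means of the raw trace (spike waveforms are not excised; the alternative is
not documented in this experimental tradition, so the simpler convention is
declared) over the pre-light minute, the first minute of light, and the
final minute of the recording (valid only when it starts ≥ 60 s after light
off). For 1 Hz / 5 ms pulsed light, the 1 s epochs after each of the 120
pulse onsets are averaged pointwise into a composite and the response is the
composite's first-100-ms mean relative to baseline. Secondary spikes are
counted 100–500 ms after each pulse's first evoked spike (first spike within
50 ms of onset); reliability is the fraction of evoked pulses with at least
one.

The Vm generator plants all of these: a rise/decay depolarisation for
constant light, per-pulse bumps normalised so the composite first-100-ms
mean equals the planted value exactly, burst volleys riding a +10 mV plateau
with 18.75 ms intra-burst spacing, and Bernoulli secondary spikes at
uniform 200–400 ms latencies.

## LFP analysis

Spectrograms use complex Morlet wavelets of width 30 cycles, Gaussian
envelope truncated at ±3 SD, on an inclusive 0.1 Hz grid from 1.0 to 15.0 Hz
(141 bins). Wavelets are scaled to unit energy so power is comparable across
frequencies (the width-30 convention follows the standard field-trip
parameterisation; exact numeric agreement with any particular toolbox output
is not claimed). Signals sampled faster than 500 Hz are decimated first with
an anti-alias filter — lossless for a 1–15 Hz analysis band and necessary
for tractability, since the 1 Hz wavelet spans 28.6 s. Samples closer to an
edge than half the wavelet support are masked and excluded from every mean,
never zero-padded.

For statistics, each 0.1 Hz row is divided by its mean baseline power and
the baseline is zeroed (ratio − 1), one mean stimulation-period ratio per
fly over 1–15 Hz; for display averaging across flies the whole matrix is
normalised by the grand baseline mean instead, since raw wavelet magnitudes
differ across recordings. The ERP measure re-zeroes each trial by its 50 ms
pre-pulse mean (the published "deviation from zero" leaves its zero
undefined; per-trial re-zeroing is the declared convention) and takes the
maximum absolute deviation in the 50 ms after pulse onset, averaged over the
120 trials.

The LFP generator shapes Gaussian noise to a 1/f spectrum, splits it into
its 1–15 Hz component and remainder by Fourier masking, scales the in-band
component by the planted amplitude gain during light (with 0.5 s cosine
ramps), and adds a deterministic Gaussian-shaped deflection (FWHM 5 ms)
at the planted latency after each pulse. The in-band amplitude also carries
a slow log-normal drift (SD 0.3, ~20 s correlation time): in vivo band
power is nonstationary on this scale, and without the drift the across-fly
spread of baseline-zeroed ratios collapses to near zero, making the small
positive Jensen bias of ratio-to-baseline normalisation (the 1 Hz row has
only a handful of independent baseline samples in one minute) spuriously
"significant" in control cohorts.

## Group statistics

The test battery mirrors the analysis plan of this experimental design:
Friedman tests with Dunn's post hoc comparisons against the pre-stimulus
condition for within-cell pre/stim/post designs (Dunn implemented as
within-block mean-rank z statistics with Bonferroni family adjustment — the
standard Dunn definition; the adjusted p never falls below the unadjusted),
Wilcoxon signed rank against zero for baseline-zeroed power ratios,
Mann-Whitney for two independent strains, paired/unpaired t-tests screened
by Shapiro-Wilk at p < 0.05 and demoted to the matching nonparametric test
on failure, and two-way ANOVA (additive genotype + bin model, type-I sums
of squares) with single-step Dunnett contrasts against the declared control
genotype. Everything is two-tailed at α = 0.05. `build_report()` writes the
per-observation tables and computes all statistics *from those tables*, so
every reported p-value is reproducible from the emitted CSVs.

## Numerical choices and test problem sizes

* ">5 min" immobility is implemented as ≥ 300 s; the strict inequality
  differs by one frame at 1 Hz.
* Stimulus onsets sit mid-hour; immobility ages are right-censored at 40
  minutes (binning tops out at 30).
* The tracking frame rate is not dictated by the assay; 1 Hz is the default
  and is adequate for 5-min bouts and 60-s response windows.
* Fit bounds: A ∈ [0, 10⁴] mm/s, rise ∈ [0.01, 600] s, decay ∈ [0.1, 5000] s.
* Recovery and pattern tests run on 2-day cohorts (the assay records 2–4
  days; two gives ~24 trials per window per fly, enough for stable per-fly
  fits), Vm traces at 2–10 kHz as noted per test, and LFP checks at 250 Hz —
  all stated here as the package's analysis sizes.
* Correlation-recovery checks compare seed-averaged estimates against the
  planted value's 95% Fisher-z sampling band; at n = 51 the per-seed power
  of a two-tailed Pearson test at |R| ≈ 0.4 is only ~0.85 even for perfect
  recovery, so per-seed significance is required only in the large-n
  wildtype configuration.

## Limitations

Estimated peaks inherit the fitted family; responses with genuinely
different shapes (plateaus, double rises) are summarised by the best-fitting
single-inactivation curve. The wavelet implementation targets the 1–15 Hz
band; higher bands would need a different decimation target. The Dunn and
Dunnett variants are declared choices among several in common use, and the
synthetic generator's realism limits (above) bound what green tests certify
about real recordings.
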