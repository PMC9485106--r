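---
title: "Quantifying fear-state-dependent theta dynamics in two-region LFP recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fear-state-dependent theta dynamics in two-region LFP recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearlfp)
```

## The analysis problem

During discriminative auditory fear conditioning (DAFC), a rodent learns that
one 30-s tone (CS+) predicts a foot-shock while a second tone (CS-) does not.
Over a five-day protocol — habituation, acquisition, two days of extinction,
extinction recall and renewal — the animal's fear state changes session by
session, and local field potentials (LFPs) recorded simultaneously in the
prelimbic (PL) and infralimbic (IL) subdivisions of the medial prefrontal
cortex change with it. Two quantities capture those changes:

1. **CS-evoked normalized band power.** For each trial, band and region, the
   Welch power spectral density (PSD) of the first 15 s of the CS window is
   summed over frequency and divided by the summed PSD of the 15 s
   immediately before CS onset:
   \[
   \mathrm{power\ ratio} \;=\;
   \frac{\sum \mathrm{PSD}_{\,15\,\mathrm{s\ CS}}}
        {\sum \mathrm{PSD}_{\,15\,\mathrm{s\ pre\text{-}CS}}}.
   \]
   A ratio of 1 means the CS evoked no power change; a multiplicative
   amplitude gain \(g\) on a band-limited component appears as a ratio of
   \(g^2\).

2. **Inter-region coupling.** PL and IL signals are band-filtered, the 15-s
   CS windows are cross-correlated using the raw-moment convention
   \[
   \hat R_{xy}(m) = \sum_{n=0}^{N-m-1} x_{n+m}\,y_n,\qquad
   \hat R_{xy,\mathrm{coeff}}(m) =
   \frac{\hat R_{xy}(m)}{\sqrt{\hat R_{xx}(0)\,\hat R_{yy}(0)}},
   \]
   and the peak of \(\hat R_{xy,\mathrm{coeff}}\) over lags is the
   functional-connectivity strength for that trial.

Because the in-vivo recordings behind this kind of experiment are rarely
deposited, the package is organised around a synthetic-data generator with
known ground truth: every stage of the pipeline is verified by parameter
recovery rather than against an unavailable reference dataset.

## Band decomposition

The canonical bands are theta (4–10 Hz), slow gamma (30–55 Hz) and fast gamma
(55–100 Hz). Filtering uses linear-phase FIR bandpass filters specified by a
tolerance scheme, not by tap identity: at least 80 dB stopband attenuation, at
most 1 dB passband ripple, and 0.5 Hz transition regions on each side of the
passband.

`design_bandpass()` chooses the design method automatically. A 0.5 Hz
transition at 1 kHz sampling demands roughly \(10^4\) taps; equiripple
exchange algorithms are unreliable at such orders, so the Kaiser-window design
is used there (an equiripple design is attempted when the estimated order is
modest). Because the textbook Kaiser order and shape formulas are
approximations, the design applies a small internal margin — 5 dB extra
attenuation and a 10% narrower transition — and then *measures* its own
frequency response on a dense grid; a design that misses the nominal
tolerances is an error, never a silent degradation. The achieved
characteristics are attached to the taps and logged by the pipeline.

```{r filter}
h <- design_bandpass(band_definition("theta", 4, 10), filter_spec(), 1000)
attr(h, "achieved")
```

`apply_zero_phase()` compensates the constant group delay \((L-1)/2\) of the
symmetric taps so that filtered signals stay time-aligned with the raw signal
— essential when two regions are cross-correlated against a common event
clock. The signal is extended by reflection at both ends; edge effects decay
within half the filter length, and since every analyzed window starts at
least 15 s into the session they never reach analyzed samples at the default
specs.

Artifact handling makes an often-unstated manual step explicit: a trial is
excluded when the broadband signal's robust z-score (median/MAD) exceeds 6
continuously for at least 50 ms anywhere in the trial's pre-CS or CS window.
Both parameters are configurable; exclusions are logged with the triggering
time, and an exclusion in either region removes the trial everywhere so that
power and coupling tables stay aligned.

## Welch PSD conventions

`welch_psd()` splits a window into 16 equal non-overlapping segments
(remainder samples dropped — 8 of 15 000 at 1 kHz), subtracts each segment's
mean, applies a Hann window, and averages the one-sided modified
periodograms, scaled so that the integral of the density over frequency
equals the signal variance for white noise. Mean subtraction per segment is
deliberate: at the ~1.07 Hz resolution of 937-sample segments, DC leakage
would otherwise bias the theta band. The frequency resolution is a direct
consequence of the 16-segment convention and is accepted as such; no
zero-padding is applied by default.

The power ratio is computed on the band-filtered signal, summing its PSD over
all bins. Summing a broadband PSD over band bins only is nearly equivalent
for filters meeting the 80 dB contract, but the filtered-signal form matches
the band-decomposition-first structure of the pipeline. Because both windows
share one segmentation and normalization, the ratio is invariant to rescaling
the recording — unit mistakes (mV vs µV) cannot bias it.

## Cross-correlation conventions

`xcorr_coeff()` implements the raw-moment (biased, no mean subtraction)
convention literally: it is what the displayed normalization computes, and
band-filtered signals are near-zero-mean so a Pearson-style variant (left as
an option) nearly coincides. There is no per-lag edge correction; at
\(N = 15\,000\) samples and lags up to 500 ms the maximal bias is
\(m/N < 3.5\%\). The FFT implementation is required to match the direct
double-loop sum to \(10^{-10}\) relative — this dual-route check is part of
the test suite. The default lag window of ±500 ms covers more than two theta
cycles; the peak is the signed maximum by default (an absolute-value mode
exists), with ties broken toward the smallest |lag|, negative first.

"Instantaneous amplitudes" of band-limited LFPs can be read either as the
filtered samples themselves or as their Hilbert envelopes; the filtered
samples are the default (`amplitude_mode = "filtered"`), the envelope is
available behind the same flag, and cross-correlation is computed per 15-s CS
window (mirroring the power analysis) rather than over concatenated sessions.

**Lag estimation.** The peak *coefficient* is stable per trial, but the peak
*lag* of a single trial jitters by several samples whenever coupling is
moderate: near the peak the cross-correlation curve is locally flat (a 7 Hz
carrier changes by only ~0.1% one sample away), so the independent theta
fraction dominates the argmax. `session_coupling_curve()` therefore averages
the coefficient curves across trials before taking the peak; with 20 trials
and strong coupling this recovers an injected 25 ms lag to the sample.

## The synthetic-data generator

Each region's signal is a sum of \(1/f^{\beta}\) background noise
(\(\beta = 1\) by default) and one band-limited Gaussian oscillation per
band, built in the frequency domain (random complex coefficients confined to
the band with short cosine edge tapers) and scaled to exact RMS. Band-filtered
Gaussian noise was chosen over drifting sinusoids because it is stationary
and analytically tractable: a 15-s theta window then has ~110 effective
degrees of freedom, which fixes the variance every recovery test must live
with (per-trial power ratios have ~19% relative SD; 20-trial means ~4%).

Default amplitudes (theta 60 µV, slow gamma 10 µV, fast gamma 8 µV over
15 µV RMS background) give the theta-dominated spectrum typical of rodent
prefrontal LFP and keep in-band background contamination of the theta ratio
below 2%.

CS-evoked effects are multiplicative amplitude envelopes per (region,
session, stimulus, band), with 200 ms raised-cosine ramps at CS on- and
offset to avoid spectral splatter; onset dynamics within the 30-s CS are
otherwise flat, since block-wise freezing analyses give no reason to model a
build-up. Coupling is injected at the theta-component level only:
\[
\mathrm{IL}_\theta(t) = c(t)\,\hat p(t + k) +
\sqrt{1 - c(t)^2}\,\hat q(t),
\]
with \(\hat p\) the (unit-variance) PL theta component shifted by the
configured lag \(k\), \(\hat q\) an independent component, and \(c(t)\)
switching between the baseline coupling (0.2) and the per-(session, stimulus)
table value inside CS windows. The theoretical peak correlation of the two
components during a CS is then exactly \(c\). Gamma components are
independent between regions. A positive configured lag produces a
cross-correlation peak at a positive lag with x = PL, y = IL.

Trial structure follows the canonical protocol: Hab 5/5, ACQ 5/5 (US
co-terminating with the CS+), two extinction days of 12/12, recall 2/2,
renewal 2/2 — 38 CS+ and 38 CS- events in total; pseudorandom ordering is a
constrained shuffle with at most 3 consecutive same-type trials; ITIs are
uniform on 90–120 s; the pre-session period is 180 s, so every onset has far
more than the required 15 s of clean baseline. The default gain and coupling
tables emulate the qualitative fear-state pattern this analysis is built to
detect: PL theta up in acquisition and renewal, IL theta up in late
extinction and down in renewal, coupling elevated through fear and extinction
learning and recall (0.45–0.52) but reduced in renewal (0.30), all effects
CS+-specific and absent in gamma. The recall/renewal coupling defaults sit in
the empirically representative 0.3–0.5 range for prefrontal pairs.

What the generator does *not* emulate: non-stationary theta frequency drift,
movement- and freezing-locked power modulation, volume conduction between
regions, electrode drift, and realistic artifact waveforms. Passing recovery
tests therefore demonstrate that the estimators are correct and well-scaled
under the generative model's assumptions, not that those assumptions hold for
any particular in-vivo dataset.

## Session blocks and aggregation

Quantification uses fixed trial blocks per behavioural state: all 5
habituation trials, acquisition trials 3–5 (fear learning), extinction-day-1
trials 1–3 (fear expression), extinction-day-2 trials 10–12 (extinction
learning), both recall trials, both renewal trials — identical rules for CS+
and CS-. Block averages report mean, SEM and n; excluded trials reduce n, and
an emptied block yields an NA row with a warning rather than a silent gap.
Parametric session statistics are intentionally out of scope; the pipeline
provides a seeded label-shuffle permutation contrast
(`permutation_contrast()`, add-one two-sided p) as its self-contained
inferential tool.

## Numerical choices and degenerate inputs

* FFT lengths are padded to powers of two everywhere (mixed-radix transforms
  on awkward lengths are catastrophically slow in practice); generators build
  at the padded length and keep the leading samples.
* Time convention: seconds from session start, sample 1 at t = 0, half-open
  windows \([t_0, t_1)\) mapped by `floor(t * fs)`.
* Zero-energy inputs: an all-zero window has an all-zero PSD; a zero-power
  pre-CS window makes the ratio an error (not Inf); zero-energy
  cross-correlation inputs are an error (normalization undefined).
* Determinism: every stochastic step derives from a single integer seed via
  labeled child streams, so a fixed (config, plan, seed) triple yields a
  byte-identical dataset; analysis outputs are deterministic given the data.

## Verification problem sizes

The test suite verifies the pipeline at sizes chosen to keep the full suite
in the minutes range while preserving the statistics that matter: estimator/
oracle equivalence on hundreds of random inputs; filter contracts at 500 Hz
and 1 kHz; theta gain recovery (g ∈ {1.5, 2} → ratio g² ± 10%) and coupling
recovery (c ∈ {0.2, 0.4, 0.6, 0.8} → peak ± 0.05, monotone; lag 25 ms ± 1
sample at c = 0.9) on 20-trial sessions at 1 kHz with shortened ITIs
(16–18 s — the 15-s analysis windows are untouched); and the fear-state
pattern at 250 Hz with 20 trials per stimulus per session across 100 seeded
runs, where session-mean orderings must respect every injected separation
larger than the single-condition recovery tolerance, and the
renewal-vs-recall coupling contrast must be significant in at least 90% of
runs. The default generator configuration — full protocol, 1 kHz, 90–120 s
ITIs — is used where structure rather than statistical power is being
checked.

## Known limitations

* The first 15 s of each CS window is analyzed by convention; the second
  half of the 30-s CS is ignored (a window offset is configurable).
* The artifact criterion is an explicit stand-in for manual screening; its
  defaults (z > 6, ≥ 50 ms) were chosen to catch gross transients, not
  subtle contamination.
* Per-trial peak lags are reported but should not be averaged naively; use
  the averaged-curve estimator for lag inference.
* The permutation contrast treats trials as exchangeable units within a
  session pair; it does not model animal-level nesting.
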