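---
title: "Estimating FFR latency by constrained phase-unwrapping group delay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating FFR latency by constrained phase-unwrapping group delay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrdelay)
```

## The problem and the model

The frequency following response (FFR) is a sustained scalp potential phase
locked to the periodicity of a sound. Its latency carries information about
which stage of the auditory pathway dominates the recorded activity: a
response delayed by $\tau$ seconds has phase
$\phi(f) = \phi_0 - f\,\tau$ cycles at frequency $f$, so the *group delay*
$\tau = -\,d\phi/df$ can be read off a straight-line fit of phase against
frequency — **if** the phases, which are measured only modulo one cycle, can
be unwrapped correctly.

This package implements a complete pipeline around that idea for a
particular stimulus design: five three-tone complexes sharing a 576-Hz
center tone, with tone spacings (modulation rates)
$f_m \in \{85, 100, 115, 130, 145\}$ Hz. Each stimulus is presented in
alternating polarity. The polarity-*addition* waveform isolates
envelope-locked activity, analyzed at the five modulation rates; the
polarity-*subtraction* waveform isolates fine-structure-locked activity,
analyzed at the five lower and five upper side-tone frequencies. Each of the
three frequency regions, per electrode montage, yields one group delay.

Assumptions worth keeping in mind:

* a region's sources have a *constant* group delay across its ~60-Hz span
  (a mixture of sources with fixed relative weights also satisfies this, so
  a good linear fit never proves a single generator);
* envelope-locked activity does not invert with stimulus polarity while
  fine-structure-locked activity does — exactly true in the generator,
  approximately true of real physiology (half-wave rectification makes
  envelope responses only *mostly* polarity-invariant);
* the cochlear microphonic behaves like a near-zero-latency fine-structure
  source and therefore contaminates the subtraction waveform, biasing TFS
  delays short (the package demonstrates this monotone bias in simulation).

## The analysis chain and its tunable parameters

1. **Trial rejection** — raw trials with peak magnitude above ±60 µV are
   dropped before subaveraging.
2. **Zero-phase filtering** — stored subaverages are band-passed 60–2000 Hz
   with a fourth-order Butterworth applied forward and reversed
   (`bandpass_zero_phase()`), doubling the effective order and leaving zero
   net phase. Because a 140-ms epoch is barely eight periods of the 60-Hz
   corner, the trace is extended by odd-symmetric reflection (default three
   corner periods per side) before filtering; without padding the
   forward–reverse transients visibly perturb the epoch ends.
3. **Subaverage rejection** — filtered subaverages with peaks above ±35 µV
   are excluded; the rule deliberately applies *after* filtering, so a large
   out-of-band sway does not cost a clean subaverage.
4. **Polarity combination** — unweighted grand means per polarity over the
   accepted subaverages, then addition/subtraction halved
   (`combine_polarity()`). Means are formed per polarity first, so unequal
   accepted counts cannot bias the combination.
5. **Spectral estimation** (`spectral_estimate()`) — the Fourier coefficient
   at exactly the target frequency over an analysis window (default
   20–140 ms, the between-ramp steady state), normalized so a sinusoid of
   amplitude $A$ measures $A$. Target and noise frequencies (e.g. 85 Hz,
   offsets of 9 Hz) are not integer bins of any FFT of the epoch, so the
   coefficient is evaluated by direct correlation with a complex
   exponential rather than by zero-padded FFT; the stated "4-Hz resolution"
   of the noise bins is honored as 4-Hz *spacing*.
6. **Presence criterion** (`presence_test()`) — the F ratio of on-frequency
   power (2 df) to the mean power of the 16 bins at
   $f \pm \{9, 13, \ldots, 37\}$ Hz (32 df), accepted at the 1 % level,
   threshold `qf(0.99, 2, 32)` ≈ 5.34. Note that 5.34 as a power *ratio*
   corresponds to about 7.3 dB; both forms are exposed by
   `presence_threshold()`.
7. **Transducer correction** (`correct_transducer_delay()`) — the
   earphone-tube chain delays the stimulus acoustically by 18.2 ms; the
   fractional part of $0.0182 f$ cycles is added back to each phase before
   unwrapping (whole cycles are irrelevant to unwrapping).
8. **Group-delay fit** (`fit_group_delay()`) — described next. A region is
   fitted only when at least three of its five frequencies pass the
   presence criterion.

Key defaults, all configurable through `study_config()` /
`unwrap_search_config()`: delay window 0–20 ms (slope $[-0.02, 0]$
cycles/Hz), SSE bound 0.05 squared cycles, search depth 0.04 cycles per Hz
of anchor distance, minimum 3 points, significance level 0.01, rejection
limits 60/35 µV, filter band 60–2000 Hz.

## The constrained unwrapping search

Sequential (nearest-value) unwrapping is unambiguous only for delays below
$1000/(2\,\Delta f)$ ms (`ambiguity_limit()`): 33.3 ms at the full 15-Hz
spacing, but 16.7 or 11.1 ms when one or two consecutive frequencies fail
the presence criterion — squarely inside the physiological range. The
package therefore enumerates *all* delay-feasible unwrappings:

* the lowest present frequency anchors the fit at its principal phase
  $p_0 \in [0, 1)$;
* every other point is first unwrapped to the nearest congruent value at or
  above $p_0$ (which by itself would imply a non-causal, negative delay);
* integer cycles are then subtracted, keeping every congruent value in
  $[\,p_0 - 0.04\,\Delta x,\; p_0 + \mathrm{frac}\,]$ where $\Delta x$ is
  the point's distance in Hz from the anchor.

The lower edge of that region is the geometric boundary "0.04 cycles per Hz
below the anchor", i.e. twice the 20-ms delay bound, leaving headroom for
residual scatter around a steep fit. Defining the candidate set by this
*region* (rather than by a fixed offset count per point) guarantees the true
unwrapping is inside it for any delay up to 40 ms: the required offset for
point $i$ is exactly $\mathrm{frac}_i + |s|\,\Delta x_i$ cycles for true
slope $s$, which is within the region whenever $|s| \le 0.04$. The test
suite verifies containment and exact (machine-precision) recovery for
arbitrary slopes in $(-0.02, 0)$, including series with 30- and 45-Hz gaps,
and checks the whole search against a brute-force enumeration oracle.

Each candidate is fitted by ordinary least squares (phase in cycles on
frequency in Hz). Candidates with slope outside $[-0.02, 0]$ or
SSE ≥ 0.05 are discarded; the minimum-SSE survivor wins, with exact ties
broken toward the smaller $|$slope$|$ (a deterministic rule; "best fit"
alone does not decide ties). If nothing survives, the fit is reported as
`no_valid_fit` — a missing value, mirroring how real datasets lose cells —
and never as a number.

## Phase conventions

Phases are in cycles throughout: the transducer correction term
$0.0182 f$ and the slope window $[-0.02, 0]$ are mutually consistent only in
cycles/Hz. `dft_at()` defines phase 0 as a cosine starting at the *window*
onset; the pipeline, however, references phases to the *epoch* (stimulus)
onset (`phase_ref = "epoch"`). This matters: with window-onset referencing,
a window starting at 20 ms would subtract 20 ms from every fitted delay.
Truncating a delayed tone inside the window does not bias its phase (the
dominant coefficient term is $e^{-2\pi i f \tau}$ times a positive real
number for any real amplitude envelope); leakage from the neighboring tones
≥ 85 Hz away contributes only a sub-0.01-cycle perturbation.

## What the synthetic generator emulates — and what it does not

`simulation_config()` builds trials as montage-weighted sums of
latency-shifted sources plus noise:

* **Sources.** `tfs` and `cm` sources are delayed copies of the stimulus
  waveform itself (sign-flipping with polarity); the `envelope` source is a
  delayed copy of the mean-removed analytic-signal magnitude of the
  stimulus (`envelope_drive()`), which is *exactly* polarity-invariant —
  chosen over half-wave rectification so the cancellation identities are
  exact and testable. Latencies are applied as fractional-sample delays via
  frequency-domain phase shift, since ±0.5-ms recovery claims need
  sub-sample accuracy. The acoustic 18.2-ms tube delay is added to every
  source and corrected by the analysis, so the correction path is exercised
  end to end.
* **Defaults as study conditions.** Envelope source at 8.5 ms (both
  montages); TFS sources at 4.5 ms (horizontal montage) and 8.0 ms
  (vertical); a cochlear-microphonic source at 0.8 ms with zero default
  gain, switched on by contamination experiments. 1600 trials per block
  stored as 16 subaverages of 100, per polarity.
* **Noise.** Pink noise (white Gaussian noise shaped by a $1/\sqrt{f}$
  magnitude filter above 1 Hz, the standard EEG background approximation)
  plus white noise, each 6 µV per trial by default. Source gains (0.45 µV)
  were calibrated once so a 100-trial subaverage has an on-frequency SNR
  near 15 dB while trial peaks stay meaningfully below the ±60-µV rejection
  limit; the response amplitude scale of real recordings is not observable
  in simulation, so these are modeling choices, not measurements.
* **Artifacts.** With probability 0.02 a trial receives a one-period 10-Hz
  sinusoid pulse of 120 µV peak — an arbitrary but documented shape; only
  its peak matters to the rejection logic.

Not emulated: biophysical dipole/head geometry, onset (ABR-like)
transients, listener-state drift, stimulus artifact, mains interference.
Passing tests therefore show the *analysis* is correct under its own
assumptions, not that real FFRs satisfy those assumptions.

## Statistical and numerical choices

* **Noise power is the mean of the 16 squared magnitudes.** Averaging the
  magnitudes first and squaring (an alternative reading of "square of the
  mean magnitude") does not yield an F(2, 32) statistic: under the null the
  expected squared mean magnitude is $\pi/4$ of the expected power, the
  ratio's null distribution shifts, and a nominal 1 % criterion would
  reject ~1.5 % of pure noise. With power averaging the statistic is
  exactly F(2, 32) when the bins are independent, and the test suite's
  $10^4$-draw null simulation confirms the 1.0 % ± 0.3 % rejection rate.
  The mean magnitude is still reported on the `noise_estimate` object.
* **Noise-bin correlation.** Bins 4 Hz apart are uncorrelated only when the
  window length is a multiple of 250 ms; on a 120-ms window neighboring
  bins overlap spectrally (effective denominator df below 32) and the test
  becomes slightly anti-conservative. The null-calibration simulation
  therefore uses 250-ms noise epochs, where the F(2, 32) model is exact; on
  real 140-ms epochs the criterion should be read as approximate. At the
  SNRs this pipeline targets the distinction is immaterial for detection.
* **SNR saturation by leakage.** The off-frequency noise bins also receive
  rectangular-window leakage from the response itself (the worst offsets
  sit near side-lobe peaks), so reported SNR saturates around 19–20 dB on
  120-ms windows no matter how strong the response — a property of this
  estimator family, visible in the simulated spectra tables.
* **Degenerate inputs.** Zero noise power ⇒ `present` with p = 0, flagged
  `degenerate`; all trials or subaverages rejected ⇒ explicit warnings and
  missing condition rows, never silent zeros; fewer than 3 present
  frequencies ⇒ `insufficient_points`.
* **Timing.** Durations are truncated to whole samples at 24 414 Hz; event
  times are carried in seconds to avoid rounding drift. Fitted delays are
  reported to 3 decimals (ms) in the output tables; objects keep full
  precision.

## Problem sizes

The package's heavy verification runs were sized once for convenient
desk-scale execution: the 20-replicate end-to-end study uses 160 trials in
16 subaverages of 10 per polarity, with per-trial noise scaled by
$1/\sqrt{10}$ so the per-subaverage SNR matches the ~15-dB study condition;
the null-calibration simulation uses $10^4$ 250-ms epochs at 2 kHz; oracle
equivalence uses 200 random series. Full-size simulation (1600 trials at
24 414 Hz) is the generator default and runs in tens of seconds per
condition.

## Interfaces

Functions are the interface: `run_study()` orchestrates simulation (or
reading interchange-format recordings from disk), preprocessing, spectra
and fits; `run_replicates()`/`summarize_fits()` aggregate across synthetic
listeners; `write_study_result()` exports CSV tables plus a JSON manifest;
`read_study_config()` accepts YAML or JSON configurations whose keys mirror
the constructor arguments, with the analysis constants above as defaults.

## Known limitations

* Group-delay summaries are descriptive (means with normal-approximation
  95 % CIs); mixed-effects inference over unbalanced listener data is out
  of scope.
* The generator's amplitude scale, montage weights and artifact shape are
  plausible conventions, not fitted to recordings.
* A linear phase-frequency fit cannot distinguish one source from a
  fixed-weight mixture; the contamination experiments quantify the
  resulting bias only for the microphonic case.
* No real-EEG ingestion (EDF/BDF); recordings enter via the delimited-text
  interchange format.
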