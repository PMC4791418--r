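# ffrdelay

Latency analysis of the scalp-recorded **frequency following response (FFR)**
by group delay, for auditory-neurophysiology researchers who want to ask
*where along the auditory pathway* phase locking to a sound's temporal
envelope and temporal fine structure (TFS) arises, using nothing more
invasive than a pair of EEG electrode montages.

## The method

Stimuli are three-tone complexes: equal-amplitude pure tones at
$f_c - f_m$, $f_c$ and $f_c + f_m$ (center $f_c$ = 576 Hz; modulation rates
$f_m \in \{85, 100, 115, 130, 145\}$ Hz), i.e. amplitude-modulated tones
whose envelope periodicity equals the tone spacing. Each 140-ms burst is
presented in alternating polarity. Averaging responses to the two polarities
(**addition** waveform) cancels fine-structure-locked activity and retains
the envelope-FFR at $f_m$; differencing (**subtraction** waveform) retains
TFS-locked activity (and any cochlear microphonic) at the side-tone
frequencies.

After zero-phase Butterworth band-pass filtering (60–2000 Hz) and
peak-amplitude artifact rejection (trials beyond ±60 µV, filtered
subaverages beyond ±35 µV), the response at each target frequency is an
exact-frequency DFT coefficient. A response is *present* when the F ratio of
its power (2 df) over the mean power of 16 off-frequency bins at
$f \pm \{9, 13, \ldots, 37\}$ Hz (32 df) exceeds the F(2, 32) criterion at
the 1 % level (ratio ≈ 5.34).

Across the five stimulus conditions each of three frequency regions —
modulation rates, lower side tones, upper side tones — yields up to five
phases $\phi(f)$ (cycles). After restoring the transducer-tube phase delay
(18.2 ms, i.e. adding $0.0182 f - \lfloor 0.0182 f \rfloor$ cycles), group
delay is the negated slope of the phase-frequency line:

$$\tau = -\frac{d\phi}{df} \cdot 1000 \ \text{ms}.$$

Because phases are only known modulo one cycle, and missing frequencies
leave 30- or 45-Hz gaps whose sequential-unwrapping ambiguity limits
(16.7 ms, 11.1 ms) fall inside the physiological range, the package fits
**every** unwrapping candidate within a delay-bounded search region (down to
$0.04\,\Delta x$ cycles below the lowest-frequency anchor), keeps fits with
slope in $[-0.02, 0]$ cycles/Hz and SSE < 0.05, and reports the best
surviving fit — or an honest missing value when none survives.

The study's human EEG recordings are not available, so the package ships a
synthetic scalp-recording generator (latency-shifted envelope / TFS /
cochlear-microphonic sources, montage-specific mixing, pink + white EEG
noise, artifact epochs, 16 × 100-trial subaverage blocks) whose statistical
structure matches what the analysis assumes, making every stage testable
against known ground truth.

## Worked example

Simulate a study whose ground truth is an envelope source at 8.5 ms (both
montages), an early TFS source at 4.5 ms (horizontal montage) and a later
TFS source at 8 ms (vertical montage), then recover those latencies:

```r
library(ffrdelay)

sim <- simulation_config(n_trials = 160, subaverage_size = 10,
                         noise_white_sigma = 6 / sqrt(10),
                         noise_pink_sigma = 6 / sqrt(10))
cfg <- study_config(sim = sim, seed = 1)
run_study(cfg)
#> FFR study result: 30 spectral estimates, 6 of 6 group delays fitted
#>     montage     region n_points group_delay_ms status
#>  horizontal modulation        5          8.471     ok
#>  horizontal lower_side        5          4.587     ok
#>  horizontal upper_side        5          4.476     ok
#>    vertical modulation        5          8.449     ok
#>    vertical lower_side        5          7.913     ok
#>    vertical upper_side        5          7.948     ok
```

Every fitted delay lands within ~0.1 ms of its configured source. Across
replicates ("listeners"):

```r
fits <- run_replicates(cfg, 5)
summarize_fits(fits)
#>      montage     region n mean_delay_ms ci95_halfwidth_ms
#> 2 horizontal lower_side 5          4.48            0.0440
#> 1 horizontal modulation 5          8.59            0.0990
#> 3 horizontal upper_side 5          4.53            0.0384
#> 5   vertical lower_side 5          7.94            0.0395
#> 4   vertical modulation 5          8.52            0.1309
#> 6   vertical upper_side 5          8.01            0.0314
```

The side-tone (TFS) regions show the shorter horizontal-montage latency; the
modulation (envelope) region shows the same ~8.5 ms in both montages — the
qualitative montage pattern the method is designed to expose.
`write_study_result()` exports the spectra/fit/count tables as CSV with a
JSON run manifest; `fixture_study()` writes synthetic recordings in a
delimited-text interchange format that `run_study()` can re-analyze from
disk.

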