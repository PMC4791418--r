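#' Specification of one amplitude-modulated three-tone stimulus
#'
#' A stimulus is the sum of three equal-amplitude pure tones: a center tone and
#' two side tones equidistant from it by the modulation rate `mod_rate`. The
#' spacing makes the complex amplitude-modulated with envelope periodicity
#' `mod_rate`. Each tone burst carries raised-cosine onset/offset ramps and is
#' presented in alternating polarity (all components in sine phase, or all
#' phase-inverted).
#'
#' @param mod_rate Modulation rate f_m in Hz; equals the spacing between the
#'   component tones.
#' @param center_freq Center tone frequency in Hz.
#' @param tone_ms Tone-burst duration in ms.
#' @param ramp_ms Raised-cosine ramp duration in ms (applied at onset and
#'   offset of the summed complex).
#' @param gap_after_pos_ms Silent interval after the positive-polarity burst,
#'   ms.
#' @param gap_after_neg_ms Silent interval after the negative-polarity burst,
#'   ms.
#' @param level_rms Target steady-state RMS amplitude (arbitrary linear units;
#'   absolute SPL calibration is out of scope).
#' @param fs Sample rate in Hz.
#' @param polarity `+1` (sine phase) or `-1` (phase-inverted).
#' @return An object of class `stimulus_spec`.
#' @examples
#' spec <- stimulus_spec(mod_rate = 130)
#' side_tone_frequencies(spec$center_freq, spec$mod_rate)
#' @export
stimulus_spec <- function(mod_rate,
                          center_freq = 576,
                          tone_ms = 140,
                          ramp_ms = 20,
                          gap_after_pos_ms = 120,
                          gap_after_neg_ms = 170,
                          level_rms = 1,
                          fs = 24414,
                          polarity = 1) {
  stopifnot(length(mod_rate) == 1, length(center_freq) == 1)
  if (!polarity %in% c(-1, 1)) {
    stop("polarity must be +1 or -1")
  }
  if (!(mod_rate >= 0 && mod_rate < center_freq)) {
    stop("invalid stimulus: need 0 <= mod_rate < center_freq")
  }
  if (2 * ramp_ms > tone_ms) {
    stop("invalid stimulus: ramps (2 * ramp_ms) exceed tone duration")
  }
  side <- side_tone_frequencies(center_freq, mod_rate)
  if (side[1] <= 0 || side[2] >= fs / 2) {
    stop("invalid stimulus: side tones must lie in (0, fs/2)")
  }
  structure(
    list(
      center_freq = center_freq, mod_rate = mod_rate,
      tone_ms = tone_ms, ramp_ms = ramp_ms,
      gap_after_pos_ms = gap_after_pos_ms,
      gap_after_neg_ms = gap_after_neg_ms,
      level_rms = level_rms, fs = fs, polarity = polarity
    ),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  side <- side_tone_frequencies(x$center_freq, x$mod_rate)
  cat(sprintf(
    "AM three-tone stimulus: %g + %g + %g Hz (f_m = %g Hz), polarity %+d\n",
    side[1], x$center_freq, side[2], x$mod_rate, x$polarity
  ))
  cat(sprintf(
    "  %g ms burst, %g ms ramps, RMS %g, fs %g Hz\n",
    x$tone_ms, x$ramp_ms, x$level_rms, x$fs
  ))
  invisible(x)
}

#' Side-tone frequencies of an AM three-tone complex
#'
#' The lower and upper tones are equidistant from the center tone by the
#' modulation rate.
#'
#' @param center Center tone frequency, Hz.
#' @param mod_rate Modulation rate, Hz.
#' @return Numeric length-2 vector `c(lower, upper)` in Hz.
#' @examples
#' side_tone_frequencies(576, 130) # 446, 706
#' @export
side_tone_frequencies <- function(center, mod_rate) {
  if (mod_rate < 0 || mod_rate >= center) {
    stop("invalid spec: need 0 <= mod_rate < center")
  }
  c(center - mod_rate, center + mod_rate)
}

# Hann half-window onset/offset ramps multiplying the summed complex.
raised_cosine_ramps <- function(n, n_ramp) {
  env <- rep(1, n)
  if (n_ramp > 0) {
    up <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / n_ramp))
    env[seq_len(n_ramp)] <- up
    env[n - seq_len(n_ramp) + 1] <- rev(up)
  }
  env
}

#' Synthesize one tone burst
#'
#' Sums three equal-amplitude sinusoids (lower, center, upper tone), each
#' starting in sine phase multiplied by the stimulus polarity, scales the
#' steady-state (between-ramp) RMS to `level_rms`, then applies raised-cosine
#' ramps to the summed complex.
#'
#' @param spec A [stimulus_spec()].
#' @return Numeric waveform of `floor(tone_ms/1000 * fs)` samples. Attribute
#'   `steady_idx` gives the sample indices of the unramped steady state.
#' @export
synthesize_tone <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- floor(spec$tone_ms / 1000 * spec$fs)
  n_ramp <- floor(spec$ramp_ms / 1000 * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  freqs <- c(
    spec$center_freq - spec$mod_rate,
    spec$center_freq,
    spec$center_freq + spec$mod_rate
  )
  x <- rowSums(sapply(freqs, function(f) sin(2 * pi * f * t)))
  x <- x * spec$polarity
  steady <- seq.int(n_ramp + 1, n - n_ramp)
  x <- x * spec$level_rms / sqrt(mean(x[steady]^2))
  x <- x * raised_cosine_ramps(n, n_ramp)
  attr(x, "steady_idx") <- steady
  x
}

#' Build one alternating-polarity trial
#'
#' Concatenates the positive-polarity burst, a silent gap, the phase-inverted
#' burst, and a final silent gap. Event times (the two burst onsets) are in
#' seconds to avoid sample-rounding drift.
#'
#' @param spec A [stimulus_spec()]; its `polarity` field is ignored (both
#'   polarities are generated).
#' @return List with `waveform` (numeric) and `event_times` (seconds, length
#'   2).
#' @export
make_trial_sequence <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  pos <- spec
  pos$polarity <- 1
  tone <- synthesize_tone(pos)
  attributes(tone) <- NULL
  fs <- spec$fs
  gap1 <- numeric(floor(spec$gap_after_pos_ms / 1000 * fs))
  gap2 <- numeric(floor(spec$gap_after_neg_ms / 1000 * fs))
  waveform <- c(tone, gap1, -tone, gap2)
  onset2 <- (spec$tone_ms + spec$gap_after_pos_ms) / 1000
  list(waveform = waveform, event_times = c(0, onset2))
}

#' Region frequencies across the stimulus set
#'
#' For a set of modulation rates sharing one center frequency, returns the
#' three frequency regions over which group delay is fitted: the modulation
#' rates themselves (envelope response), and the lower and upper side-tone
#' frequencies (fine-structure response), each in ascending order.
#'
#' @param mod_rates Modulation rates in Hz.
#' @param center_freq Shared center tone frequency in Hz.
#' @return Named list `modulation`, `lower_side`, `upper_side`.
#' @export
region_frequencies <- function(mod_rates, center_freq = 576) {
  list(
    modulation = sort(mod_rates),
    lower_side = sort(center_freq - mod_rates),
    upper_side = sort(center_freq + mod_rates)
  )
}

#' Export a waveform as delimited text
#'
#' One sample per line at full double precision, with a one-line header
#' comment recording the sample rate.
#'
#' @param x Numeric waveform.
#' @param fs Sample rate, Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_txt <- function(x, fs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.17g", fs), con)
  writeLines(sprintf("%.17g", as.numeric(x)), con)
  invisible(path)
}
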