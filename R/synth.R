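#' One latent response source
#'
#' The generator mixes latency-shifted copies of stimulus-locked components
#' into each montage. `tfs` and `cm` sources follow the stimulus waveform
#' itself (so they invert with stimulus polarity; the cochlear microphonic is
#' simply a near-zero-latency instance), while an `envelope` source follows
#' the polarity-invariant envelope drive.
#'
#' @param kind One of `"envelope"`, `"tfs"`, `"cm"`.
#' @param latency_ms Source latency in ms (>= 0), excluding the acoustic
#'   transducer delay, which is added separately.
#' @param gain Source gain in microvolts per unit stimulus amplitude (>= 0).
#' @return Object of class `source_config`.
#' @export
source_config <- function(kind, latency_ms, gain) {
  kind <- match.arg(kind, c("envelope", "tfs", "cm"))
  stopifnot(latency_ms >= 0, gain >= 0)
  structure(list(kind = kind, latency_ms = latency_ms, gain = gain),
            class = "source_config")
}

#' Electrode-montage mixing weights
#'
#' @param name Montage label, e.g. `"horizontal"` or `"vertical"`.
#' @param weights Nonnegative weight per source (aligned with the
#'   `sources` list of the [simulation_config()]); at least one positive.
#' @return Object of class `montage_mix`.
#' @export
montage_mix <- function(name, weights) {
  stopifnot(all(weights >= 0), any(weights > 0))
  structure(list(name = name, weights = weights), class = "montage_mix")
}

#' Configuration of the synthetic scalp-recording generator
#'
#' Defaults emulate the study conditions: blocks of 1600 trials stored as 16
#' subaverages of 100 trials per polarity, an envelope-following source at
#' 8.5 ms, an early fine-structure source at 4.5 ms seen by the horizontal
#' montage, a later one at 8 ms seen by the vertical montage, and an inert
#' (zero-gain) cochlear-microphonic source at 0.8 ms that contamination
#' experiments can switch on. Gains and noise levels are calibrated so that a
#' 100-trial subaverage has an on-frequency SNR of roughly 15 dB (the response
#' amplitude scale of real recordings is not observable in simulation).
#'
#' @param sources List of [source_config()] objects.
#' @param montages List of [montage_mix()] objects; each `weights` vector must
#'   match `length(sources)`.
#' @param noise_white_sigma White-noise standard deviation per trial, uV.
#' @param noise_pink_sigma Pink-noise (1/sqrt(f) magnitude above 1 Hz)
#'   standard deviation per trial, uV.
#' @param n_trials Trials per block (each trial yields one response per
#'   polarity).
#' @param subaverage_size Trials per stored subaverage; must divide
#'   `n_trials`.
#' @param artifact_rate Probability per trial of an added high-amplitude
#'   transient.
#' @param artifact_amp Peak amplitude of the artifact transient, uV.
#' @param transducer_delay_s Acoustic delay of the transducer/tubing chain,
#'   seconds, added to every source latency (the analysis corrects it back).
#' @param seed Integer seed making a simulation reproducible.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(sources = default_sources(),
                              montages = default_montages(),
                              noise_white_sigma = 6,
                              noise_pink_sigma = 6,
                              n_trials = 1600,
                              subaverage_size = 100,
                              artifact_rate = 0.02,
                              artifact_amp = 120,
                              transducer_delay_s = 0.0182,
                              seed = 1L) {
  stopifnot(
    length(sources) >= 1,
    all(vapply(sources, inherits, logical(1), "source_config")),
    all(vapply(montages, inherits, logical(1), "montage_mix")),
    n_trials %% subaverage_size == 0,
    artifact_rate >= 0, artifact_rate <= 1,
    noise_white_sigma >= 0, noise_pink_sigma >= 0,
    transducer_delay_s >= 0
  )
  for (m in montages) {
    if (length(m$weights) != length(sources)) {
      stop("montage '", m$name, "': weights length must match sources")
    }
  }
  structure(
    list(
      sources = sources, montages = montages,
      noise_white_sigma = noise_white_sigma,
      noise_pink_sigma = noise_pink_sigma,
      n_trials = n_trials, subaverage_size = subaverage_size,
      artifact_rate = artifact_rate, artifact_amp = artifact_amp,
      transducer_delay_s = transducer_delay_s,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' @rdname simulation_config
#' @export
default_sources <- function() {
  list(
    source_config("envelope", 8.5, 0.45),
    source_config("tfs", 4.5, 0.45),
    source_config("tfs", 8.0, 0.45),
    source_config("cm", 0.8, 0.0)
  )
}

#' @rdname simulation_config
#' @export
default_montages <- function() {
  # horizontal: early fine-structure source dominant (plus any CM);
  # vertical: later fine-structure source. Envelope source seen by both.
  list(
    montage_mix("horizontal", c(1, 1, 0, 1)),
    montage_mix("vertical",   c(1, 0, 1, 0.3))
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic FFR recording: %d trials (%d subaverages of %d) per polarity\n",
    x$n_trials, x$n_trials %/% x$subaverage_size, x$subaverage_size
  ))
  for (s in x$sources) {
    cat(sprintf("  source %-8s latency %5.2f ms  gain %.3g uV\n",
                s$kind, s$latency_ms, s$gain))
  }
  for (m in x$montages) {
    cat(sprintf("  montage %-10s weights [%s]\n", m$name,
                paste(format(m$weights), collapse = ", ")))
  }
  cat(sprintf("  noise sd white %g + pink %g uV; artifacts %g at %g uV\n",
              x$noise_white_sigma, x$noise_pink_sigma,
              x$artifact_rate, x$artifact_amp))
  invisible(x)
}

# Analytic signal via the frequency-domain construction (zero the negative
# frequencies, double the positive ones).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Envelope drive of a stimulus
#'
#' The mean-removed magnitude of the analytic signal of the stimulus
#' waveform. The magnitude is exactly invariant to stimulus polarity, which
#' makes the envelope-locked component cancel exactly under polarity
#' subtraction (and add under polarity addition).
#'
#' @param x Stimulus waveform (finite numeric vector).
#' @return Numeric drive waveform, same length as `x`.
#' @export
envelope_drive <- function(x) {
  stopifnot(all(is.finite(x)))
  env <- Mod(analytic_signal(as.numeric(x)))
  env - mean(env)
}

# Fractional-sample delay via frequency-domain phase shift, with zero padding
# so the shifted tail cannot wrap around. Output keeps the input length.
fractional_delay <- function(x, delay_s, fs) {
  n <- length(x)
  pad <- as.integer(ceiling(abs(delay_s) * fs)) + 64L
  m <- stats::nextn(n + pad, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  f <- (seq_len(m) - 1) / m
  f[f > 0.5] <- f[f > 0.5] - 1
  shift <- exp(-2i * pi * f * fs * delay_s)
  if (m %% 2 == 0) shift[m / 2 + 1] <- Re(shift[m / 2 + 1])
  Re(stats::fft(X * shift, inverse = TRUE) / m)[seq_len(n)]
}

# Pink noise: white Gaussian noise shaped by a 1/sqrt(f) magnitude filter
# above 1 Hz, normalized to unit variance, generated column-wise.
pink_noise <- function(n, ncol, fs) {
  f <- (seq_len(n) - 1) / n * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]
  mag <- 1 / sqrt(pmax(f, 1))
  mag[1] <- 0
  mag <- mag / sqrt(mean(mag^2))
  w <- matrix(stats::rnorm(n * ncol), n, ncol)
  W <- stats::mvfft(w) * mag
  Re(stats::mvfft(W, inverse = TRUE)) / n
}

# One-period 10-Hz sinusoid transient scaled to the requested peak amplitude.
artifact_pulse <- function(fs, amp) {
  n <- floor(fs / 10)
  amp * sin(2 * pi * 10 * (seq_len(n) - 1) / fs)
}

# Deterministic (noise-free) response epoch per montage x polarity.
# Returns list over montages of list(pos=, neg=) numeric vectors.
deterministic_components <- function(spec, sim) {
  pos <- spec
  pos$polarity <- 1
  tone <- synthesize_tone(pos)
  attributes(tone) <- NULL
  fs <- spec$fs
  delayed <- lapply(sim$sources, function(s) {
    base <- if (s$kind == "envelope") envelope_drive(tone) else tone
    s$gain * fractional_delay(
      base, s$latency_ms / 1000 + sim$transducer_delay_s, fs
    )
  })
  flips <- vapply(sim$sources, function(s) {
    if (s$kind == "envelope") 1 else -1
  }, numeric(1))
  lapply(sim$montages, function(m) {
    det_pos <- Reduce(`+`, Map(`*`, delayed, m$weights))
    det_neg <- Reduce(`+`, Map(`*`, delayed, m$weights * flips))
    list(pos = det_pos, neg = det_neg)
  })
}

#' Simulate per-trial scalp epochs
#'
#' Each trial epoch is the montage-weighted sum of latency-shifted source
#' components plus pink and white noise; with probability `artifact_rate` a
#' trial additionally receives a high-amplitude transient at a random
#' position. The two polarities of a trial share the deterministic component
#' pattern (fine-structure and microphonic sources sign-flip; the envelope
#' source does not) but have independent noise.
#'
#' @param spec Positive-polarity [stimulus_spec()]; the negative-polarity
#'   stimulus is its exact inversion.
#' @param sim A [simulation_config()].
#' @param seed Seed for this call; defaults to `sim$seed`. Pass `NULL` to use
#'   the current RNG state.
#' @return List (one element per montage, named) of lists with `pos` and
#'   `neg` trial matrices (`n_trials` rows, one epoch sample per column, uV).
#' @export
simulate_trials <- function(spec, sim, seed = sim$seed) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(sim, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  fs <- spec$fs
  det <- deterministic_components(spec, sim)
  n <- length(det[[1]]$pos)
  pulse <- artifact_pulse(fs, sim$artifact_amp)
  out <- vector("list", length(sim$montages))
  names(out) <- vapply(sim$montages, `[[`, character(1), "name")
  for (mi in seq_along(sim$montages)) {
    pol <- list()
    for (p in c("pos", "neg")) {
      noise <- matrix(0, n, sim$n_trials)
      if (sim$noise_white_sigma > 0) {
        noise <- noise + sim$noise_white_sigma *
          matrix(stats::rnorm(n * sim$n_trials), n, sim$n_trials)
      }
      if (sim$noise_pink_sigma > 0) {
        noise <- noise + sim$noise_pink_sigma * pink_noise(n, sim$n_trials, fs)
      }
      epochs <- noise + det[[mi]][[p]]
      if (sim$artifact_rate > 0 && length(pulse) <= n) {
        hit <- which(stats::runif(sim$n_trials) < sim$artifact_rate)
        for (tr in hit) {
          at <- sample.int(n - length(pulse) + 1L, 1L)
          idx <- seq.int(at, length.out = length(pulse))
          epochs[idx, tr] <- epochs[idx, tr] + pulse
        }
      }
      pol[[p]] <- t(epochs)
    }
    out[[mi]] <- pol
  }
  out
}

#' Collapse trials into subaverages with peak-amplitude trial rejection
#'
#' Applies the per-trial rejection (raw trials whose peak magnitude exceeds
#' `trial_limit` uV are dropped) within each consecutive block of
#' `subaverage_size` trials, then averages the surviving trials of the block.
#' Blocks losing every trial are dropped.
#'
#' @param trials Trial matrix (rows = trials).
#' @param subaverage_size Trials per block.
#' @param trial_limit Rejection threshold in uV (`Inf` disables rejection).
#' @return Matrix of subaverages (rows) with attributes `n_rejected` (trials
#'   rejected) and `n_trials_per_subaverage`.
#' @export
make_subaverages <- function(trials, subaverage_size, trial_limit = 60) {
  n_tr <- nrow(trials)
  stopifnot(n_tr %% subaverage_size == 0)
  block <- rep(seq_len(n_tr %/% subaverage_size), each = subaverage_size)
  keep <- rowSums(abs(trials) > trial_limit) == 0
  n_rej <- sum(!keep)
  counts <- tapply(keep, block, sum)
  sums <- rowsum(trials * keep, block)
  ok <- counts > 0
  sub <- sums[ok, , drop = FALSE] / as.numeric(counts[ok])
  attr(sub, "n_rejected") <- n_rej
  attr(sub, "n_trials_per_subaverage") <- as.numeric(counts[ok])
  sub
}

#' Write a recording to the delimited-text interchange format
#'
#' Writes one tab-delimited matrix (rows = subaverages or trials, columns =
#' samples, unit uV) at full double precision, plus a JSON sidecar with the
#' sample rate, per-row polarity, condition, montage, units and level.
#'
#' @param waveforms Numeric matrix, rows = records.
#' @param polarity_order Integer vector (+1/-1) per row.
#' @param fs Sample rate, Hz.
#' @param condition Modulation rate (Hz) labelling the condition.
#' @param montage Montage label.
#' @param base Path without extension; `<base>.tsv` and `<base>.json` are
#'   written.
#' @param level `"subaverage"` or `"trial"`.
#' @param derived Optional `"addition"`/`"subtraction"` tag for derived
#'   waveforms.
#' @return `base`, invisibly.
#' @export
write_recording <- function(waveforms, polarity_order, fs, condition, montage,
                            base, level = "subaverage", derived = NULL) {
  stopifnot(nrow(waveforms) == length(polarity_order))
  tsv <- paste0(base, ".tsv")
  lines <- apply(waveforms, 1, function(r) paste(sprintf("%.17g", r),
                                                 collapse = "\t"))
  ok <- tryCatch({
    writeLines(lines, tsv)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed writing ", tsv, ": ", conditionMessage(ok))
  side <- list(
    fs_hz = fs, polarity_order = as.integer(polarity_order),
    condition = condition, montage = montage, units = "uV", level = level
  )
  if (!is.null(derived)) side$derived <- derived
  jsonlite::write_json(side, paste0(base, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Read a recording written by [write_recording()]
#'
#' @param base Path without extension.
#' @return List with `waveforms` (matrix), `polarity_order`, `fs`,
#'   `condition`, `montage`, `units`, `level` and (if present) `derived`.
#' @export
read_recording <- function(base) {
  tsv <- paste0(base, ".tsv")
  js <- paste0(base, ".json")
  if (!file.exists(tsv)) stop("missing recording matrix: ", tsv)
  if (!file.exists(js)) stop("missing recording sidecar: ", js)
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  rows <- readLines(tsv)
  wf <- do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE), as.numeric))
  list(
    waveforms = wf,
    polarity_order = as.integer(side$polarity_order),
    fs = side$fs_hz, condition = side$condition, montage = side$montage,
    units = side$units, level = side$level, derived = side$derived
  )
}

#' Generate and write a full synthetic study
#'
#' Simulates every modulation-rate condition for every montage, collapses the
#' trials into subaverages (after per-trial rejection), and writes one
#' interchange-format recording per montage x condition. The default montage
#' parameterization gives the horizontal montage a shorter-latency
#' fine-structure mix than the vertical montage.
#'
#' @param sim A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param mod_rates Modulation rates, Hz.
#' @param stim Arguments forwarded to [stimulus_spec()] (named list).
#' @param trial_limit Per-trial rejection threshold, uV.
#' @return Data frame manifest (condition, montage, base path, subaverage and
#'   rejection counts), invisibly.
#' @export
fixture_study <- function(sim, dir, mod_rates = c(85, 100, 115, 130, 145),
                          stim = list(), trial_limit = 60) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list()
  for (ci in seq_along(mod_rates)) {
    spec <- do.call(stimulus_spec, c(list(mod_rate = mod_rates[ci]), stim))
    trials <- simulate_trials(spec, sim, seed = sim$seed + ci)
    for (m in names(trials)) {
      sub_pos <- make_subaverages(trials[[m]]$pos, sim$subaverage_size,
                                  trial_limit)
      sub_neg <- make_subaverages(trials[[m]]$neg, sim$subaverage_size,
                                  trial_limit)
      base <- file.path(dir, sprintf("fm%03d_%s", mod_rates[ci], m))
      write_recording(
        rbind(sub_pos, sub_neg),
        c(rep(1L, nrow(sub_pos)), rep(-1L, nrow(sub_neg))),
        spec$fs, mod_rates[ci], m, base
      )
      manifest[[length(manifest) + 1L]] <- data.frame(
        condition = mod_rates[ci], montage = m, base = base,
        n_subaverages_pos = nrow(sub_pos), n_subaverages_neg = nrow(sub_neg),
        n_trials_rejected = attr(sub_pos, "n_rejected") +
          attr(sub_neg, "n_rejected")
      )
    }
  }
  invisible(do.call(rbind, manifest))
}
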