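test_that("envelope drive is exactly polarity-invariant and peaks at f_m", {
  spec <- stimulus_spec(130)
  x <- synthesize_tone(spec)
  d_pos <- envelope_drive(x)
  d_neg <- envelope_drive(-x)
  expect_identical(d_pos, d_neg)
  fr <- seq(60, 600, by = 5)
  mags <- vapply(fr, function(f) {
    Mod(dft_at(d_pos, spec$fs, f, window_ms = c(20, 140)))
  }, numeric(1))
  expect_equal(fr[which.max(mags)], 130)
})

test_that("an unmodulated tone has (near) zero envelope drive", {
  fs <- 24414
  t <- (0:4999) / fs
  d <- envelope_drive(sin(2 * pi * 576 * t))
  interior <- 500:4500
  expect_lt(max(abs(d[interior])), 0.01)
})

test_that("simulation is reproducible under a fixed seed", {
  spec <- stimulus_spec(100)
  sim <- simulation_config(n_trials = 8, subaverage_size = 4,
                           artifact_rate = 0.5)
  a <- simulate_trials(spec, sim, seed = 42)
  b <- simulate_trials(spec, sim, seed = 42)
  expect_identical(a, b)
})

test_that("polarity combination cancels the right sources exactly", {
  spec <- stimulus_spec(115)
  mk <- function(kind) {
    simulation_config(
      sources = list(source_config(kind, 6, 0.5)),
      montages = list(montage_mix("horizontal", 1)),
      noise_white_sigma = 0, noise_pink_sigma = 0,
      n_trials = 4, subaverage_size = 2, artifact_rate = 0
    )
  }
  energy <- function(v) sum(v^2)
  # envelope source: subtraction waveform vanishes
  tr <- simulate_trials(spec, mk("envelope"))$horizontal
  dw <- combine_polarity(colMeans(tr$pos), colMeans(tr$neg))
  expect_lt(energy(dw$subtraction), 1e-6 * energy(dw$addition))
  # fine-structure source: addition waveform vanishes
  tr <- simulate_trials(spec, mk("tfs"))$horizontal
  dw <- combine_polarity(colMeans(tr$pos), colMeans(tr$neg))
  expect_lt(energy(dw$addition), 1e-6 * energy(dw$subtraction))
})

test_that("no trial exceeds the rejection limit at default gains and noise", {
  spec <- stimulus_spec(85)
  sim <- simulation_config(n_trials = 200, subaverage_size = 100,
                           artifact_rate = 0)
  tr <- simulate_trials(spec, sim, seed = 3)
  peaks <- vapply(tr, function(m) max(abs(m$pos), abs(m$neg)), numeric(1))
  expect_true(all(peaks <= 60))
})

test_that("artifact epochs are caught by trial rejection", {
  spec <- stimulus_spec(85)
  sim <- simulation_config(n_trials = 20, subaverage_size = 10,
                           noise_white_sigma = 1, noise_pink_sigma = 1,
                           artifact_rate = 1, artifact_amp = 120)
  tr <- simulate_trials(spec, sim, seed = 9)$horizontal$pos
  expect_warning(kept <- reject_trials(tr, limit = 60), "rejected")
  expect_identical(nrow(kept), 0L)
  expect_identical(attr(kept, "n_rejected"), 20L)
})

test_that("averaging N subaverages raises SNR by about 10*log10(N) dB", {
  fs <- 2000
  n <- 500
  t <- (seq_len(n) - 1) / fs
  sig <- 0.05 * cos(2 * pi * 576 * t)
  set.seed(21)
  snr_at <- function(n_sub) {
    mean(replicate(30, {
      sub <- replicate(n_sub, sig + rnorm(n, sd = 0.5))
      est <- spectral_estimate(rowMeans(sub), fs, 576)
      est$snr_db
    }))
  }
  gain16 <- snr_at(16) - snr_at(1)
  expect_equal(gain16, 10 * log10(16), tolerance = 3)
})

test_that("fixture studies have full structure and round-trip bit-exactly", {
  dir <- file.path(tempdir(), "fixture-study")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  sim <- simulation_config(n_trials = 32, subaverage_size = 2,
                           noise_white_sigma = 2, noise_pink_sigma = 2,
                           artifact_rate = 0, seed = 4)
  man <- fixture_study(sim, dir)
  expect_identical(nrow(man), 10L) # 5 conditions x 2 montages
  expect_setequal(unique(man$montage), c("horizontal", "vertical"))
  expect_true(all(man$n_subaverages_pos == 16)) # 2 polarities x 16 each
  expect_true(all(man$n_subaverages_neg == 16))
  rec <- read_recording(man$base[1])
  expect_identical(length(rec$polarity_order), 32L)
  expect_equal(rec$fs, 24414)
  # round trip: write what was read, read it back, compare bit-for-bit
  base2 <- file.path(dir, "copy")
  write_recording(rec$waveforms, rec$polarity_order, rec$fs, rec$condition,
                  rec$montage, base2)
  rec2 <- read_recording(base2)
  expect_identical(rec2$waveforms, rec$waveforms)
})

test_that("missing recording files are reported with their path", {
  expect_error(read_recording(file.path(tempdir(), "nope")), "nope")
})
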