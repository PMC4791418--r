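test_that("dft_at follows the cosine-at-window-onset phase convention", {
  fs <- 10000
  t <- (0:9999) / fs
  co <- dft_at(2 * cos(2 * pi * 500 * t), fs, 500)
  expect_equal(Mod(co), 2, tolerance = 1e-9)
  expect_equal(sin(Arg(co)), 0, tolerance = 1e-9)
  # sine lags cosine by a quarter cycle -> phase 0.75 cycles
  co <- dft_at(sin(2 * pi * 500 * t), fs, 500)
  expect_equal((Arg(co) / (2 * pi)) %% 1, 0.75, tolerance = 1e-9)
  expect_error(dft_at(t, fs, 5000), "Nyquist")
  expect_error(dft_at(t, fs, 0), "positive")
})

test_that("components are resolved exactly over integer-cycle windows", {
  fs <- 5000
  t <- (0:2499) / fs # 0.5 s: 446 and 706 Hz both land on whole cycles
  x <- 1.5 * cos(2 * pi * 446 * t) + 0.7 * cos(2 * pi * 706 * t)
  expect_equal(Mod(dft_at(x, fs, 446)), 1.5, tolerance = 1e-6)
  expect_equal(Mod(dft_at(x, fs, 706)), 0.7, tolerance = 1e-6)
})

test_that("dft_at matches the brute-force correlation oracle", {
  set.seed(101)
  for (i in 1:10) {
    x <- rnorm(1000)
    fs <- 2000
    f <- runif(1, 50, 900)
    a <- dft_at(x, fs, f)
    b <- brute_dft(x, fs, f)
    expect_lt(Mod(a - b) / Mod(b), 1e-10)
  }
})

test_that("epoch phase referencing recovers the latency of a delayed tone", {
  fs <- 24414
  tau <- 0.006
  t <- (0:3416) / fs
  x <- cos(2 * pi * 400 * (t - tau)) * (t >= tau)
  co <- dft_at(x, fs, 400, window_ms = c(20, 140), phase_ref = "epoch")
  ph <- (Arg(co) / (2 * pi)) %% 1
  expect_equal(ph, (-400 * tau) %% 1, tolerance = 5e-3)
})

test_that("noise floor has 16 offsets, 32 df, and vanishes for a pure tone", {
  fs <- 4000
  t <- (0:3999) / fs # 1 s: target and all 4-Hz-grid offsets are whole cycles
  x <- 3 * cos(2 * pi * 576 * t)
  nf <- noise_floor(x, fs, 576)
  expect_length(nf$offsets, 16)
  expect_identical(nf$df, 32L)
  expect_identical(nf$offsets, c(-rev(seq(9, 37, 4)), seq(9, 37, 4)))
  expect_lt(nf$mean_magnitude, 1e-6 * Mod(dft_at(x, fs, 576)))
  expect_error(noise_floor(x, fs, 30), "below 0")
})

test_that("under white noise the on-frequency power matches the floor", {
  set.seed(55)
  fs <- 2000
  n <- 500
  draws <- 400
  sig <- numeric(draws)
  noi <- numeric(draws)
  for (i in seq_len(draws)) {
    x <- rnorm(n)
    sig[i] <- Mod(dft_at(x, fs, 576))^2
    noi[i] <- noise_floor(x, fs, 576)$noise_power
  }
  expect_equal(mean(sig) / mean(noi), 1, tolerance = 0.15)
})

test_that("presence test implements the F(2,32) criterion", {
  expect_equal(round(presence_threshold(0.01), 2), 5.34)
  thr <- presence_threshold(0.01)
  just_under <- presence_test(thr * 0.999, 1)
  just_over <- presence_test(thr * 1.001, 1)
  expect_false(just_under$present)
  expect_true(just_over$present)
  expect_false(presence_test(1, 1)$present)
  degen <- presence_test(1, 0)
  expect_true(degen$present)
  expect_true(degen$degenerate)
  expect_identical(degen$p_value, 0)
})

test_that("snr_db converts power ratios", {
  expect_equal(snr_db(2, 2), 0)
  expect_equal(snr_db(10, 1), 10)
  expect_equal(snr_db(5.336, 1), 7.27, tolerance = 0.005)
  expect_error(snr_db(0, 1), "positive")
})

test_that("spectral_estimate flags a clear tone and wraps phase to [0,1)", {
  fs <- 4000
  t <- (0:3999) / fs
  set.seed(8)
  x <- 2 * cos(2 * pi * 576 * t) + rnorm(length(t), sd = 0.5)
  est <- spectral_estimate(x, fs, 576)
  expect_true(est$present)
  expect_equal(est$magnitude, 2, tolerance = 0.1)
  expect_gte(est$phase_cycles, 0)
  expect_lt(est$phase_cycles, 1)
  expect_true(abs(est$phase_cycles) < 0.05 || abs(est$phase_cycles - 1) < 0.05)
  df <- as.data.frame(est)
  expect_identical(names(df)[1:3],
                   c("freq_hz", "magnitude_uv", "phase_cycles"))
})
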