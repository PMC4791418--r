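test_that("transducer correction restores the fractional delay phase", {
  expect_equal(correct_transducer_delay(0, 1000), 0.2)
  expect_equal(correct_transducer_delay(0.4, 1000, delay = 0), 0.4)
  expect_equal(correct_transducer_delay(0.1, 85), 0.1 + (0.0182 * 85) %% 1)
})

test_that("ambiguity limits follow the half-cycle rule", {
  expect_equal(ambiguity_limit(15), 1000 / 30)
  expect_equal(ambiguity_limit(30), 1000 / 60)
  expect_equal(ambiguity_limit(45), 1000 / 90)
  expect_error(ambiguity_limit(0), "positive")
})

test_that("candidate enumeration depth scales with anchor distance", {
  cfg <- unwrap_search_config()
  # equal phases: anchor distance 60 Hz admits offsets {0, 1, 2}
  s <- phase_series("modulation", c(85, 100, 145), rep(0.2, 3))
  offs <- candidate_unwrappings(s, cfg)
  expect_setequal(unique(offs[, "f145"]), 0:2)
  expect_setequal(unique(offs[, "f100"]), 0L)
  # distances 15 and 30 Hz: 1 x 2 combinations
  s <- phase_series("modulation", c(85, 100, 115), rep(0.2, 3))
  expect_identical(nrow(candidate_unwrappings(s, cfg)), 2L)
  # equal phases, small distances: single all-zero candidate
  s <- phase_series("modulation", c(85, 95, 105), rep(0.2, 3))
  offs <- candidate_unwrappings(s, cfg)
  expect_identical(nrow(offs), 1L)
  expect_true(all(offs == 0L))
  expect_error(
    candidate_unwrappings(
      phase_series("modulation", c(85, 100, 115), rep(0, 3),
                   present = c(TRUE, TRUE, FALSE)), cfg),
    "insufficient"
  )
})

test_that("the candidate set always contains the true unwrapping", {
  cfg <- unwrap_search_config()
  set.seed(77)
  for (i in 1:50) {
    slope <- runif(1, -0.0199, -0.0001)
    freqs <- sort(sample(c(85, 100, 115, 130, 145), sample(3:5, 1)))
    ser <- delay_series(freqs, slope, intercept = runif(1))
    offs <- candidate_unwrappings(ser, cfg)
    f <- c(attr(offs, "anchor_freq"), attr(offs, "freqs"))
    truth <- attr(offs, "anchor_phase") + slope * (f[-1] - f[1])
    needed <- round(attr(offs, "initial_phases") - truth)
    hit <- apply(offs, 1, function(k) all(k == needed))
    expect_true(any(hit))
  }
})

test_that("noiseless delays are recovered exactly, including across gaps", {
  cfg <- unwrap_search_config()
  masks <- list(c(85, 100, 115, 130, 145), c(85, 115, 145),
                c(85, 130, 145), c(85, 100, 145))
  for (slope in seq(-0.0195, -0.0005, length.out = 12)) {
    for (freqs in masks) {
      fit <- fit_group_delay(delay_series(freqs, slope), cfg)
      expect_identical(fit$status, "ok")
      expect_lt(abs(fit$slope - slope), 1e-12)
    }
  }
  # known-value checks
  f5 <- c(85, 100, 115, 130, 145)
  fit <- fit_group_delay(delay_series(f5, -0.008), cfg)
  expect_equal(fit$group_delay, 8, tolerance = 1e-9)
  expect_lt(fit$sse, 1e-20)
  fit <- fit_group_delay(delay_series(c(85, 130, 145), -0.005), cfg)
  expect_equal(fit$group_delay, 5, tolerance = 1e-9)
})

test_that("delays outside the 0-20 ms window are refused", {
  fit <- fit_group_delay(delay_series(c(85, 100, 115, 130, 145), -0.025))
  expect_identical(fit$status, "no_valid_fit")
  expect_true(is.na(fit$group_delay))
  # slightly positive slopes (negative delay) are refused too
  fit <- fit_group_delay(delay_series(c(85, 100, 115, 130, 145), 0.002))
  expect_identical(fit$status, "no_valid_fit")
})

test_that("exhaustive search defeats the sequential ambiguity limit", {
  # 14-ms delay across a 45-Hz gap: above the 11.1-ms sequential limit
  freqs <- c(85, 130, 145)
  expect_lt(ambiguity_limit(45), 14)
  fit <- fit_group_delay(delay_series(freqs, -0.014))
  expect_identical(fit$status, "ok")
  expect_equal(fit$group_delay, 14, tolerance = 1e-9)
})

test_that("fit equals the brute-force enumeration oracle", {
  cfg <- unwrap_search_config()
  set.seed(303)
  grids <- list(c(85, 100, 115, 130, 145), sort(576 - c(85, 100, 115, 130, 145)),
                576 + c(85, 100, 115, 130, 145))
  n_ok <- 0
  for (i in 1:200) {
    grid <- grids[[sample.int(3, 1)]]
    freqs <- sort(sample(grid, sample(3:5, 1)))
    ser <- phase_series("modulation", freqs, runif(length(freqs)))
    fit <- fit_group_delay(ser, cfg)
    oracle <- brute_fit(ser, cfg)
    if (is.null(oracle)) {
      expect_identical(fit$status, "no_valid_fit")
    } else {
      expect_identical(fit$status, "ok")
      expect_lt(abs(fit$slope - oracle$slope), 1e-9)
      expect_lt(abs(fit$sse - oracle$sse), 1e-9)
      n_ok <- n_ok + 1
    }
  }
  expect_gt(n_ok, 20) # the comparison exercised real winners
})

test_that("small phase noise degrades the delay estimate gracefully", {
  cfg <- unwrap_search_config()
  freqs <- c(85, 100, 115, 130, 145)
  set.seed(99)
  within_1ms <- replicate(1000, {
    slope <- runif(1, -0.018, -0.002)
    ph <- (0.3 + slope * freqs + rnorm(5, sd = 0.02)) %% 1
    fit <- fit_group_delay(phase_series("modulation", freqs, ph), cfg)
    fit$status == "ok" && abs(fit$group_delay - (-slope * 1000)) <= 1
  })
  expect_gte(mean(within_1ms), 0.95)
})

test_that("region series carry presence and the transducer correction", {
  cfg <- unwrap_search_config()
  est <- data.frame(
    freq = c(145, 85, 115, 100, 130), # unordered on purpose
    phase_cycles = c(0.5, 0.1, 0.3, 0.2, 0.4),
    present = c(TRUE, TRUE, FALSE, TRUE, FALSE)
  )
  ser <- region_phase_series(est, "modulation", cfg)
  expect_equal(ser$freqs, c(85, 100, 115, 130, 145))
  expect_identical(ser$present, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(ser$phase_cycles[1], 0.1 + (0.0182 * 85) %% 1)
  # 3 of 5 present supports a fit; 2 of 5 does not
  expect_identical(sum(ser$present), 3L)
  ser2 <- ser
  ser2$present[5] <- FALSE
  fit <- fit_group_delay(ser2, cfg)
  expect_identical(fit$status, "insufficient_points")
  # an end-to-end linear series through the correction: source at 6 ms plus
  # an 18.2-ms chain delay, measured phases, corrected, recovered
  freqs <- c(85, 100, 115, 130, 145)
  measured <- (-(0.006 + 0.0182) * freqs) %% 1
  ser3 <- region_phase_series(
    data.frame(freq = freqs, phase_cycles = measured, present = TRUE),
    "modulation", cfg
  )
  fit3 <- fit_group_delay(ser3, cfg)
  expect_equal(fit3$group_delay, 6, tolerance = 1e-9)
})
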