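# Independent oracles and small generators shared across tests.

# Brute-force Fourier coefficient: explicit accumulation loop, separate
# cosine/sine sums (independent of the vectorized implementation).
brute_dft <- function(x, fs, freq) {
  n <- length(x)
  re <- 0
  im <- 0
  for (i in seq_len(n)) {
    ang <- 2 * pi * freq * (i - 1) / fs
    re <- re + x[i] * cos(ang)
    im <- im - x[i] * sin(ang)
  }
  complex(real = re, imaginary = im) * 2 / n
}

# Brute-force constrained-unwrapping fit: enumerates candidate phase VALUES
# (rather than integer offsets) for each non-anchor point, fits with lm(),
# applies the slope/SSE bounds and picks the minimum-SSE survivor with the
# smaller-|slope| tie rule. Returns NULL when nothing survives.
brute_fit <- function(series, cfg) {
  f <- series$freqs[series$present]
  p <- series$phase_cycles[series$present] %% 1
  p0 <- p[1]
  cands <- lapply(seq_along(f)[-1], function(i) {
    dx <- f[i] - f[1]
    lo <- p0 - cfg$search_coeff * dx - 1e-9
    hi <- p0 + (p[i] - p0) %% 1 + 1e-9
    m <- seq(floor(lo - p[i]) - 1, ceiling(hi - p[i]) + 1)
    v <- p[i] + m
    v[v >= lo & v <= hi]
  })
  grid <- expand.grid(cands)
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    y <- c(p0, as.numeric(grid[r, ]))
    m <- stats::lm(y ~ f)
    sl <- unname(stats::coef(m)[2])
    sse <- sum(stats::resid(m)^2)
    if (sl < cfg$slope_min - 1e-12 || sl > cfg$slope_max + 1e-12 ||
        sse >= cfg$sse_max) {
      next
    }
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && abs(sl) < abs(best$slope))) {
      best <- list(slope = sl, sse = sse)
    }
  }
  best
}

# Wrapped phases from a pure delay: slope in cycles/Hz (negative), anchor
# intercept in cycles.
delay_series <- function(freqs, slope, intercept = 0.3,
                         present = rep(TRUE, length(freqs)),
                         region = "modulation") {
  phase_series(region, freqs, (intercept + slope * freqs) %% 1, present)
}

# Small quiet simulation used by pipeline-level tests.
tiny_sim <- function(...) {
  simulation_config(
    n_trials = 32, subaverage_size = 4,
    noise_white_sigma = 0.4, noise_pink_sigma = 0.4,
    artifact_rate = 0, ...
  )
}
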