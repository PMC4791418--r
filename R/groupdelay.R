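#' Restore the transducer phase delay
#'
#' The acoustic chain (earphone plus tubing) delays the stimulus by a fixed
#' time, tilting the measured phase-versus-frequency slope. The correction
#' adds `delay * freq - floor(delay * freq)` cycles to the measured phase:
#' the fractional part of the delay phase is restored, while the redundant
#' whole cycles (irrelevant before unwrapping) are dropped.
#'
#' @param phase_cycles Measured phase in cycles.
#' @param freq Frequency, Hz (> 0).
#' @param delay Transducer group delay in seconds (default 0.0182).
#' @return Corrected phase in cycles (not reduced modulo 1).
#' @export
correct_transducer_delay <- function(phase_cycles, freq, delay = 0.0182) {
  stopifnot(all(freq > 0), delay >= 0)
  phase_cycles + (delay * freq - floor(delay * freq))
}

#' Ambiguity limit of sequential phase unwrapping
#'
#' The group delay at which the phases of two components `spacing` Hz apart
#' differ by exactly half a cycle. Beyond it, sequential (nearest-value)
#' unwrapping becomes ambiguous, which is why the exhaustive delay-bounded
#' search is used instead.
#'
#' @param spacing Frequency spacing in Hz (> 0).
#' @return Delay limit in ms: `1000 / (2 * spacing)`.
#' @examples
#' ambiguity_limit(15) # 33.3 ms
#' ambiguity_limit(45) # 11.1 ms
#' @export
ambiguity_limit <- function(spacing) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  1000 / (2 * spacing)
}

#' Search configuration for delay-bounded phase unwrapping
#'
#' @param delay_min,delay_max Acceptable group-delay range, ms.
#' @param slope_min,slope_max Acceptable fitted slope range, cycles/Hz
#'   (`slope_min = -delay_max/1000`).
#' @param sse_max Maximum accepted sum of squared residuals, squared cycles.
#' @param search_coeff Depth of the candidate enumeration in cycles per Hz of
#'   anchor distance: candidate phase values reach down to
#'   `search_coeff * dx` cycles below the anchor phase (twice the slope
#'   bound, leaving room for residual error around the fit).
#' @param min_points Minimum number of present frequencies for a fit.
#' @param transducer_delay Transducer group delay, seconds, for
#'   [region_phase_series()].
#' @return Object of class `unwrap_search_config`.
#' @export
unwrap_search_config <- function(delay_min = 0, delay_max = 20,
                                 slope_min = -0.02, slope_max = 0,
                                 sse_max = 0.05, search_coeff = 0.04,
                                 min_points = 3, transducer_delay = 0.0182) {
  stopifnot(
    delay_min < delay_max,
    isTRUE(all.equal(slope_min, -delay_max / 1000)),
    search_coeff >= -slope_min,
    min_points >= 2
  )
  structure(
    list(
      delay_min = delay_min, delay_max = delay_max,
      slope_min = slope_min, slope_max = slope_max,
      sse_max = sse_max, search_coeff = search_coeff,
      min_points = as.integer(min_points),
      transducer_delay = transducer_delay
    ),
    class = "unwrap_search_config"
  )
}

#' Phase series over one frequency region
#'
#' @param region `"modulation"`, `"lower_side"` or `"upper_side"`.
#' @param freqs Strictly increasing frequencies, Hz.
#' @param phase_cycles Phase per frequency, cycles (used modulo 1).
#' @param present Logical per frequency: passed the presence criterion.
#' @return Object of class `phase_series`.
#' @export
phase_series <- function(region, freqs, phase_cycles,
                         present = rep(TRUE, length(freqs))) {
  region <- match.arg(region, c("modulation", "lower_side", "upper_side"))
  stopifnot(
    length(freqs) == length(phase_cycles),
    length(freqs) == length(present),
    all(diff(freqs) > 0)
  )
  structure(
    list(region = region, freqs = freqs,
         phase_cycles = phase_cycles, present = present),
    class = "phase_series"
  )
}

#' Assemble a region's phase series from per-frequency spectral estimates
#'
#' Orders the estimates by frequency, applies the transducer phase
#' correction, and carries the presence mask. A region supports a group-delay
#' fit only when at least `cfg$min_points` (three by default) of its
#' frequencies passed the presence criterion; [fit_group_delay()] reports
#' `insufficient_points` otherwise.
#'
#' @param estimates Data frame with columns `freq`, `phase_cycles`,
#'   `present` (e.g. rows built from [spectral_estimate()] objects).
#' @param region Region label, see [phase_series()].
#' @param cfg An [unwrap_search_config()]; supplies the transducer delay.
#' @return A [phase_series()].
#' @export
region_phase_series <- function(estimates, region,
                                cfg = unwrap_search_config()) {
  ord <- order(estimates$freq)
  f <- estimates$freq[ord]
  ph <- correct_transducer_delay(estimates$phase_cycles[ord], f,
                                 cfg$transducer_delay)
  phase_series(region, f, ph, as.logical(estimates$present[ord]))
}

# Initial above-anchor unwrapping: for each non-anchor point, the smallest
# value congruent to its phase (mod 1) that is >= the anchor phase.
initial_unwrap <- function(p_anchor, p_other) {
  p_anchor + (p_other - p_anchor) %% 1
}

#' Enumerate candidate unwrappings of a phase series
#'
#' Anchored at the lowest present frequency (whose phase is fixed at its
#' principal value), each other present point is first unwrapped to the
#' nearest congruent value at or above the anchor phase; integer cycles are
#' then successively subtracted. All values reaching down to
#' `search_coeff * dx` cycles below the anchor phase are kept, where `dx` is
#' the point's frequency distance from the anchor; this region is guaranteed
#' to contain the true unwrapping for any delay up to
#' `1000 * search_coeff` ms.
#'
#' @param series A [phase_series()].
#' @param cfg An [unwrap_search_config()].
#' @return Integer matrix, one row per candidate, one column per non-anchor
#'   present point (cycles subtracted from the initial unwrapping).
#'   Attributes: `anchor_freq`, `anchor_phase`, `freqs` (non-anchor present
#'   frequencies), `initial_phases`.
#' @export
candidate_unwrappings <- function(series, cfg = unwrap_search_config()) {
  stopifnot(inherits(series, "phase_series"))
  f <- series$freqs[series$present]
  p <- series$phase_cycles[series$present] %% 1
  if (length(f) < cfg$min_points) {
    stop("insufficient present points (", length(f), " < ",
         cfg$min_points, ")")
  }
  p[1] <- p[1] # anchor stays at principal value
  dx <- f[-1] - f[1]
  init <- initial_unwrap(p[1], p[-1])
  frac <- init - p[1]
  k_max <- floor(frac + cfg$search_coeff * dx + 1e-9)
  grid <- expand.grid(lapply(k_max, function(k) 0:k))
  offs <- as.matrix(grid)
  dimnames(offs) <- list(NULL, sprintf("f%g", f[-1]))
  storage.mode(offs) <- "integer"
  attr(offs, "anchor_freq") <- f[1]
  attr(offs, "anchor_phase") <- p[1]
  attr(offs, "freqs") <- f[-1]
  attr(offs, "initial_phases") <- init
  offs
}

# Closed-form OLS of y on x: returns slope, intercept, sse.
ols_line <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  slope <- sum(dx * (y - my)) / sum(dx^2)
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  c(slope = slope, intercept = intercept, sse = sum(res^2))
}

#' Fit group delay by exhaustive constrained unwrapping
#'
#' Fits an ordinary least-squares line (phase in cycles versus frequency in
#' Hz) to every candidate unwrapping from [candidate_unwrappings()], discards
#' fits whose slope falls outside `[slope_min, slope_max]` or whose sum of
#' squared residuals reaches `sse_max`, and selects the surviving candidate
#' with the smallest SSE (ties broken toward the smaller `|slope|`). The
#' group delay is `-slope * 1000` ms. When no candidate survives, the status
#' is `no_valid_fit` and no delay is reported, mirroring the missing group
#' delays of real recordings.
#'
#' @param series A [phase_series()].
#' @param cfg An [unwrap_search_config()].
#' @return Object of class `group_delay_fit`: `status` (`"ok"`,
#'   `"insufficient_points"` or `"no_valid_fit"`), `offsets`, `slope`
#'   (cycles/Hz), `intercept`, `sse`, `group_delay` (ms), `n_points`,
#'   `region`.
#' @export
fit_group_delay <- function(series, cfg = unwrap_search_config()) {
  stopifnot(inherits(series, "phase_series"))
  n_present <- sum(series$present)
  empty <- list(
    status = "insufficient_points", offsets = NULL, slope = NA_real_,
    intercept = NA_real_, sse = NA_real_, group_delay = NA_real_,
    n_points = n_present, region = series$region
  )
  if (n_present < cfg$min_points) {
    return(structure(empty, class = "group_delay_fit"))
  }
  offs <- candidate_unwrappings(series, cfg)
  f <- c(attr(offs, "anchor_freq"), attr(offs, "freqs"))
  p0 <- attr(offs, "anchor_phase")
  init <- attr(offs, "initial_phases")
  best <- NULL
  for (i in seq_len(nrow(offs))) {
    y <- c(p0, init - offs[i, ])
    fit <- ols_line(f, y)
    if (fit["slope"] < cfg$slope_min - 1e-12 ||
        fit["slope"] > cfg$slope_max + 1e-12 ||
        fit["sse"] >= cfg$sse_max) {
      next
    }
    if (is.null(best) ||
        fit["sse"] < best$fit["sse"] - 1e-12 ||
        (abs(fit["sse"] - best$fit["sse"]) <= 1e-12 &&
         abs(fit["slope"]) < abs(best$fit["slope"]))) {
      best <- list(fit = fit, offsets = offs[i, ])
    }
  }
  if (is.null(best)) {
    empty$status <- "no_valid_fit"
    return(structure(empty, class = "group_delay_fit"))
  }
  structure(
    list(
      status = "ok", offsets = best$offsets,
      slope = unname(best$fit["slope"]),
      intercept = unname(best$fit["intercept"]),
      sse = unname(best$fit["sse"]),
      group_delay = -unname(best$fit["slope"]) * 1000,
      n_points = n_present, region = series$region
    ),
    class = "group_delay_fit"
  )
}

#' @export
print.group_delay_fit <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf(
      "group delay %.3f ms (%s region, %d points, slope %.6f cyc/Hz, SSE %.2g)\n",
      x$group_delay, x$region, x$n_points, x$slope, x$sse
    ))
  } else {
    cat(sprintf("no group delay (%s region): %s (%d points)\n",
                x$region, x$status, x$n_points))
  }
  invisible(x)
}
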