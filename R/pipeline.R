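#' Configuration of a full study run
#'
#' Bundles stimulus defaults, analysis settings and either a simulation
#' configuration or a directory of interchange-format recordings.
#'
#' @param mod_rates Modulation rates (Hz), one per condition.
#' @param center_freq Center tone frequency, Hz.
#' @param tone_ms,ramp_ms,gap_after_pos_ms,gap_after_neg_ms,level_rms,fs
#'   Stimulus settings, see [stimulus_spec()].
#' @param window_ms Spectral analysis window `c(start, end)` in ms relative
#'   to the epoch (stimulus) onset; defaults to the between-ramp steady
#'   state. Phases are referenced to the epoch onset.
#' @param alpha Presence-test significance level.
#' @param trial_limit Per-trial rejection threshold, uV.
#' @param subaverage_limit Post-filter subaverage rejection threshold, uV.
#' @param filter_low,filter_high,filter_order Band-pass settings.
#' @param unwrap An [unwrap_search_config()].
#' @param sim A [simulation_config()], used when `recordings_dir` is `NULL`.
#' @param recordings_dir Optional directory of recordings written by
#'   [fixture_study()]; when given, data are read instead of simulated.
#' @param seed Integer master seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(mod_rates = c(85, 100, 115, 130, 145),
                         center_freq = 576,
                         tone_ms = 140, ramp_ms = 20,
                         gap_after_pos_ms = 120, gap_after_neg_ms = 170,
                         level_rms = 1, fs = 24414,
                         window_ms = c(20, 140),
                         alpha = 0.01,
                         trial_limit = 60, subaverage_limit = 35,
                         filter_low = 60, filter_high = 2000,
                         filter_order = 4,
                         unwrap = unwrap_search_config(),
                         sim = simulation_config(),
                         recordings_dir = NULL,
                         seed = 1L) {
  stopifnot(length(mod_rates) >= 1, inherits(unwrap, "unwrap_search_config"))
  if (is.null(recordings_dir)) {
    stopifnot(inherits(sim, "simulation_config"))
  } else if (!dir.exists(recordings_dir)) {
    stop("recordings_dir does not exist: ", recordings_dir)
  }
  structure(
    list(
      mod_rates = mod_rates, center_freq = center_freq,
      tone_ms = tone_ms, ramp_ms = ramp_ms,
      gap_after_pos_ms = gap_after_pos_ms,
      gap_after_neg_ms = gap_after_neg_ms,
      level_rms = level_rms, fs = fs,
      window_ms = window_ms, alpha = alpha,
      trial_limit = trial_limit, subaverage_limit = subaverage_limit,
      filter_low = filter_low, filter_high = filter_high,
      filter_order = filter_order,
      unwrap = unwrap, sim = sim, recordings_dir = recordings_dir,
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Read a study configuration from a YAML or JSON file
#'
#' Top-level keys follow the [study_config()] arguments; `unwrap` and `sim`
#' may be given as nested maps of [unwrap_search_config()] /
#' [simulation_config()] arguments, with simulation sources as a list of
#' `{kind, latency_ms, gain}` maps and montages as `{name, weights}` maps.
#'
#' @param path File path ending in `.yaml`/`.yml` (requires the `yaml`
#'   package) or `.json`.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
  if (!is.null(raw$unwrap)) {
    raw$unwrap <- do.call(unwrap_search_config, raw$unwrap)
  }
  if (!is.null(raw$sim)) {
    if (!is.null(raw$sim$sources)) {
      raw$sim$sources <- lapply(raw$sim$sources, function(s) {
        do.call(source_config, as.list(s))
      })
    }
    if (!is.null(raw$sim$montages)) {
      raw$sim$montages <- lapply(raw$sim$montages, function(m) {
        montage_mix(m$name, as.numeric(unlist(m$weights)))
      })
    }
    raw$sim <- do.call(simulation_config, raw$sim)
  }
  do.call(study_config, raw)
}

condition_stimulus <- function(config, fm) {
  stimulus_spec(
    mod_rate = fm, center_freq = config$center_freq,
    tone_ms = config$tone_ms, ramp_ms = config$ramp_ms,
    gap_after_pos_ms = config$gap_after_pos_ms,
    gap_after_neg_ms = config$gap_after_neg_ms,
    level_rms = config$level_rms, fs = config$fs, polarity = 1
  )
}

# Obtain per-polarity subaverage sets for one condition x montage, either by
# simulation or from disk. Returns list(montage_name = list(pos=, neg=)).
condition_subaverages <- function(config, ci) {
  fm <- config$mod_rates[ci]
  if (is.null(config$recordings_dir)) {
    spec <- condition_stimulus(config, fm)
    trials <- simulate_trials(spec, config$sim,
                              seed = config$seed + 1000L * ci)
    n_rej <- integer(0)
    out <- lapply(trials, function(tm) {
      lapply(tm, function(mat) {
        sub <- make_subaverages(mat, config$sim$subaverage_size,
                                config$trial_limit)
        subaverage_set(sub, config$fs, 1L, "", fm)
      })
    })
    for (m in names(out)) {
      out[[m]]$pos$montage <- m
      out[[m]]$neg$montage <- m
      out[[m]]$neg$polarity <- -1L
    }
    out
  } else {
    montages <- sub(
      "\\.tsv$", "",
      sub(sprintf("^fm%03d_", fm), "",
          list.files(config$recordings_dir,
                     pattern = sprintf("^fm%03d_.*\\.tsv$", fm)))
    )
    if (length(montages) == 0) {
      stop("no recordings for f_m ", fm, " Hz in ", config$recordings_dir)
    }
    out <- lapply(montages, function(m) {
      rec <- read_recording(file.path(config$recordings_dir,
                                      sprintf("fm%03d_%s", fm, m)))
      split_polarities(rec)
    })
    names(out) <- montages
    out
  }
}

#' Run one complete study
#'
#' For every condition (modulation rate) and montage: preprocess (zero-phase
#' filter, subaverage rejection, polarity combination), estimate the spectrum
#' at the condition's three region frequencies (the addition waveform at the
#' modulation rate; the subtraction waveform at the two side tones), then fit
#' one group delay per montage x region across conditions from the
#' transducer-corrected phases of the frequencies that passed the presence
#' criterion.
#'
#' @param config A [study_config()].
#' @return List of class `study_result`: `spectra` (data frame, one row per
#'   condition x montage x region frequency), `fits` (one row per montage x
#'   region), `counts` (per-stage bookkeeping), `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  spectra <- list()
  counts <- list()
  for (ci in seq_along(config$mod_rates)) {
    fm <- config$mod_rates[ci]
    side <- side_tone_frequencies(config$center_freq, fm)
    subs <- condition_subaverages(config, ci)
    for (m in names(subs)) {
      targets <- data.frame(
        region = c("modulation", "lower_side", "upper_side"),
        freq = c(fm, side[1], side[2]),
        waveform = c("addition", "subtraction", "subtraction")
      )
      dw <- tryCatch(
        preprocess_recordings(
          subs[[m]]$pos, subs[[m]]$neg,
          low = config$filter_low, high = config$filter_high,
          order = config$filter_order,
          subaverage_limit = config$subaverage_limit
        ),
        error = function(e) {
          if (!grepl("no accepted subaverages", conditionMessage(e))) stop(e)
          NULL
        }
      )
      if (is.null(dw)) {
        # every subaverage of one polarity was rejected: the condition
        # contributes missing (absent) estimates, never numbers
        spectra[[length(spectra) + 1L]] <- data.frame(
          condition = fm, montage = m, region = targets$region,
          freq_hz = targets$freq, magnitude_uv = NA_real_,
          phase_cycles = NA_real_, snr_db = NA_real_, f_stat = NA_real_,
          p_value = NA_real_, present = FALSE
        )
        counts[[length(counts) + 1L]] <- data.frame(
          condition = fm, montage = m,
          subaverages_pos = 0L, subaverages_neg = 0L
        )
        next
      }
      for (ri in seq_len(nrow(targets))) {
        wf <- dw[[targets$waveform[ri]]]
        est <- spectral_estimate(wf, config$fs, targets$freq[ri],
                                 window_ms = config$window_ms,
                                 phase_ref = "epoch",
                                 alpha = config$alpha)
        spectra[[length(spectra) + 1L]] <- cbind(
          data.frame(condition = fm, montage = m,
                     region = targets$region[ri]),
          as.data.frame(est)
        )
      }
      cc <- attr(dw, "counts")
      counts[[length(counts) + 1L]] <- data.frame(
        condition = fm, montage = m,
        subaverages_pos = unname(cc["pos"]),
        subaverages_neg = unname(cc["neg"])
      )
    }
  }
  spectra <- do.call(rbind, spectra)
  fits <- list()
  for (m in unique(spectra$montage)) {
    for (r in c("modulation", "lower_side", "upper_side")) {
      sel <- spectra[spectra$montage == m & spectra$region == r, ]
      ser <- region_phase_series(
        data.frame(freq = sel$freq_hz, phase_cycles = sel$phase_cycles,
                   present = sel$present),
        region = r, cfg = config$unwrap
      )
      fit <- fit_group_delay(ser, config$unwrap)
      fits[[length(fits) + 1L]] <- data.frame(
        montage = m, region = r, n_points = fit$n_points,
        slope_cycles_per_hz = fit$slope, sse = fit$sse,
        group_delay_ms = if (is.na(fit$group_delay)) {
          NA_real_
        } else {
          round(fit$group_delay, 3)
        },
        status = fit$status,
        offsets = if (is.null(fit$offsets)) {
          ""
        } else {
          paste(fit$offsets, collapse = ",")
        }
      )
    }
  }
  structure(
    list(
      spectra = spectra, fits = do.call(rbind, fits),
      counts = do.call(rbind, counts), config = config
    ),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat("FFR study result:", nrow(x$spectra), "spectral estimates,",
      sum(x$fits$status == "ok"), "of", nrow(x$fits), "group delays fitted\n")
  print(x$fits[, c("montage", "region", "n_points", "group_delay_ms",
                   "status")], row.names = FALSE)
  invisible(x)
}

#' Run a study across replicates
#'
#' Repeats [run_study()] with per-replicate seeds (`seed + 100000 * rep`)
#' and stacks the fit tables.
#'
#' @param config A [study_config()].
#' @param n_replicates Number of replicates.
#' @return Data frame of fits with a leading `replicate` column.
#' @export
run_replicates <- function(config, n_replicates) {
  out <- lapply(seq_len(n_replicates), function(rep) {
    cfg <- config
    cfg$seed <- config$seed + 100000L * rep
    cbind(replicate = rep, run_study(cfg)$fits)
  })
  do.call(rbind, out)
}

#' Summarize group delays across replicates
#'
#' Mean and normal-approximation 95% confidence half-width of the fitted
#' group delay per montage x region, over replicates with status `"ok"`
#' (missing fits are excluded). Cells with no successful fit are omitted.
#'
#' @param fits Data frame from [run_replicates()] (or a stacked set of
#'   `$fits` tables).
#' @return Data frame: `montage`, `region`, `n`, `mean_delay_ms`,
#'   `ci95_halfwidth_ms` (`NA` when `n < 2`).
#' @export
summarize_fits <- function(fits) {
  ok <- fits[fits$status == "ok" & !is.na(fits$group_delay_ms), ]
  if (nrow(ok) == 0) {
    message("no successful fits to summarize")
    return(data.frame(montage = character(0), region = character(0),
                      n = integer(0), mean_delay_ms = numeric(0),
                      ci95_halfwidth_ms = numeric(0)))
  }
  cells <- unique(ok[, c("montage", "region")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- ok$group_delay_ms[ok$montage == cells$montage[i] &
                             ok$region == cells$region[i]]
    data.frame(
      montage = cells$montage[i], region = cells$region[i],
      n = length(d), mean_delay_ms = mean(d),
      ci95_halfwidth_ms = if (length(d) >= 2) {
        stats::qnorm(0.975) * stats::sd(d) / sqrt(length(d))
      } else {
        NA_real_
      }
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$montage, out$region), ]
}

#' Write the result tables of a study
#'
#' Writes `spectra.csv`, `fits.csv`, `counts.csv` and a JSON run manifest
#' (seed, package version, settings digest).
#'
#' @param result A `study_result` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$spectra, file.path(dir, "spectra.csv"),
                   row.names = FALSE)
  utils::write.csv(result$fits, file.path(dir, "fits.csv"),
                   row.names = FALSE)
  utils::write.csv(result$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("ffrdelay")),
    mod_rates = result$config$mod_rates,
    window_ms = result$config$window_ms,
    alpha = result$config$alpha
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
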