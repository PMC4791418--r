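#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the given (single-pass) order forward
#' and then reversed in time, for zero net phase and a squared magnitude
#' response (effective order doubled). Because the epochs are short relative
#' to the low corner, the trace is extended on both sides by odd-symmetric
#' reflection before filtering to suppress forward-reverse edge transients.
#'
#' @param x Numeric trace.
#' @param fs Sample rate, Hz.
#' @param low,high Band edges, Hz.
#' @param order Single-pass filter order (even; the band-pass is designed
#'   from an `order/2`-pole low-pass prototype).
#' @param pad_samples Reflection-padding length per side; default three
#'   low-corner periods, capped at `length(x) - 1`.
#' @return Filtered trace, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, low = 60, high = 2000, order = 4,
                                pad_samples = NULL) {
  if (high >= fs / 2) stop("high cutoff must be below the Nyquist frequency")
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (order %% 2 != 0) stop("order must be even")
  n <- length(x)
  if (is.null(pad_samples)) {
    pad_samples <- min(n - 1L, as.integer(3 * ceiling(fs / low)))
  }
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  head_pad <- 2 * x[1] - x[pad_samples + 1 - seq_len(pad_samples) + 1]
  tail_pad <- 2 * x[n] - x[n - seq_len(pad_samples)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y[pad_samples + seq_len(n)]
}

#' Reject trials by peak amplitude
#'
#' Removes (raw, unfiltered) trial epochs whose peak magnitude exceeds the
#' limit.
#'
#' @param trials Matrix, rows = trials.
#' @param limit Threshold in uV; `Inf` keeps everything.
#' @return Matrix of accepted trials with attributes `n_rejected` and
#'   `n_input`. If every trial is rejected a zero-row matrix is returned and a
#'   warning is raised.
#' @export
reject_trials <- function(trials, limit = 60) {
  trials <- as.matrix(trials)
  keep <- rowSums(abs(trials) > limit) == 0
  out <- trials[keep, , drop = FALSE]
  attr(out, "n_rejected") <- sum(!keep)
  attr(out, "n_input") <- nrow(trials)
  if (nrow(out) == 0) {
    warning("all ", nrow(trials), " trials rejected at +/-", limit, " uV")
  }
  out
}

#' A set of subaverage waveforms for one montage, polarity and condition
#'
#' @param waveforms Matrix, rows = subaverages, columns = samples (uV).
#' @param fs Sample rate, Hz.
#' @param polarity `+1` or `-1`.
#' @param montage Montage label.
#' @param condition Modulation rate (Hz) of the condition.
#' @param accepted Logical per subaverage (default all `TRUE`).
#' @return Object of class `subaverage_set`.
#' @export
subaverage_set <- function(waveforms, fs, polarity, montage, condition,
                           accepted = rep(TRUE, nrow(waveforms))) {
  waveforms <- as.matrix(waveforms)
  stopifnot(
    length(accepted) == nrow(waveforms),
    polarity %in% c(-1, 1)
  )
  structure(
    list(
      waveforms = waveforms, fs = fs, polarity = polarity,
      montage = montage, condition = condition, accepted = accepted
    ),
    class = "subaverage_set"
  )
}

#' @export
print.subaverage_set <- function(x, ...) {
  cat(sprintf(
    "subaverage_set: %d x %d samples, %s montage, f_m %g Hz, polarity %+d, %d accepted\n",
    nrow(x$waveforms), ncol(x$waveforms), x$montage, x$condition,
    x$polarity, sum(x$accepted)
  ))
  invisible(x)
}

#' Filter every subaverage of a set
#'
#' @param set A [subaverage_set()].
#' @inheritParams bandpass_zero_phase
#' @return The set with filtered waveforms.
#' @export
filter_subaverages <- function(set, low = 60, high = 2000, order = 4) {
  stopifnot(inherits(set, "subaverage_set"))
  if (nrow(set$waveforms) > 0) {
    set$waveforms <- t(apply(set$waveforms, 1, bandpass_zero_phase,
                             fs = set$fs, low = low, high = high,
                             order = order))
  }
  set
}

#' Reject subaverages by post-filter peak amplitude
#'
#' Applied after zero-phase filtering and before grand averaging: any
#' subaverage whose filtered peak magnitude exceeds the limit is marked not
#' accepted.
#'
#' @param set A [subaverage_set()] of filtered waveforms.
#' @param limit Threshold in uV.
#' @return The set with an updated `accepted` mask.
#' @export
reject_subaverages <- function(set, limit = 35) {
  stopifnot(inherits(set, "subaverage_set"))
  if (nrow(set$waveforms) > 0) {
    peaks <- apply(abs(set$waveforms), 1, max)
    set$accepted <- set$accepted & peaks <= limit
  }
  set
}

#' Grand mean over accepted subaverages
#'
#' Unweighted mean of the accepted subaverages.
#'
#' @param set A [subaverage_set()].
#' @return Numeric trace; errors if no subaverage is accepted.
#' @export
grand_mean <- function(set) {
  stopifnot(inherits(set, "subaverage_set"))
  if (!any(set$accepted)) {
    stop("no accepted subaverages for ", set$montage,
         " montage, f_m ", set$condition, " Hz, polarity ", set$polarity)
  }
  colMeans(set$waveforms[set$accepted, , drop = FALSE])
}

#' Combine the two polarity means into addition and subtraction waveforms
#'
#' The addition waveform `(pos + neg)/2` retains envelope-locked activity
#' (which does not invert with stimulus polarity); the subtraction waveform
#' `(pos - neg)/2` retains fine-structure-locked (and microphonic) activity.
#' Halving accounts for the effective doubling of trials when the two
#' polarities are combined. Means are computed per polarity before combining,
#' so unequal accepted counts introduce no bias.
#'
#' @param mean_pos,mean_neg Per-polarity grand-mean traces (equal length).
#' @param n_pos,n_neg Numbers of subaverages behind each mean (bookkeeping).
#' @return Object of class `derived_waveforms` with elements `addition`,
#'   `subtraction`, `n_pos`, `n_neg`.
#' @export
combine_polarity <- function(mean_pos, mean_neg, n_pos = 1L, n_neg = 1L) {
  if (length(mean_pos) != length(mean_neg)) {
    stop("polarity means differ in length (", length(mean_pos), " vs ",
         length(mean_neg), ")")
  }
  stopifnot(n_pos >= 1, n_neg >= 1)
  structure(
    list(
      addition = (mean_pos + mean_neg) / 2,
      subtraction = (mean_pos - mean_neg) / 2,
      n_pos = n_pos, n_neg = n_neg
    ),
    class = "derived_waveforms"
  )
}

#' Full preprocessing of one montage x condition recording pair
#'
#' Runs the fixed pipeline order on stored subaverages: zero-phase band-pass
#' filter, post-filter subaverage rejection, per-polarity grand mean, and
#' polarity combination.
#'
#' @param set_pos,set_neg [subaverage_set()] objects for the two polarities.
#' @param low,high,order Filter settings, see [bandpass_zero_phase()].
#' @param subaverage_limit Post-filter rejection threshold, uV.
#' @return A `derived_waveforms` object with attribute `fs` and a
#'   `counts` attribute recording accepted subaverages per polarity.
#' @export
preprocess_recordings <- function(set_pos, set_neg, low = 60, high = 2000,
                                  order = 4, subaverage_limit = 35) {
  run <- function(set) {
    set <- filter_subaverages(set, low = low, high = high, order = order)
    reject_subaverages(set, limit = subaverage_limit)
  }
  set_pos <- run(set_pos)
  set_neg <- run(set_neg)
  out <- combine_polarity(grand_mean(set_pos), grand_mean(set_neg),
                          n_pos = sum(set_pos$accepted),
                          n_neg = sum(set_neg$accepted))
  attr(out, "fs") <- set_pos$fs
  attr(out, "counts") <- c(pos = sum(set_pos$accepted),
                           neg = sum(set_neg$accepted))
  out
}

#' Split an interchange-format recording into per-polarity subaverage sets
#'
#' @param rec A list as returned by [read_recording()].
#' @return List with `pos` and `neg` [subaverage_set()] objects.
#' @export
split_polarities <- function(rec) {
  mk <- function(p) {
    idx <- rec$polarity_order == p
    if (!any(idx)) stop("recording has no polarity ", p, " rows")
    subaverage_set(rec$waveforms[idx, , drop = FALSE], rec$fs, p,
                   rec$montage, rec$condition)
  }
  list(pos = mk(1L), neg = mk(-1L))
}
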