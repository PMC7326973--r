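#' Linear-envelope EMG processing
#'
#' Standard surface-EMG conditioning: zero-phase 4th-order Butterworth
#' high-pass at `high_hz` (removes movement artefact and offset),
#' full-wave rectification, then zero-phase low-pass at `low_hz`
#' (linear envelope). Cutoffs default to 10 Hz / 20 Hz, consistent with
#' SENIAM practice. Filtering is applied forward-backward so the
#' envelope has no phase lag, which matters for the correlation
#' analyses downstream; end effects are controlled by odd-reflection
#' padding. The envelope is clamped at zero (the low-pass can
#' undershoot slightly around sharp transients).
#'
#' @param x Numeric vector, the raw EMG trace.
#' @param fs Sample rate in Hz; must exceed twice the highest cutoff.
#' @param high_hz High-pass cutoff (Hz). Default 10.
#' @param low_hz Low-pass cutoff (Hz). Default 20.
#' @return Numeric vector of the same length: the nonnegative envelope.
#' @export
#' @examples
#' fs <- 2000
#' t <- seq(0, 1, by = 1 / fs)
#' env <- emg_envelope(sin(2 * pi * 100 * t), fs)
#' mean(env[500:1500])  # ~ 2/pi, the rectified-sine mean
emg_envelope <- function(x, fs, high_hz = 10, low_hz = 20) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (fs <= 2 * max(high_hz, low_hz)) {
    abort("`fs` must exceed twice the highest filter cutoff.")
  }
  if (!length(x)) return(numeric(0))
  hp <- zero_phase_filter(x, fs, high_hz, type = "high")
  env <- zero_phase_filter(abs(hp), fs, low_hz, type = "low")
  pmax(env, 0)
}

#' Movement onset and offset from a distance profile
#'
#' Finds movement onset and offset as prominent local maxima of the
#' third time-derivative (jerk) of a displacement/distance trace: the
#' first prominent peak of |jerk| before the time of peak speed is the
#' onset, the last after it is the offset. The third derivative is
#' estimated by Savitzky--Golay differentiation (quintic fit), which is
#' exact on minimum-jerk interiors and avoids the (2*pi*f)^3 noise
#' amplification of repeated finite differencing. Peaks below
#' `prominence` times the global |jerk| maximum are ignored.
#'
#' @param x Numeric distance/displacement trace covering rest before
#'   and after the movement.
#' @param fs Sample rate in Hz.
#' @param window Savitzky--Golay window length in samples (odd,
#'   > polynomial order 5). Default 9; widen for noisy traces.
#' @param prominence Fraction of the global |jerk| maximum a local peak
#'   must reach (default 0.1).
#' @return A list with integer elements `onset` and `offset` (sample
#'   indices, onset < offset).
#' @export
detect_onset_offset <- function(x, fs, window = 9L, prominence = 0.1) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 7L) {
    abort("`window` must be an odd integer >= 7.")
  }
  if (length(x) <= window + 2L) {
    abort("Trace too short for onset detection.")
  }
  if (diff(range(x)) == 0) {
    abort("No movement detected: third derivative is flat.")
  }
  d3 <- signal::sgolayfilt(x, p = 5, n = window, m = 3, ts = 1 / fs)
  d1 <- signal::sgolayfilt(x, p = 5, n = window, m = 1, ts = 1 / fs)
  a <- abs(d3)
  top <- max(a)
  # numerical floor: differentiation noise scales with eps * fs^3
  tol <- 1e3 * .Machine$double.eps * fs^3 * max(1, max(abs(x)))
  if (!is.finite(top) || top <= tol) {
    abort("No movement detected: third derivative is flat.")
  }
  # interior local maxima of |jerk|
  loc <- which(diff(sign(diff(a))) < 0) + 1L
  loc <- loc[a[loc] >= prominence * top]
  pk <- which.max(abs(d1))
  onset <- loc[loc <= pk]
  offset <- loc[loc >= pk]
  if (!length(onset) || !length(offset)) {
    abort("No movement detected: no prominent jerk peaks straddle peak speed.")
  }
  list(onset = onset[1L], offset = offset[length(offset)])
}

#' Time-normalize a trace onto a movement-phase grid
#'
#' Re-samples the window between movement onset and offset onto
#' `n_phase` uniformly spaced points of normalized movement phase
#' \[0, 1\] using shape-preserving piecewise-cubic (PCHIP)
#' interpolation, which does not overshoot at this density. Endpoint
#' samples are preserved exactly.
#'
#' @param x Numeric trace.
#' @param onset,offset Sample indices delimiting the movement
#'   (onset < offset, both within the trace).
#' @param n_phase Number of phase samples (default 100).
#' @return Numeric vector of length `n_phase`.
#' @export
time_normalize <- function(x, onset, offset, n_phase = 100L) {
  onset <- as.integer(onset); offset <- as.integer(offset)
  if (onset < 1L || offset > length(x) || offset - onset < 1L) {
    abort("Degenerate onset/offset window.")
  }
  seg <- x[onset:offset]
  xi <- seq(onset, offset, length.out = n_phase)
  pracma::pchip(seq(onset, offset), seg, xi)
}

#' Average per-trial profiles and amplitude-normalize across tasks
#'
#' Averages movement-phase profiles across trials within each
#' participant x task x channel, then divides each channel by its
#' maximum across all tasks of that participant, producing unitless
#' profiles with a per-channel, per-participant maximum of 1. A channel
#' whose maximum is zero is returned as zeros with a warning rather
#' than dividing by zero.
#'
#' @param profiles A data frame with columns `participant`, `task`,
#'   `trial`, `channel`, `phase`, `value` (phase profiles from
#'   [time_normalize()]).
#' @return A tibble with columns `participant`, `task`, `channel`,
#'   `phase`, `value` (trial-averaged, amplitude-normalized).
#' @export
average_and_normalize <- function(profiles) {
  needed <- c("participant", "task", "channel", "phase", "value")
  if (!all(needed %in% names(profiles))) {
    abort("`profiles` needs columns participant, task, trial, channel, phase, value.")
  }
  mean_prof <- profiles %>%
    group_by(.data$participant, .data$task, .data$channel, .data$phase) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  out <- mean_prof %>%
    group_by(.data$participant, .data$channel) %>%
    mutate(.chan_max = max(.data$value)) %>%
    ungroup()
  if (any(out$.chan_max <= 0)) {
    warn("Channel(s) with non-positive maximum left as zeros during normalization.")
  }
  out %>%
    mutate(value = ifelse(.data$.chan_max > 0,
                          .data$value / .data$.chan_max, 0)) %>%
    select(-".chan_max")
}

#' Wasted contraction of an antagonist pair
#'
#' Co-contraction between two normalized activation profiles, measured
#' as their sample-wise minimum ("wasted contraction"): the portion of
#' recruitment that produces opposing moments and therefore no net
#' torque. Commutative, idempotent, and bounded above by both inputs.
#'
#' @param a,b Numeric profiles of equal length (normalized envelopes).
#' @return Numeric vector: `pmin(a, b)`.
#' @export
#' @examples
#' wasted_contraction(c(0.2, 0.5), c(0.4, 0.3))  # 0.2 0.3
wasted_contraction <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have the same length.")
  }
  pmin(a, b)
}

#' Co-contraction profiles for all antagonist pairs
#'
#' Applies [wasted_contraction()] to each antagonist pair within every
#' participant x task of a normalized profile table.
#'
#' @param profiles A tibble as returned by [average_and_normalize()]
#'   (columns `participant`, `task`, `channel`, `phase`, `value`).
#' @param pairs An antagonist-pair table (default [antagonist_pairs()]).
#' @return A tibble with columns `participant`, `task`, `channel` (the
#'   pair name), `phase`, `value`.
#' @export
cocontraction_profiles <- function(profiles, pairs = antagonist_pairs()) {
  missing <- setdiff(unique(c(pairs$flexor, pairs$extensor)),
                     unique(profiles$channel))
  if (length(missing)) {
    abort(paste0("Channels missing for antagonist pairs: ",
                 paste(missing, collapse = ", ")))
  }
  purrr::pmap_dfr(pairs, function(pair, flexor, extensor) {
    fl <- profiles %>% filter(.data$channel == flexor)
    ex <- profiles %>% filter(.data$channel == extensor)
    joined <- dplyr::inner_join(
      fl, ex, by = c("participant", "task", "phase"),
      suffix = c("_f", "_e"))
    joined %>%
      mutate(channel = pair,
             value = wasted_contraction(.data$value_f, .data$value_e)) %>%
      select("participant", "task", "channel", "phase", "value")
  })
}
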