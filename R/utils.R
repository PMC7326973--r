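# Internal helpers shared across modules.

# Derive a reproducible child seed from a parent seed and a stream index.
# Keeps everything inside the 32-bit signed range R requires of set.seed().
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 123457 * as.double(index)) %% 2147483647L)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# Zero-phase Butterworth filtering with odd-reflection end padding.
# signal::filtfilt() alone assumes zero initial conditions, which corrupts
# traces that do not start and end at zero; reflecting about the end points
# (as MATLAB's filtfilt does) removes the transient.
zero_phase_filter <- function(x, fs, cutoff, type, order = 4L) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (cutoff >= fs / 2) {
    abort("Filter cutoff must be below the Nyquist frequency fs/2.")
  }
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = type)
  npad <- min(n - 1L, ceiling(3 * fs / cutoff))
  if (npad < 1L) {
    return(as.numeric(signal::filtfilt(bf, x)))
  }
  xp <- c(2 * x[1L] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  y <- signal::filtfilt(bf, xp)
  as.numeric(y[(npad + 1L):(npad + n)])
}

# Trapezoid-rule integral of y(t) sampled at uniform spacing dt.
trapz_integral <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * sum((y[-1L] + y[-n]) / 2)
}

# Central-difference derivative on a uniform grid (pracma::gradient wrapper).
time_derivative <- function(x, fs) {
  pracma::gradient(x, h1 = 1 / fs)
}
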