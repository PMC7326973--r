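#' Spindle model coefficients
#'
#' Coefficients of the phenomenological Ia afferent model
#' `Ia = A * sgn(v) * |v|^0.5 + B * l + C`, where `l` is muscle length
#' in rest-length units and `v` its rate of change in rest-lengths per
#' second. The defaults (A = 65, B = 200, C = 10) are the empirically
#' validated values for human microneurography; `A` scales velocity
#' (dynamic) sensitivity and `B` length (static) sensitivity.
#'
#' @param A Velocity coefficient (imp/s per sqrt(rest-length/s)), >= 0.
#' @param B Length coefficient (imp/s per rest-length), >= 0.
#' @param C Baseline firing rate (imp/s), >= 0.
#' @return A named list with elements `A`, `B`, `C`.
#' @export
spindle_params <- function(A = 65, B = 200, C = 10) {
  for (nm in c("A", "B", "C")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm)
    if (v < 0) abort(sprintf("`%s` must be nonnegative.", nm))
  }
  list(A = A, B = B, C = C)
}

#' Static-set fusimotor variants
#'
#' The four corner models of the static-set parameter grid, in which a
#' constant (within-movement) fusimotor drive rescales the velocity
#' coefficient `A` in \{33, 200\} and the length coefficient `B` in
#' \{50, 400\} while the baseline stays at 10 imp/s, plus the reference
#' Prochazka parameterization. Variant names encode the coefficients:
#' V33-L50, V33-L400, V200-L50, V200-L400.
#'
#' @param include_prochazka Prepend the reference model (default TRUE).
#' @return A tibble with columns `variant`, `A`, `B`, `C`.
#' @export
#' @examples
#' static_set_grid()
static_set_grid <- function(include_prochazka = TRUE) {
  grid <- tibble(
    variant = c("V33-L50", "V33-L400", "V200-L50", "V200-L400"),
    A = c(33, 33, 200, 200),
    B = c(50, 400, 50, 400),
    C = 10
  )
  if (include_prochazka) {
    grid <- bind_rows(tibble(variant = "Prochazka", A = 65, B = 200, C = 10),
                      grid)
  }
  grid
}

#' Convert a muscle-length trace to rest-length units
#'
#' The spindle model operates on dimensionless muscle kinematics. The
#' rest length is the midpoint of the minimal and maximal muscle
#' lengths over the configured posture range,
#' `l_rest = (l_min + l_max) / 2`; length is divided by `l_rest` (so
#' l ~ 1 at rest) and velocity is expressed in rest-lengths per second.
#' Alternatively the rest length may be supplied directly (e.g. a
#' median over a posture distribution) via `l_rest`.
#'
#' @param length_m Numeric muscle-length trace in metres.
#' @param l_min,l_max Minimal and maximal muscle length (m) over the
#'   posture range; `l_min < l_max`.
#' @param fs Sample rate of the trace in Hz (for the velocity).
#' @param l_rest Optional explicit rest length (m), overriding the
#'   midpoint definition.
#' @return A tibble with columns `l` (rest-length units) and `v`
#'   (rest-lengths per second).
#' @export
#' @examples
#' rest_length_units(rep(0.11, 5), l_min = 0.08, l_max = 0.12, fs = 100)$l
rest_length_units <- function(length_m, l_min, l_max, fs, l_rest = NULL) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (is.null(l_rest)) {
    stopifnot_scalar_number(l_min, "l_min", positive = TRUE)
    stopifnot_scalar_number(l_max, "l_max", positive = TRUE)
    if (l_min >= l_max) abort("`l_min` must be smaller than `l_max`.")
    l_rest <- (l_min + l_max) / 2
  }
  l <- length_m / l_rest
  v <- if (length(l) > 1L) time_derivative(l, fs) else rep(0, length(l))
  tibble(l = l, v = v)
}

# signed square root used by both model forms
signed_sqrt <- function(v) sign(v) * sqrt(abs(v))

#' Ia afferent firing rate (constant-coefficient model)
#'
#' Evaluates `Ia = A * sgn(v) * |v|^0.5 + B * l + C` sample-wise. The
#' square-root velocity term is extended to shortening (negative `v`)
#' as an odd function, the standard continuous treatment for this
#' phenomenological family. Rates are clamped below at 0 imp/s; the
#' number of clamped samples is recorded in the `clamped` attribute.
#'
#' @param l Muscle length in rest-length units (nonnegative).
#' @param v Length rate of change in rest-lengths per second.
#' @param params Coefficients from [spindle_params()].
#' @return Numeric vector of firing rates (imp/s), attribute `clamped`.
#' @export
#' @examples
#' ia_rate(1, 0)    # 210 imp/s with default coefficients
#' ia_rate(1, 1)    # 275 imp/s
ia_rate <- function(l, v, params = spindle_params()) {
  if (length(l) != length(v)) abort("`l` and `v` must have equal length.")
  if (any(l < 0)) abort("Muscle length in rest-length units must be >= 0.")
  rate <- params$A * signed_sqrt(v) + params$B * l + params$C
  clamped <- sum(rate < 0)
  rate <- pmax(rate, 0)
  attr(rate, "clamped") <- clamped
  rate
}

#' Ia afferent firing rate with alpha-gamma coactivation (EMG-coupled)
#'
#' Couples the fusimotor drive to the homonymous muscle's motor
#' command: the velocity and length terms of the reference model are
#' scaled by the normalized mean EMG profile `a`, while the baseline
#' stays uncoupled: `Ia = a * 65 * sgn(v)|v|^0.5 + a * 200 * l + 10`.
#' With `a` identically 1 this reduces exactly to [ia_rate()] with
#' default coefficients.
#'
#' @param l,v Muscle kinematics as in [ia_rate()].
#' @param a Normalized mean EMG profile in \[0, 1\], same length.
#' @return Numeric vector of firing rates (imp/s), attribute `clamped`.
#' @export
#' @examples
#' ia_rate_emg_coupled(1, 0, 0.5)  # 0.5 * 200 + 10 = 110 imp/s
ia_rate_emg_coupled <- function(l, v, a) {
  if (length(l) != length(v) || length(l) != length(a)) {
    abort("`l`, `v` and `a` must have equal length.")
  }
  if (any(l < 0)) abort("Muscle length in rest-length units must be >= 0.")
  rate <- a * 65 * signed_sqrt(v) + a * 200 * l + 10
  clamped <- sum(rate < 0)
  rate <- pmax(rate, 0)
  attr(rate, "clamped") <- clamped
  rate
}

#' Simulate Ia profiles for a table of muscle-length phase profiles
#'
#' Converts per-muscle length profiles to rest-length units (per-muscle
#' posture range), differentiates them on the phase-consistent time
#' base, and evaluates the requested fusimotor variant for every
#' participant x task x muscle. For the `"EMG-coupled"` variant the
#' matching normalized EMG profile must be supplied.
#'
#' @param lengths A tibble with columns `participant`, `task`,
#'   `channel`, `phase`, `value` (muscle length in metres on the phase
#'   grid) and a `duration_s` column or attribute giving the movement
#'   duration represented by phase \[0, 1\].
#' @param ranges A tibble with columns `channel`, `l_min`, `l_max` (m);
#'   defaults to the per-muscle range observed in `lengths`.
#' @param variant Variant name from [static_set_grid()] or
#'   `"EMG-coupled"`.
#' @param emg For `"EMG-coupled"`: normalized EMG profiles with the
#'   same `participant`, `task`, `channel`, `phase` grid.
#' @param duration_s Movement duration (s) mapped to phase \[0, 1\]
#'   (used to express velocity per second): either a scalar or a tibble
#'   with columns `participant`, `task`, `duration_s`. Default 1.
#' @return A tibble with columns `participant`, `task`, `channel`,
#'   `phase`, `rate` (imp/s), `variant`.
#' @export
ia_profiles <- function(lengths, ranges = NULL, variant = "Prochazka",
                        emg = NULL, duration_s = 1) {
  grid <- static_set_grid()
  known <- c(grid$variant, "EMG-coupled")
  if (!variant %in% known) {
    abort(paste0("Unknown variant; expected one of: ",
                 paste(known, collapse = ", ")))
  }
  if (is.null(ranges)) {
    ranges <- lengths %>%
      group_by(.data$channel) %>%
      summarise(l_min = min(.data$value), l_max = max(.data$value),
                .groups = "drop")
  }
  n_phase <- length(unique(lengths$phase))
  if (variant == "EMG-coupled" && is.null(emg)) {
    abort("The EMG-coupled variant needs the `emg` profile table.")
  }
  if (is.data.frame(duration_s)) {
    lengths <- lengths %>%
      left_join(rename(duration_s, .dur = "duration_s"),
                by = c("participant", "task"))
    if (anyNA(lengths$.dur)) abort("Duration missing for some participant/task.")
  } else {
    lengths$.dur <- duration_s
  }
  lengths <- lengths %>% left_join(ranges, by = "channel")
  if (anyNA(lengths$l_min)) abort("Posture range missing for some channel.")
  out <- lengths %>%
    group_by(.data$participant, .data$task, .data$channel) %>%
    arrange(.data$phase, .by_group = TRUE) %>%
    mutate({
      kin <- rest_length_units(.data$value, .data$l_min[1L],
                               .data$l_max[1L],
                               fs = (n_phase - 1) / .data$.dur[1L])
      tibble(l = kin$l, v = kin$v)
    }) %>%
    ungroup()
  if (variant == "EMG-coupled") {
    out <- out %>%
      left_join(emg %>% rename(a = "value"),
                by = c("participant", "task", "channel", "phase"))
    if (anyNA(out$a)) abort("EMG profile missing for some channel.")
    out <- out %>%
      group_by(.data$participant, .data$task, .data$channel) %>%
      mutate(rate = as.numeric(ia_rate_emg_coupled(.data$l, .data$v, .data$a))) %>%
      ungroup()
  } else {
    pars <- grid[grid$variant == variant, ]
    prm <- spindle_params(pars$A, pars$B, pars$C)
    out <- out %>%
      mutate(rate = as.numeric(ia_rate(.data$l, .data$v, prm)))
  }
  out %>%
    mutate(variant = variant) %>%
    select("participant", "task", "channel", "phase", "rate", "variant")
}

#' Amplitude-normalize Ia profiles across tasks
#'
#' Divides each Ia channel by its maximum across all tasks of the same
#' participant (mirroring the EMG normalization) to obtain unitless
#' profiles for clustering.
#'
#' @param ia A tibble from [ia_profiles()].
#' @return The same tibble with `value` (normalized rate) added.
#' @export
normalize_ia <- function(ia) {
  ia %>%
    group_by(.data$participant, .data$channel, .data$variant) %>%
    mutate(value = if (max(.data$rate) > 0) .data$rate / max(.data$rate)
           else 0) %>%
    ungroup()
}

#' Per-muscle peak firing-rate summary
#'
#' Maximum simulated firing rate per participant and muscle, summarised
#' as mean and SD across participants. For fixed kinematics the peak
#' rate is affine in the model coefficients, so this summary is the
#' natural check that firing rates scale linearly with fusimotor gain.
#'
#' @param ia A tibble from [ia_profiles()] (columns `participant`,
#'   `task`, `channel`, `rate`).
#' @return A tibble with columns `channel`, `mean_peak`, `sd_peak`.
#' @export
peak_rate_summary <- function(ia) {
  if (!nrow(ia)) abort("Empty Ia profile set.")
  ia %>%
    group_by(.data$participant, .data$channel) %>%
    summarise(peak = max(.data$rate), .groups = "drop") %>%
    group_by(.data$channel) %>%
    summarise(mean_peak = mean(.data$peak),
              sd_peak = if (dplyr::n() > 1L) sd(.data$peak) else 0,
              .groups = "drop")
}
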