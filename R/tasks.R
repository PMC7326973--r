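#' Planar reaching task definitions
#'
#' The three point-to-point reaching tasks used throughout the package,
#' distinguished by the role passive limb dynamics plays in each:
#'
#' * **Control** -- shoulder and elbow rotate in opposite directions
#'   (shoulder excursion -60 deg, elbow +60 deg); the arm is largely
#'   lowered by gravity.
#' * **Resistive** -- shoulder and elbow rotate in the same direction
#'   (shoulder +45 deg, elbow +10 deg); gravity and interaction torques
#'   oppose the motion.
#' * **Assistive** -- opposite-direction rotations (shoulder -40 deg,
#'   elbow +100 deg) with assistive interaction torques.
#'
#' The wrist starts and ends at neutral (zero excursion) in every task.
#' Each task carries a dimensionless `cocontraction` level in \[0, 1\]
#' controlling the common drive the EMG generator adds to both members
#' of each antagonist pair; the Assistive task is given the most
#' co-contraction, mirroring the behaviour the tasks were designed to
#' elicit.
#'
#' @param duration_s Movement duration in seconds (default 1.0).
#' @return A tibble with one row per task x joint: columns `task`,
#'   `joint`, `start_deg`, `end_deg`, `duration_s`, `cocontraction`.
#' @export
#' @examples
#' reaching_tasks()
reaching_tasks <- function(duration_s = 1.0) {
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  coc <- c(Control = 0.10, Resistive = 0.25, Assistive = 0.50)
  tasks <- tibble::tribble(
    ~task,       ~joint,     ~start_deg, ~end_deg,
    "Control",   "shoulder",  80,         20,
    "Control",   "elbow",     10,         70,
    "Control",   "wrist",      0,          0,
    "Resistive", "shoulder",  30,         75,
    "Resistive", "elbow",     45,         55,
    "Resistive", "wrist",      0,          0,
    "Assistive", "shoulder",  70,         30,
    "Assistive", "elbow",      0,        100,
    "Assistive", "wrist",      0,          0
  )
  tasks$duration_s <- duration_s
  tasks$cocontraction <- unname(coc[tasks$task])
  tasks
}

#' Minimum-jerk point-to-point trajectory
#'
#' The smooth quintic profile connecting two postures with zero velocity
#' and acceleration at both ends, used as the stand-in for recorded
#' joint kinematics. Analytic first and second derivatives are returned
#' alongside the position so downstream dynamics can be checked against
#' closed forms.
#'
#' @param start,end Start and end values (e.g. joint angle in degrees).
#' @param duration Movement duration in seconds; must be positive.
#' @param n_samples Number of samples (>= 2).
#' @return A tibble with columns `time_s`, `value`, `velocity`,
#'   `acceleration` (`velocity` and `acceleration` are per second and
#'   per second squared in the units of `value`).
#' @export
#' @examples
#' mj <- minimum_jerk_trajectory(0, 60, 1, 101)
#' mj$value[51]          # midpoint: 30 by symmetry
#' mj$velocity[c(1, 101)] # zero at both ends
minimum_jerk_trajectory <- function(start, end, duration, n_samples) {
  stopifnot_scalar_number(start, "start")
  stopifnot_scalar_number(end, "end")
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  if (!is.numeric(n_samples) || n_samples < 2) {
    abort("`n_samples` must be at least 2.")
  }
  t <- seq(0, duration, length.out = n_samples)
  s <- t / duration
  d <- end - start
  value <- start + d * (10 * s^3 - 15 * s^4 + 6 * s^5)
  velocity <- d / duration * (30 * s^2 - 60 * s^3 + 30 * s^4)
  acceleration <- d / duration^2 * (60 * s - 180 * s^2 + 120 * s^3)
  tibble(time_s = t, value = value, velocity = velocity,
         acceleration = acceleration)
}

# Minimum-jerk profile evaluated on an arbitrary time grid with rest
# padding outside [t0, t0 + duration]. Used by the dataset generator.
minimum_jerk_padded <- function(time_s, start, end, t0, duration) {
  s <- pmin(pmax((time_s - t0) / duration, 0), 1)
  d <- end - start
  value <- start + d * (10 * s^3 - 15 * s^4 + 6 * s^5)
  velocity <- d / duration * (30 * s^2 - 60 * s^3 + 30 * s^4)
  acceleration <- d / duration^2 * (60 * s - 180 * s^2 + 120 * s^3)
  list(value = value, velocity = velocity, acceleration = acceleration)
}
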