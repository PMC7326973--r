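#' Anthropometric three-segment arm model
#'
#' Builds a planar arm / forearm / hand chain from body height and
#' weight using Winter's (2009) proportionality coefficients: segment
#' length as a fraction of height, segment mass as a fraction of body
#' mass, centre of mass as a fraction of segment length from the
#' proximal joint, and moment of inertia from the radius of gyration
#' about the centre of mass.
#'
#' @param height_m Body height in metres.
#' @param weight_kg Body mass in kilograms.
#' @return An object of class `arm_model`: a tibble with columns
#'   `segment` (`"arm"`, `"forearm"`, `"hand"`), `length_m`, `mass_kg`,
#'   `com_m` (CoM distance from the proximal joint), and
#'   `inertia_kgm2` (about the CoM), with gravity (9.81 m/s^2) stored
#'   as the `g` attribute.
#' @references Winter, D. A. (2009). Biomechanics and Motor Control of
#'   Human Movement, 4th ed. Wiley. (Anthropometric tables.)
#' @export
#' @examples
#' anthropometric_arm(1.80, 80)
anthropometric_arm <- function(height_m, weight_kg) {
  stopifnot_scalar_number(height_m, "height_m", positive = TRUE)
  stopifnot_scalar_number(weight_kg, "weight_kg", positive = TRUE)
  # Winter (2009): length/height, mass/body mass, CoM/length (proximal),
  # radius of gyration about CoM / length.
  coeff <- tibble::tribble(
    ~segment,  ~len_h, ~mass_b, ~com_l, ~rho_l,
    "arm",      0.186,  0.028,   0.436,  0.322,
    "forearm",  0.146,  0.016,   0.430,  0.303,
    "hand",     0.108,  0.006,   0.506,  0.297
  )
  model <- tibble(
    segment = coeff$segment,
    length_m = coeff$len_h * height_m,
    mass_kg = coeff$mass_b * weight_kg,
    com_m = coeff$com_l * coeff$len_h * height_m,
    inertia_kgm2 = coeff$mass_b * weight_kg * (coeff$rho_l * coeff$len_h * height_m)^2
  )
  attr(model, "g") <- 9.81
  class(model) <- c("arm_model", class(model))
  model
}

# Pull validated segment parameter vectors out of an arm_model tibble.
arm_params <- function(model) {
  if (!all(c("segment", "length_m", "mass_kg", "com_m", "inertia_kgm2") %in%
             names(model))) {
    abort("`model` must be an arm model tibble (see anthropometric_arm()).")
  }
  ord <- match(c("arm", "forearm", "hand"), model$segment)
  if (anyNA(ord)) abort("Arm model must contain segments arm, forearm, hand.")
  list(
    L = model$length_m[ord], m = model$mass_kg[ord],
    c = model$com_m[ord], I = model$inertia_kgm2[ord],
    g = attr(model, "g") %||% 9.81
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# time x (shoulder, elbow, wrist) matrix of one long-format column.
joint_matrix <- function(traj, col, t) {
  out <- vapply(c("shoulder", "elbow", "wrist"), function(j) {
    sub <- traj[traj$joint == j, ]
    sub[[col]][match(t, sub$time_s)]
  }, numeric(length(t)))
  out
}

#' Inverse dynamics of a planar three-link arm
#'
#' Computes the net muscle torque at the shoulder, elbow, and wrist
#' required to realise a given joint trajectory of a gravity-loaded
#' three-segment chain moving in the vertical plane (recursive
#' Newton--Euler). Joint angles follow the chain convention: the
#' shoulder angle is the absolute arm-segment angle from the horizontal
#' (+x) axis, elbow and wrist angles are relative to the parent
#' segment, all in radians, with gravity acting along -y.
#'
#' Angular velocity and acceleration are taken from the input when
#' present; otherwise they are derived by central differences on the
#' angle traces.
#'
#' @param traj A data frame with columns `time_s`, `joint`
#'   (`"shoulder"|"elbow"|"wrist"`), `angle_rad`, and optionally
#'   `velocity_rad_s` and `acceleration_rad_s2`.
#' @param model An [anthropometric_arm()] model.
#' @param g Gravitational acceleration (m/s^2). Defaults to the model's
#'   `g` attribute; set 0 for weightless checks.
#' @return A tibble with columns `time_s`, `joint`, `torque_nm`.
#' @export
#' @examples
#' arm <- anthropometric_arm(1.75, 70)
#' tr <- tidyr::expand_grid(
#'   time_s = seq(0, 1, by = 1 / 480),
#'   joint = c("shoulder", "elbow", "wrist")
#' )
#' tr$angle_rad <- 0   # static, fully extended horizontal arm
#' tau <- inverse_dynamics(tr, arm)
#' # shoulder torque equals the closed-form static gravity moment
inverse_dynamics <- function(traj, model, g = NULL) {
  p <- arm_params(model)
  if (!is.null(g)) p$g <- g
  if (!all(c("time_s", "joint", "angle_rad") %in% names(traj))) {
    abort("`traj` needs columns time_s, joint, angle_rad.")
  }
  joints <- c("shoulder", "elbow", "wrist")
  if (!all(joints %in% traj$joint)) {
    abort("`traj` must contain shoulder, elbow and wrist joints.")
  }
  traj <- arrange(traj, .data$joint, .data$time_s)
  t <- sort(unique(traj$time_s))
  nt <- length(t)
  if (nt < 3L) abort("Trajectory must contain at least 3 samples.")
  fs <- 1 / stats::median(diff(t))
  th <- joint_matrix(traj, "angle_rad", t)
  if (anyNA(th)) abort("NA joint angles in trajectory.")
  if ("velocity_rad_s" %in% names(traj)) {
    thd <- joint_matrix(traj, "velocity_rad_s", t)
  } else {
    thd <- apply(th, 2, time_derivative, fs = fs)
  }
  if ("acceleration_rad_s2" %in% names(traj)) {
    thdd <- joint_matrix(traj, "acceleration_rad_s2", t)
  } else {
    thdd <- apply(thd, 2, time_derivative, fs = fs)
  }

  # absolute segment angles / rates
  phi <- t(apply(th, 1, cumsum)); om <- t(apply(thd, 1, cumsum))
  al <- t(apply(thdd, 1, cumsum))
  cphi <- cos(phi); sphi <- sin(phi)

  # forward pass: CoM and joint-origin accelerations (planar)
  apx <- matrix(0, nt, 4); apy <- matrix(0, nt, 4)  # joint origins 1..4
  acx <- matrix(0, nt, 3); acy <- matrix(0, nt, 3)
  for (i in 1:3) {
    ux <- cphi[, i]; uy <- sphi[, i]        # along segment
    px <- -uy; py <- ux                     # perpendicular
    acx[, i] <- apx[, i] + al[, i] * p$c[i] * px - om[, i]^2 * p$c[i] * ux
    acy[, i] <- apy[, i] + al[, i] * p$c[i] * py - om[, i]^2 * p$c[i] * uy
    apx[, i + 1] <- apx[, i] + al[, i] * p$L[i] * px - om[, i]^2 * p$L[i] * ux
    apy[, i + 1] <- apy[, i] + al[, i] * p$L[i] * py - om[, i]^2 * p$L[i] * uy
  }

  # backward pass: joint forces and torques
  fx <- matrix(0, nt, 4); fy <- matrix(0, nt, 4)
  tau <- matrix(0, nt, 3)
  nmom <- matrix(0, nt, 4)
  for (i in 3:1) {
    fx[, i] <- p$m[i] * acx[, i] + fx[, i + 1]
    fy[, i] <- p$m[i] * (acy[, i] + p$g) + fy[, i + 1]
    rx_p <- p$c[i] * cphi[, i]; ry_p <- p$c[i] * sphi[, i]
    rx_d <- (p$L[i] - p$c[i]) * cphi[, i]; ry_d <- (p$L[i] - p$c[i]) * sphi[, i]
    nmom[, i] <- p$I[i] * al[, i] + nmom[, i + 1] +
      (rx_p * fy[, i] - ry_p * fx[, i]) +
      (rx_d * fy[, i + 1] - ry_d * fx[, i + 1])
    tau[, i] <- nmom[, i]
  }

  tibble(
    time_s = rep(t, 3),
    joint = rep(joints, each = nt),
    torque_nm = c(tau[, 1], tau[, 2], tau[, 3])
  )
}

# Total mechanical energy (kinetic + potential) along a trajectory, for
# energy-balance checks. Same input contract as inverse_dynamics() but
# velocities are required.
mechanical_energy <- function(traj, model, g = NULL) {
  p <- arm_params(model)
  if (!is.null(g)) p$g <- g
  t <- sort(unique(traj$time_s))
  th <- joint_matrix(traj, "angle_rad", t)
  thd <- joint_matrix(traj, "velocity_rad_s", t)
  nt <- nrow(th)
  phi <- t(apply(th, 1, cumsum)); om <- t(apply(thd, 1, cumsum))
  jx <- matrix(0, nt, 4); jy <- matrix(0, nt, 4)
  vx <- matrix(0, nt, 4); vy <- matrix(0, nt, 4)
  ke <- rep(0, nt); pe <- rep(0, nt)
  for (i in 1:3) {
    ux <- cos(phi[, i]); uy <- sin(phi[, i])
    px <- -uy; py <- ux
    cx <- jx[, i] + p$c[i] * ux; cy <- jy[, i] + p$c[i] * uy
    vcx <- vx[, i] + om[, i] * p$c[i] * px
    vcy <- vy[, i] + om[, i] * p$c[i] * py
    ke <- ke + 0.5 * p$m[i] * (vcx^2 + vcy^2) + 0.5 * p$I[i] * om[, i]^2
    pe <- pe + p$m[i] * p$g * cy
    jx[, i + 1] <- jx[, i] + p$L[i] * ux
    jy[, i + 1] <- jy[, i] + p$L[i] * uy
    vx[, i + 1] <- vx[, i] + om[, i] * p$L[i] * px
    vy[, i + 1] <- vy[, i] + om[, i] * p$L[i] * py
  }
  tibble(time_s = t, kinetic_j = ke, potential_j = pe,
         total_j = ke + pe)
}

#' Postural torque change across a movement
#'
#' Difference between the mean muscle torque over a window following
#' movement offset and the mean over a window preceding movement onset
#' (default 100 ms each), per joint. Positive values indicate a larger
#' holding torque in the final posture.
#'
#' @param torque A tibble from [inverse_dynamics()] (columns `time_s`,
#'   `joint`, `torque_nm`).
#' @param onset_s,offset_s Movement onset and offset times (seconds).
#' @param window_s Averaging window length in seconds (default 0.1).
#' @return A tibble with columns `joint` and `postural_change_nm`.
#' @export
postural_torque_change <- function(torque, onset_s, offset_s,
                                   window_s = 0.1) {
  stopifnot_scalar_number(window_s, "window_s", positive = TRUE)
  if (onset_s >= offset_s) abort("`onset_s` must precede `offset_s`.")
  tmin <- min(torque$time_s); tmax <- max(torque$time_s)
  if (onset_s - window_s < tmin - 1e-9 || offset_s + window_s > tmax + 1e-9) {
    abort(sprintf(
      "Need %.0f ms of trace on both sides of the movement window.",
      window_s * 1000))
  }
  torque %>%
    group_by(.data$joint) %>%
    summarise(
      postural_change_nm =
        mean(.data$torque_nm[.data$time_s >= offset_s &
                               .data$time_s <= offset_s + window_s]) -
        mean(.data$torque_nm[.data$time_s >= onset_s - window_s &
                               .data$time_s <= onset_s]),
      .groups = "drop"
    )
}

#' Peak torque change during the acceleration phase
#'
#' Maximal rate of torque change (N·m/s) between movement onset and the
#' halfway point, per joint, signed by the direction of the maximal
#' change. The first half of the movement reflects the largely
#' feedforward drive needed to launch the limb.
#'
#' @inheritParams postural_torque_change
#' @return A tibble with columns `joint` and `peak_change_nm_s`.
#' @export
peak_torque_change <- function(torque, onset_s, offset_s) {
  if (onset_s >= offset_s) abort("`onset_s` must precede `offset_s`.")
  half <- onset_s + (offset_s - onset_s) / 2
  torque %>%
    group_by(.data$joint) %>%
    summarise(peak_change_nm_s = {
      sel <- .data$time_s >= onset_s & .data$time_s <= half
      if (sum(sel) < 3L) abort("Acceleration-phase window has < 3 samples.")
      tt <- .data$time_s[sel]
      dtau <- time_derivative(.data$torque_nm[sel], fs = 1 / stats::median(diff(tt)))
      dtau[which.max(abs(dtau))]
    }, .groups = "drop")
}

#' Mechanical muscle work per joint
#'
#' Time integral of muscle torque times joint angular velocity
#' (trapezoid rule). Positive work indicates concentric muscle action
#' (energy flows from muscles to segments); negative work indicates
#' eccentric action with passive forces driving the motion.
#'
#' @param torque A tibble with columns `time_s`, `joint`, `torque_nm`.
#' @param velocity A tibble with columns `time_s`, `joint`,
#'   `velocity_rad_s`, aligned sample-for-sample with `torque`.
#' @return A tibble with columns `joint` and `work_j` (joules).
#' @export
mechanical_work <- function(torque, velocity) {
  joined <- dplyr::inner_join(torque, velocity, by = c("time_s", "joint"))
  per_joint <- torque %>% dplyr::count(.data$joint)
  got <- joined %>% dplyr::count(.data$joint)
  if (!identical(per_joint, got)) {
    abort("`torque` and `velocity` traces are not aligned on time_s/joint.")
  }
  joined %>%
    arrange(.data$joint, .data$time_s) %>%
    group_by(.data$joint) %>%
    summarise(
      work_j = trapz_integral(.data$torque_nm * .data$velocity_rad_s,
                              dt = stats::median(diff(.data$time_s))),
      .groups = "drop"
    )
}

#' Task-dynamics descriptors for one movement
#'
#' Convenience wrapper producing the per-joint descriptor set used to
#' characterise each reaching task: angular excursion, postural torque
#' change, peak torque change in the acceleration phase, and mechanical
#' muscle work.
#'
#' @param traj Joint trajectory as for [inverse_dynamics()] (velocities
#'   are derived if absent).
#' @param model An [anthropometric_arm()] model.
#' @param onset_s,offset_s Movement onset/offset times in seconds.
#' @return A tibble with columns `joint`, `excursion_rad`,
#'   `postural_change_nm`, `peak_change_nm_s`, `work_j`.
#' @export
task_dynamics <- function(traj, model, onset_s, offset_s) {
  tau <- inverse_dynamics(traj, model)
  if (!"velocity_rad_s" %in% names(traj)) {
    traj <- traj %>%
      group_by(.data$joint) %>%
      arrange(.data$time_s, .by_group = TRUE) %>%
      mutate(velocity_rad_s = time_derivative(
        .data$angle_rad, fs = 1 / stats::median(diff(.data$time_s)))) %>%
      ungroup()
  }
  exc <- traj %>%
    group_by(.data$joint) %>%
    summarise(
      excursion_rad =
        .data$angle_rad[which.min(abs(.data$time_s - offset_s))] -
        .data$angle_rad[which.min(abs(.data$time_s - onset_s))],
      .groups = "drop"
    )
  sel <- traj$time_s >= onset_s & traj$time_s <= offset_s
  work <- mechanical_work(torque = tau[tau$time_s >= onset_s &
                                         tau$time_s <= offset_s, ],
                          velocity = traj[sel, c("time_s", "joint",
                                                 "velocity_rad_s")])
  exc %>%
    left_join(postural_torque_change(tau, onset_s, offset_s), by = "joint") %>%
    left_join(peak_torque_change(tau, onset_s, offset_s), by = "joint") %>%
    left_join(work, by = "joint") %>%
    mutate(joint = factor(.data$joint,
                          levels = c("shoulder", "elbow", "wrist"))) %>%
    arrange(.data$joint) %>%
    mutate(joint = as.character(.data$joint))
}
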