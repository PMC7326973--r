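#' Configuration for a synthetic reaching study
#'
#' Bundles the design parameters of the synthetic dataset: cohort size,
#' trials per task, sample rates, trial timing, EMG noise, and the
#' anthropometric ranges participants are drawn from. Defaults mirror
#' the study design the package emulates: 9 participants, 3 tasks, 24
#' trials per task, kinematics at 480 Hz, EMG at 2000 Hz.
#'
#' @param n_participants Number of participants (default 9).
#' @param n_trials Trials per task per participant (default 24).
#' @param fs_kin Kinematics sample rate in Hz (default 480).
#' @param fs_emg EMG sample rate in Hz (default 2000).
#' @param rest_s Rest padding before and after each movement, seconds
#'   (default 0.3; must leave >= 100 ms margins for postural windows).
#' @param noise_sd SD of the zero-mean trial-to-trial envelope noise,
#'   on the unit scale of the normalized envelopes (default 0.1).
#' @param tasks Task table from [reaching_tasks()].
#' @param arms Moment-arm table from [moment_arms()].
#' @param base_lengths Reference lengths from [muscle_base_lengths()].
#' @param height_range,weight_range Uniform sampling ranges for
#'   participant height (m) and weight (kg).
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_participants = 9L, n_trials = 24L,
                         fs_kin = 480, fs_emg = 2000, rest_s = 0.3,
                         noise_sd = 0.1, tasks = reaching_tasks(),
                         arms = moment_arms(),
                         base_lengths = muscle_base_lengths(),
                         height_range = c(1.55, 1.90),
                         weight_range = c(55, 95)) {
  if (n_participants < 1L) abort("Need at least one participant.")
  if (n_trials < 1L) abort("Need at least one trial per task.")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  check_moment_arms(arms, base_lengths)
  structure(
    list(n_participants = as.integer(n_participants),
         n_trials = as.integer(n_trials), fs_kin = fs_kin,
         fs_emg = fs_emg, rest_s = rest_s, noise_sd = noise_sd,
         tasks = tasks, arms = arms, base_lengths = base_lengths,
         height_range = height_range, weight_range = weight_range),
    class = "study_config"
  )
}

#' Muscle lengths from joint angles (first-order length model)
#'
#' Maps joint-angle traces to musculotendon lengths with constant
#' signed moment arms: `l_m(t) = base_m - sum_j r_mj * theta_j(t)`
#' with angles in radians, so a flexor (positive moment arm) shortens
#' as its joint flexes and lengthens as the joint extends. The map is
#' exactly linear in the joint angles; it provides kinematically
#' consistent length and velocity profiles, not anatomical fidelity.
#'
#' @param angles A data frame with columns `time_s`, `joint`,
#'   `angle_deg`.
#' @param arms Moment-arm table (default [moment_arms()]).
#' @param base_lengths Reference-length table (default
#'   [muscle_base_lengths()]).
#' @return A tibble with columns `time_s`, `channel` (muscle),
#'   `length_m`.
#' @export
#' @examples
#' ang <- tibble::tibble(time_s = c(0, 1), joint = "elbow",
#'                       angle_deg = c(0, 90))
#' arms <- tibble::tibble(muscle = "Bic", joint = "elbow",
#'                        moment_arm_m = 0.02)
#' base <- tibble::tibble(muscle = "Bic", base_length_m = 0.30)
#' muscle_lengths_from_angles(ang, arms, base)
muscle_lengths_from_angles <- function(angles, arms = moment_arms(),
                                       base_lengths = muscle_base_lengths()) {
  if (!all(c("time_s", "joint", "angle_deg") %in% names(angles))) {
    abort("`angles` needs columns time_s, joint, angle_deg.")
  }
  check_moment_arms(arms, base_lengths)
  missing <- setdiff(unique(arms$joint), unique(angles$joint))
  if (length(missing)) {
    abort(paste0("Joint(s) referenced by the moment-arm table absent from ",
                 "`angles`: ", paste(missing, collapse = ", ")))
  }
  contrib <- arms %>%
    dplyr::inner_join(angles, by = "joint", relationship = "many-to-many") %>%
    mutate(dl = .data$moment_arm_m * .data$angle_deg * pi / 180) %>%
    group_by(.data$muscle, .data$time_s) %>%
    summarise(dl = sum(.data$dl), .groups = "drop")
  contrib %>%
    left_join(base_lengths, by = "muscle") %>%
    mutate(length_m = .data$base_length_m - .data$dl) %>%
    select(channel = "muscle", "time_s", "length_m") %>%
    arrange(.data$channel, .data$time_s)
}

#' Synthesize raw EMG for one task
#'
#' Builds per-muscle activation envelopes from a phasic joint-torque
#' demand and a task co-contraction level, then emits raw EMG as a
#' white-noise carrier amplitude-modulated by the envelope, so the
#' downstream 10 Hz high-pass / rectify / 20 Hz low-pass chain has
#' realistic work to do.
#'
#' The torque demand is first normalized per joint to a unit peak
#' magnitude (each joint's drive is expressed relative to its own
#' demand, so weak joints such as the wrist still produce full-scale
#' activation of their muscles). Each muscle's expected envelope is
#' then its rectified agonist share `sum_j max(0, sign(r_mj) *
#' tau_j(t) / max|tau_j|)` -- a muscle is driven only when the net
#' torque at a joint it spans is in the direction of its moment arm --
#' normalized to a unit task maximum; muscles with the same joint-sign
#' pattern receive identical drive, which is exactly the grouping
#' structure the clustering stages should recover;
#' the co-contraction component adds `cocontraction * bell(t)` -- a
#' common drive shaped like the movement-speed profile -- to every
#' muscle, hence equally to both members of each antagonist pair.
#' Trial-to-trial variability is zero-mean smooth noise of SD
#' `noise_sd` added to the envelope (clamped at zero).
#'
#' @param torque_demand A tibble with columns `time_s`, `joint`,
#'   `torque_nm`: the phasic muscle-torque demand on the kinematic
#'   time base.
#' @param cocontraction Common-drive level in \[0, 1\].
#' @param bell Common-drive shape: numeric vector on the
#'   `torque_demand` time base, max 1. Default: a smooth plateau over
#'   the support of the demand -- tonic antagonist stiffening held
#'   through the movement.
#' @param arms Moment-arm table (default [moment_arms()]).
#' @param noise_sd Trial-to-trial envelope noise SD (>= 0).
#' @param n_trials Number of trials to synthesize.
#' @param fs_emg EMG sample rate (Hz).
#' @param seed Integer seed; fixed seed reproduces traces exactly.
#' @return A list of class `synthetic_emg` with elements
#'   `envelope` (tibble `time_s`, `channel`, `value`: the noise-free
#'   expected envelope on the EMG time base), `trials` (list of
#'   n_samples x n_muscles raw-EMG matrices), `time_s`, `fs_emg`.
#' @export
generate_emg <- function(torque_demand, cocontraction = 0, bell = NULL,
                         arms = moment_arms(), noise_sd = 0,
                         n_trials = 1L, fs_emg = 2000, seed = 1L) {
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (cocontraction < 0 || cocontraction > 1) {
    abort("`cocontraction` must lie in [0, 1].")
  }
  if (!all(c("time_s", "joint", "torque_nm") %in% names(torque_demand))) {
    abort("`torque_demand` needs columns time_s, joint, torque_nm.")
  }
  muscles <- unique(arms$muscle)
  joints <- unique(arms$joint)
  missing <- setdiff(joints, unique(torque_demand$joint))
  if (length(missing)) {
    abort(paste0("Torque demand missing for joint(s): ",
                 paste(missing, collapse = ", ")))
  }
  t_kin <- sort(unique(torque_demand$time_s))
  t_emg <- seq(min(t_kin), max(t_kin), by = 1 / fs_emg)
  tau <- vapply(joints, function(j) {
    sub <- torque_demand[torque_demand$joint == j, ]
    y <- approx(sub$time_s, sub$torque_nm, xout = t_emg)$y
    if (max(abs(y)) > 0) y / max(abs(y)) else y
  }, numeric(length(t_emg)))
  if (is.null(bell)) {
    tot <- rowSums(abs(tau))
    if (max(tot) > 0) {
      # tonic plateau: smoothed indicator of the movement's support
      supp <- as.numeric(tot / max(tot) > 0.05)
      bell_emg <- zero_phase_filter(supp, fs_emg, 2, type = "low")
      bell_emg <- pmax(bell_emg, 0)
      if (max(bell_emg) > 0) bell_emg <- bell_emg / max(bell_emg)
    } else {
      bell_emg <- rep(0, length(t_emg))
    }
  } else {
    if (length(bell) != length(t_kin)) {
      abort("`bell` must be on the torque-demand time base.")
    }
    bell_emg <- approx(t_kin, bell, xout = t_emg)$y
  }

  env <- matrix(0, nrow = length(t_emg), ncol = length(muscles),
                dimnames = list(NULL, muscles))
  for (i in seq_len(nrow(arms))) {
    m <- arms$muscle[i]; j <- arms$joint[i]; r <- arms$moment_arm_m[i]
    env[, m] <- env[, m] + pmax(0, sign(r) * tau[, j])
  }
  peak <- max(env)
  if (peak > 0) env <- env / peak
  env <- env + cocontraction * bell_emg

  n_emg <- length(t_emg)
  trials <- vector("list", n_trials)
  # smooth trial noise built on a coarse grid, interpolated up
  n_coarse <- max(8L, ceiling((max(t_emg) - min(t_emg)) * 10))
  t_coarse <- seq(min(t_emg), max(t_emg), length.out = n_coarse)
  for (tr in seq_len(n_trials)) {
    set.seed(child_seed(seed, tr))
    env_tr <- env
    if (noise_sd > 0) {
      for (mc in seq_along(muscles)) {
        zn <- rnorm(n_coarse, sd = noise_sd)
        env_tr[, mc] <- pmax(0, env_tr[, mc] +
                               pracma::pchip(t_coarse, zn, t_emg))
      }
    }
    carrier <- matrix(rnorm(n_emg * length(muscles)), nrow = n_emg)
    trials[[tr]] <- env_tr * carrier
    colnames(trials[[tr]]) <- muscles
  }

  envelope <- tibble(
    time_s = rep(t_emg, times = length(muscles)),
    channel = rep(muscles, each = n_emg),
    value = as.numeric(env)
  )
  structure(list(envelope = envelope, trials = trials, time_s = t_emg,
                 fs_emg = fs_emg),
            class = "synthetic_emg")
}

# Ground-truth grouping: the cluster structure the analysis chain sees
# in the noise-free envelopes. For a unit-variance Gaussian carrier the
# trial-averaged linear envelope converges to
#   sqrt(2/pi) * LP( sqrt( conv(env^2, h^2) ) ),
# where h is the (zero-phase) high-pass impulse response, so exactly
# that expectation is clustered: phase-normalized over the movement
# window, pushed through the same HVE/UPGMA machinery the pipeline
# uses, and cut at the cluster count with the widest merge-height gap
# -- the maximal-margin structure the pipeline converges to as noise
# vanishes.
planted_structure <- function(env_mat, t_emg, onset_s, offset_s,
                              fs_emg, high_hz = 10, low_hz = 20,
                              n_phase = 100L) {
  # squared impulse response of the zero-phase high-pass stage
  half <- min(512L, (length(t_emg) - 1L) %/% 2L)
  imp <- rep(0, 2L * half + 1L); imp[half + 1L] <- 1
  h2 <- zero_phase_filter(imp, fs_emg, high_hz, type = "high")^2
  expected_env <- apply(env_mat, 2, function(e) {
    v <- stats::filter(e^2, h2, sides = 2)
    v[is.na(v)] <- (e^2 * sum(h2))[is.na(v)]   # edge fill, outside window
    zero_phase_filter(sqrt(2 / pi) * sqrt(pmax(as.numeric(v), 0)),
                      fs_emg, low_hz, type = "low")
  })
  keep <- t_emg >= onset_s & t_emg <= offset_s
  t_win <- t_emg[keep]
  t_grid <- seq(onset_s, offset_s, length.out = n_phase)
  prof <- apply(expected_env[keep, , drop = FALSE], 2, function(x) {
    pracma::pchip(t_win, x, t_grid)
  })
  cl <- cluster_profiles(t(prof))
  h <- cl$tree$height
  n <- ncol(env_mat)
  gaps <- diff(h)
  k <- n - which.max(gaps)
  k <- min(max(k, 2L), n - 1L)
  cut_tree(cl$tree, k)
}

# chain-convention trajectory (radians) for the planar dynamics:
# shoulder flexion of 90 deg = horizontal arm segment.
chain_trajectory <- function(angles_deg) {
  angles_deg %>%
    mutate(angle_rad = dplyr::case_when(
      .data$joint == "shoulder" ~ (.data$angle_deg - 90) * pi / 180,
      TRUE ~ .data$angle_deg * pi / 180
    )) %>%
    select("time_s", "joint", "angle_rad")
}

#' Generate a complete synthetic reaching study
#'
#' Builds the full multi-participant dataset every downstream stage
#' consumes: minimum-jerk joint kinematics per task (with rest padding
#' on both sides), muscle lengths via the first-order length model,
#' phasic joint-torque demands from planar inverse dynamics of each
#' participant's anthropometric arm, and raw EMG trials synthesized by
#' [generate_emg()] with the task's co-contraction level. Participant
#' heights and weights are drawn uniformly from the configured ranges.
#' The generator also records its own ground truth: the noise-free
#' expected envelopes and, per task, the grouping of muscles into
#' classes of exactly proportional envelopes, which is what the
#' clustering pipeline should recover as noise vanishes.
#'
#' Kinematics are deterministic per task (trial-to-trial variability
#' enters through the EMG); everything is reproducible from `seed`,
#' which is split hierarchically per participant, task, and trial.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return An object of class `synthetic_study`: list with tibbles
#'   `participants`, `kinematics` (per task), `lengths`, `torques`,
#'   `envelopes` (noise-free), `ground_truth`, a nested `emg` tibble
#'   (list-column of raw trial matrices), the `config`, and `seed`.
#' @export
generate_dataset <- function(config = study_config(), seed = 1L) {
  if (!inherits(config, "study_config")) {
    abort("`config` must come from study_config().")
  }
  tasks <- config$tasks
  task_names <- unique(tasks$task)
  set.seed(child_seed(seed, 0L))
  participants <- tibble(
    participant = sprintf("P%02d", seq_len(config$n_participants)),
    height_m = runif(config$n_participants, config$height_range[1],
                     config$height_range[2]),
    weight_kg = runif(config$n_participants, config$weight_range[1],
                      config$weight_range[2])
  )

  kin_list <- list(); len_list <- list(); tau_list <- list()
  env_list <- list(); gt_list <- list(); emg_rows <- list()

  for (pi in seq_len(config$n_participants)) {
    pid <- participants$participant[pi]
    model <- anthropometric_arm(participants$height_m[pi],
                                participants$weight_kg[pi])
    for (ti in seq_along(task_names)) {
      tk <- task_names[ti]
      spec <- tasks[tasks$task == tk, ]
      dur <- spec$duration_s[1L]
      total <- dur + 2 * config$rest_s
      t_kin <- seq(0, total, by = 1 / config$fs_kin)
      ang <- purrr::pmap_dfr(
        spec[, c("joint", "start_deg", "end_deg")],
        function(joint, start_deg, end_deg) {
          mj <- minimum_jerk_padded(t_kin, start_deg, end_deg,
                                    t0 = config$rest_s, duration = dur)
          tibble(time_s = t_kin, joint = joint, angle_deg = mj$value)
        })
      lens <- muscle_lengths_from_angles(ang, config$arms,
                                         config$base_lengths)
      tau <- inverse_dynamics(chain_trajectory(ang), model)
      # phasic demand: departure from the initial postural torque
      demand <- tau %>%
        group_by(.data$joint) %>%
        mutate(torque_nm = .data$torque_nm -
                 mean(.data$torque_nm[.data$time_s <= config$rest_s])) %>%
        ungroup()
      emg <- generate_emg(
        demand, cocontraction = spec$cocontraction[1L],
        arms = config$arms, noise_sd = config$noise_sd,
        n_trials = config$n_trials, fs_emg = config$fs_emg,
        seed = child_seed(seed, pi * 1000L + ti)
      )
      env_mat <- matrix(emg$envelope$value, ncol = length(unique(emg$envelope$channel)))
      colnames(env_mat) <- unique(emg$envelope$channel)
      # the movement window exactly as the analysis stage will see it
      ev <- detect_onset_offset(endpoint_distance(ang, model),
                                fs = config$fs_kin)
      groups <- planted_structure(env_mat, emg$time_s,
                                  onset_s = (ev$onset - 1) / config$fs_kin,
                                  offset_s = (ev$offset - 1) / config$fs_kin,
                                  fs_emg = config$fs_emg)

      kin_list[[length(kin_list) + 1L]] <-
        mutate(ang, participant = pid, task = tk)
      len_list[[length(len_list) + 1L]] <-
        mutate(lens, participant = pid, task = tk)
      tau_list[[length(tau_list) + 1L]] <-
        mutate(tau, participant = pid, task = tk)
      env_list[[length(env_list) + 1L]] <-
        mutate(emg$envelope, participant = pid, task = tk)
      gt_list[[length(gt_list) + 1L]] <-
        tibble(participant = pid, task = tk, channel = names(groups),
               group = unname(groups))
      emg_rows[[length(emg_rows) + 1L]] <- tibble(
        participant = pid, task = tk,
        trial = seq_len(config$n_trials),
        emg = emg$trials
      )
    }
  }

  structure(
    list(
      participants = participants,
      kinematics = bind_rows(kin_list) %>%
        select("participant", "task", "time_s", "joint", "angle_deg"),
      lengths = bind_rows(len_list) %>%
        select("participant", "task", "time_s", "channel", "length_m"),
      torques = bind_rows(tau_list) %>%
        select("participant", "task", "time_s", "joint", "torque_nm"),
      envelopes = bind_rows(env_list) %>%
        select("participant", "task", "time_s", "channel", "value"),
      ground_truth = bind_rows(gt_list),
      emg = bind_rows(emg_rows),
      config = config,
      seed = as.integer(seed)
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic reaching study\n")
  cat("  participants: ", nrow(x$participants), "\n", sep = "")
  cat("  tasks: ", paste(unique(x$config$tasks$task), collapse = ", "),
      "\n", sep = "")
  cat("  trials per task: ", x$config$n_trials, "\n", sep = "")
  cat("  fs kinematics / EMG: ", x$config$fs_kin, " / ", x$config$fs_emg,
      " Hz\n", sep = "")
  cat("  EMG envelope noise SD: ", x$config$noise_sd, "\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to long-format delimited tables
#'
#' Emits one long-format CSV per signal kind -- kinematics, muscle
#' lengths, and raw EMG (columns `participant`, `task`, `trial`,
#' `time_s`, `channel`, `value`) -- plus a JSON manifest of the
#' configuration, seed, and ground-truth grouping.
#'
#' @param study A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "synthetic_study")) {
    abort("`study` must come from generate_dataset().")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  kin <- study$kinematics %>%
    mutate(trial = NA_integer_) %>%
    select("participant", "task", "trial", "time_s",
           channel = "joint", value = "angle_deg")
  f <- file.path(dir, "kinematics.csv")
  readr::write_csv(kin, f); files <- c(files, f)
  len <- study$lengths %>%
    mutate(trial = NA_integer_) %>%
    select("participant", "task", "trial", "time_s", "channel",
           value = "length_m")
  f <- file.path(dir, "lengths.csv")
  readr::write_csv(len, f); files <- c(files, f)
  emg_long <- study$emg %>%
    mutate(long = purrr::map(.data$emg, function(m) {
      tibble(
        time_s = rep(seq(0, by = 1 / study$config$fs_emg,
                         length.out = nrow(m)), times = ncol(m)),
        channel = rep(colnames(m), each = nrow(m)),
        value = as.numeric(m)
      )
    })) %>%
    select(-"emg") %>%
    tidyr::unnest("long")
  f <- file.path(dir, "emg.csv")
  readr::write_csv(emg_long, f); files <- c(files, f)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(
      seed = study$seed,
      n_participants = study$config$n_participants,
      n_trials = study$config$n_trials,
      fs_kin = study$config$fs_kin, fs_emg = study$config$fs_emg,
      noise_sd = study$config$noise_sd,
      ground_truth = study$ground_truth
    )
    f <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}
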