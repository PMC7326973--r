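test_that("anthropometric segments follow Winter's proportions", {
  arm <- anthropometric_arm(1.80, 80)
  expect_equal(arm$length_m[arm$segment == "arm"], 0.186 * 1.80)
  expect_equal(arm$mass_kg, c(0.028, 0.016, 0.006) * 80)

  heavier <- anthropometric_arm(1.80, 160)
  expect_equal(heavier$mass_kg, 2 * arm$mass_kg)
  expect_equal(heavier$length_m, arm$length_m)
  expect_identical(anthropometric_arm(1.80, 80), arm)

  expect_error(anthropometric_arm(-1, 70), "positive")
  expect_error(anthropometric_arm(1.7, 0), "positive")
})

test_that("inverse dynamics reproduces closed-form statics", {
  arm <- anthropometric_arm(1.80, 80)
  static <- tidyr::expand_grid(time_s = seq(0, 0.5, by = 1 / 480),
                               joint = c("shoulder", "elbow", "wrist"))
  static$angle_rad <- 0   # fully extended horizontal arm

  # weightless static arm: all torques vanish
  tau0 <- inverse_dynamics(static, arm, g = 0)
  expect_equal(max(abs(tau0$torque_nm)), 0)

  # gravity-loaded horizontal arm: shoulder torque equals the moment sum
  tau <- inverse_dynamics(static, arm)
  L <- arm$length_m; m <- arm$mass_kg; cc <- arm$com_m
  closed <- 9.81 * (m[1] * cc[1] + m[2] * (L[1] + cc[2]) +
                      m[3] * (L[1] + L[2] + cc[3]))
  expect_equal(unique(tau$torque_nm[tau$joint == "shoulder"]), closed)

  # linearity in mass: doubling all masses doubles gravity torques
  arm2 <- arm
  arm2$mass_kg <- 2 * arm$mass_kg
  arm2$inertia_kgm2 <- 2 * arm$inertia_kgm2
  tau2 <- inverse_dynamics(static, arm2)
  expect_equal(tau2$torque_nm, 2 * tau$torque_nm)

  # distal masses zero: reduces to a single pendulum
  armp <- arm
  armp$mass_kg[2:3] <- 0
  armp$inertia_kgm2[2:3] <- 0
  taup <- inverse_dynamics(static, armp)
  expect_equal(unique(taup$torque_nm[taup$joint == "shoulder"]),
               9.81 * m[1] * cc[1])
  expect_equal(max(abs(taup$torque_nm[taup$joint != "shoulder"])), 0)

  bad <- static
  bad$angle_rad[3] <- NA
  expect_error(inverse_dynamics(bad, arm), "NA")
})

test_that("joint work balances total mechanical energy on a reach", {
  arm <- anthropometric_arm(1.72, 68)
  traj <- min_jerk_trajectory3(fs = 480)
  tau <- inverse_dynamics(traj, arm)
  en <- spindleclust:::mechanical_energy(traj, arm)
  w <- mechanical_work(tau, traj[, c("time_s", "joint", "velocity_rad_s")])
  dE <- en$total_j[nrow(en)] - en$total_j[1]
  expect_equal(sum(w$work_j), dE, tolerance = 1e-3)
})

test_that("postural torque change is the difference of window means", {
  fs <- 480
  t <- seq(0, 2, by = 1 / fs)
  step <- ifelse(t < 1, 2, -1)   # 2 Nm before, -1 Nm after
  tau <- dplyr::bind_rows(lapply(c("shoulder", "elbow", "wrist"),
                                 function(j) tibble::tibble(
                                   time_s = t, joint = j, torque_nm = step)))
  out <- postural_torque_change(tau, onset_s = 0.8, offset_s = 1.2)
  expect_equal(out$postural_change_nm, rep(-3, 3))

  # insensitive to window placement inside constant segments
  out2 <- postural_torque_change(tau, onset_s = 0.6, offset_s = 1.5)
  expect_equal(out2$postural_change_nm, rep(-3, 3))

  # identical start and end torque: zero change
  flat <- tau |> dplyr::mutate(torque_nm = 2)
  expect_equal(postural_torque_change(flat, 0.8, 1.2)$postural_change_nm,
               rep(0, 3))

  expect_error(postural_torque_change(tau, onset_s = 0.05, offset_s = 1.2),
               "ms")
})

test_that("peak torque change is the signed max slope in the first half", {
  fs <- 480
  t <- seq(0, 2, by = 1 / fs)
  base <- tidyr::expand_grid(joint = c("shoulder", "elbow", "wrist"),
                             time_s = t)

  const <- base |> dplyr::mutate(torque_nm = 4)
  expect_equal(peak_torque_change(const, 0, 2)$peak_change_nm_s, rep(0, 3))

  # ramp of slope 5 N*m/s during the first half
  ramp <- base |> dplyr::mutate(torque_nm = 5 * pmin(time_s, 1))
  expect_equal(peak_torque_change(ramp, 0, 2)$peak_change_nm_s, rep(5, 3),
               tolerance = 1e-9)

  # change confined to the second half is invisible to the window
  late <- base |> dplyr::mutate(torque_nm = 5 * pmax(time_s - 1.2, 0))
  expect_equal(peak_torque_change(late, 0, 2)$peak_change_nm_s, rep(0, 3))

  short <- const[const$time_s < 3 / fs, ]
  expect_error(peak_torque_change(short, 0, 2 / fs), "samples")
})

test_that("mechanical work integrates torque times velocity with sign", {
  t <- seq(0, 2, by = 0.01)
  base <- tidyr::expand_grid(joint = c("shoulder", "elbow", "wrist"),
                             time_s = t)
  tau <- base |> dplyr::mutate(torque_nm = 1)
  vel_pos <- base |> dplyr::mutate(velocity_rad_s = 1)
  out <- mechanical_work(tau, vel_pos)
  expect_equal(out$work_j, rep(2, 3))                 # concentric

  vel_neg <- base |> dplyr::mutate(velocity_rad_s = -1)
  expect_equal(mechanical_work(tau, vel_neg)$work_j, rep(-2, 3))  # eccentric

  vel_still <- base |> dplyr::mutate(velocity_rad_s = 0)
  expect_equal(mechanical_work(tau, vel_still)$work_j, rep(0, 3))

  expect_error(mechanical_work(tau, vel_pos[-1, ]), "aligned")
})

test_that("the immobile wrist does zero mechanical work in every task", {
  study <- tiny_study()
  prof <- tiny_profiles()
  dyn <- prof$events |>
    purrr::pmap_dfr(function(participant, task, onset_s, offset_s, ...) {
      traj <- study$kinematics[study$kinematics$task == task, ]
      model <- anthropometric_arm(study$participants$height_m[1],
                                  study$participants$weight_kg[1])
      task_dynamics(spindleclust:::chain_trajectory(traj), model,
                    onset_s, offset_s) |>
        dplyr::mutate(task = task)
    })
  wrist <- dyn[dyn$joint == "wrist", ]
  expect_equal(wrist$excursion_rad, rep(0, 3))
  expect_equal(wrist$work_j, rep(0, 3), tolerance = 1e-6)
})
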