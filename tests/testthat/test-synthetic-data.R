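test_that("minimum-jerk trajectories satisfy their boundary conditions", {
  flat <- minimum_jerk_trajectory(10, 10, 1, 11)
  expect_equal(flat$value, rep(10, 11))

  mj <- minimum_jerk_trajectory(0, 60, 1, 101)
  expect_equal(mj$value[51], 30)                      # midpoint symmetry
  expect_equal(mj$value[c(1, 101)], c(0, 60))
  expect_equal(mj$velocity[c(1, 101)], c(0, 0))
  expect_equal(mj$acceleration[c(1, 101)], c(0, 0))

  down <- minimum_jerk_trajectory(0, -60, 0.8, 81)
  expect_equal(down$velocity[c(1, 81)], c(0, 0))

  expect_error(minimum_jerk_trajectory(0, 1, 0, 10), "positive")
  expect_error(minimum_jerk_trajectory(0, 1, 1, 1), "at least 2")
})

test_that("the muscle-length model is the stated linear map", {
  ang <- tibble::tibble(time_s = seq(0, 1, by = 0.1), joint = "elbow",
                        angle_deg = seq(0, 1, by = 0.1) * 180 / pi)
  arms <- tibble::tibble(muscle = "Bic", joint = "elbow",
                         moment_arm_m = 0.02)
  base <- tibble::tibble(muscle = "Bic", base_length_m = 0.30)
  out <- muscle_lengths_from_angles(ang, arms, base)
  # r = 0.02 m, theta ramps 0 -> 1 rad: length ramps 0.30 -> 0.28
  expect_equal(out$length_m[1], 0.30)
  expect_equal(out$length_m[nrow(out)], 0.28)
  expect_equal(out$length_m, seq(0.30, 0.28, length.out = 11))

  # zero moment arms: constant base lengths
  arms0 <- moment_arms() |> dplyr::mutate(moment_arm_m = 0)
  expect_error(muscle_lengths_from_angles(ang, arms0, muscle_base_lengths()),
               "nonzero")

  # an antagonist pair about one joint gives perfectly anticorrelated traces
  arms2 <- tibble::tibble(muscle = c("F", "E"), joint = "elbow",
                          moment_arm_m = c(0.02, -0.03))
  base2 <- tibble::tibble(muscle = c("F", "E"),
                          base_length_m = c(0.3, 0.3))
  ang2 <- tibble::tibble(time_s = seq(0, 1, by = 0.05), joint = "elbow",
                         angle_deg = 40 * sin(seq(0, 2 * pi, length.out = 21)))
  out2 <- muscle_lengths_from_angles(ang2, arms2, base2)
  lf <- out2$length_m[out2$channel == "F"]
  le <- out2$length_m[out2$channel == "E"]
  expect_equal(cor(lf, le), -1)

  expect_error(
    muscle_lengths_from_angles(
      tibble::tibble(time_s = 0:1, joint = "elbow", angle_deg = 0),
      moment_arms(), muscle_base_lengths()),
    "absent")
})

test_that("muscle lengths are exactly linear in joint angles", {
  study <- tiny_study()
  lens <- study$lengths[study$lengths$task == "Control", ]
  ang <- study$kinematics[study$kinematics$task == "Control", ]
  wide_ang <- tidyr::pivot_wider(ang, id_cols = "time_s",
                                 names_from = "joint",
                                 values_from = "angle_deg")
  for (ch in c("AD", "BicL", "ECR")) {
    y <- lens$length_m[lens$channel == ch]
    fit <- lm(y ~ shoulder + elbow + wrist, data = wide_ang)
    expect_lt(max(abs(residuals(fit))), 1e-12)
  }
})

test_that("EMG synthesis honours reciprocal drive, common drive, and the seed", {
  t <- seq(0, 1, by = 1 / 480)
  demand <- dplyr::bind_rows(
    tibble::tibble(time_s = t, joint = "shoulder",
                   torque_nm = sin(pi * t)),        # one-signed
    tibble::tibble(time_s = t, joint = "elbow", torque_nm = 0),
    tibble::tibble(time_s = t, joint = "wrist", torque_nm = 0)
  )
  # purely reciprocal drive: antagonists never overlap on one-signed demand
  res <- generate_emg(demand, cocontraction = 0, noise_sd = 0, seed = 3)
  env <- tidyr::pivot_wider(res$envelope, names_from = "channel",
                            values_from = "value")
  pairs <- antagonist_pairs()
  for (i in seq_len(nrow(pairs))) {
    wc <- wasted_contraction(env[[pairs$flexor[i]]], env[[pairs$extensor[i]]])
    expect_equal(sum(wc), 0)
  }

  # pure common drive: both members of every pair carry identical envelopes
  demand0 <- demand |> dplyr::mutate(torque_nm = 0)
  bell <- sin(pi * t)^2
  res0 <- generate_emg(demand0, cocontraction = 1, bell = bell, noise_sd = 0,
                       seed = 3)
  env0 <- tidyr::pivot_wider(res0$envelope, names_from = "channel",
                             values_from = "value")
  for (i in seq_len(nrow(pairs))) {
    expect_equal(env0[[pairs$flexor[i]]], env0[[pairs$extensor[i]]])
  }

  # determinism: a fixed seed reproduces raw traces exactly
  a <- generate_emg(demand, cocontraction = 0.3, noise_sd = 0.1,
                    n_trials = 2, seed = 11)
  b <- generate_emg(demand, cocontraction = 0.3, noise_sd = 0.1,
                    n_trials = 2, seed = 11)
  expect_identical(a$trials, b$trials)

  expect_error(generate_emg(demand, noise_sd = -1), "nonnegative")
  expect_error(generate_emg(demand[demand$joint != "wrist", ]), "wrist")
})

test_that("the study generator is reproducible with stable ground truth", {
  cfg <- study_config(n_participants = 1, n_trials = 2)
  s1 <- generate_dataset(cfg, seed = 5)
  s2 <- generate_dataset(cfg, seed = 5)
  expect_identical(s1$emg$emg, s2$emg$emg)

  s3 <- generate_dataset(cfg, seed = 6)
  # different seed: different EMG noise, same planted structure
  expect_false(identical(s1$emg$emg[[1]], s3$emg$emg[[1]]))
  expect_identical(s1$ground_truth, s3$ground_truth)

  expect_equal(nrow(s1$emg), 2 * 3)      # trials x tasks
  expect_setequal(unique(s1$lengths$channel), moment_arms()$muscle)

  # the default design: 9 participants, 24 trials, 480 / 2000 Hz
  dflt <- study_config()
  expect_equal(dflt$n_participants, 9L)
  expect_equal(dflt$n_trials, 24L)
  expect_equal(dflt$fs_kin, 480)
  expect_equal(dflt$fs_emg, 2000)
  expect_equal(nrow(dflt$tasks), 9)      # 3 tasks x 3 joints
})

test_that("task geometry matches the design: wrist fixed, excursion signs", {
  tasks <- reaching_tasks()
  wrist <- tasks[tasks$joint == "wrist", ]
  expect_equal(wrist$start_deg, wrist$end_deg)
  exc <- tasks |>
    dplyr::mutate(exc = end_deg - start_deg) |>
    tidyr::pivot_wider(id_cols = "task", names_from = "joint",
                       values_from = "exc")
  # Control / Assistive: opposite-sign shoulder vs elbow; Resistive same-sign
  expect_lt(exc$shoulder[exc$task == "Control"] *
              exc$elbow[exc$task == "Control"], 0)
  expect_lt(exc$shoulder[exc$task == "Assistive"] *
              exc$elbow[exc$task == "Assistive"], 0)
  expect_gt(exc$shoulder[exc$task == "Resistive"] *
              exc$elbow[exc$task == "Resistive"], 0)
})

test_that("a study round-trips to long-format files", {
  dir <- withr::local_tempdir()
  files <- write_study(tiny_study(), dir)
  expect_true(all(file.exists(file.path(dir, c("kinematics.csv",
                                               "lengths.csv", "emg.csv")))))
  emg <- readr::read_csv(file.path(dir, "emg.csv"), show_col_types = FALSE)
  expect_named(emg, c("participant", "task", "trial", "time_s",
                      "channel", "value"))
  expect_equal(length(unique(emg$channel)), 12)
})
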