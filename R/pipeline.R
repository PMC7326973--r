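#' Muscle length extremes over the physiological posture range
#'
#' Because the length model is linear in the joint angles, each
#' muscle's minimal and maximal lengths over a box of joint limits are
#' attained at corner postures and have a closed form. These extremes
#' define the rest length (midpoint convention) used to
#' nondimensionalize spindle inputs; by default the full physiological
#' flexion--extension range is used, not just the task workspace.
#'
#' @param arms Moment-arm table (default [moment_arms()]).
#' @param base_lengths Reference lengths (default
#'   [muscle_base_lengths()]).
#' @param joint_limits A tibble with columns `joint`, `min_deg`,
#'   `max_deg`. Defaults to shoulder \[-60, 180\], elbow \[0, 150\],
#'   wrist \[-70, 70\] degrees of flexion.
#' @return A tibble with columns `channel`, `l_min`, `l_max` (m).
#' @export
muscle_length_ranges <- function(arms = moment_arms(),
                                 base_lengths = muscle_base_lengths(),
                                 joint_limits = NULL) {
  if (is.null(joint_limits)) {
    joint_limits <- tibble(
      joint = c("shoulder", "elbow", "wrist"),
      min_deg = c(-60, 0, -70),
      max_deg = c(180, 150, 70)
    )
  }
  x <- arms %>% left_join(joint_limits, by = "joint")
  if (anyNA(x$min_deg)) abort("Joint limits missing for some joint.")
  x <- x %>%
    mutate(
      hi = pmax(.data$moment_arm_m * .data$min_deg,
                .data$moment_arm_m * .data$max_deg) * pi / 180,
      lo = pmin(.data$moment_arm_m * .data$min_deg,
                .data$moment_arm_m * .data$max_deg) * pi / 180
    ) %>%
    group_by(.data$muscle) %>%
    summarise(hi = sum(.data$hi), lo = sum(.data$lo), .groups = "drop")
  x %>%
    left_join(base_lengths, by = "muscle") %>%
    mutate(l_min = .data$base_length_m - .data$hi,
           l_max = .data$base_length_m - .data$lo) %>%
    select(channel = "muscle", "l_min", "l_max")
}

# Wrist-endpoint displacement magnitude for onset detection, from the
# planar chain geometry.
endpoint_distance <- function(angles_deg, model) {
  p <- arm_params(model)
  t <- sort(unique(angles_deg$time_s))
  th <- vapply(c("shoulder", "elbow"), function(j) {
    sub <- angles_deg[angles_deg$joint == j, ]
    sub$angle_deg[match(t, sub$time_s)]
  }, numeric(length(t)))
  phi1 <- (th[, 1] - 90) * pi / 180
  phi2 <- phi1 + th[, 2] * pi / 180
  x <- p$L[1] * cos(phi1) + p$L[2] * cos(phi2)
  y <- p$L[1] * sin(phi1) + p$L[2] * sin(phi2)
  sqrt((x - x[1])^2 + (y - y[1])^2)
}

#' Process a synthetic study into normalized phase profiles
#'
#' Runs the full signal-processing chain on a generated study:
#' movement onset/offset from the third derivative of the wrist
#' endpoint displacement, EMG linear envelopes per trial, time
#' normalization of every signal onto the movement-phase grid, trial
#' averaging, and amplitude normalization to the per-participant
#' across-task maximum. Muscle lengths and joint angles are
#' phase-normalized without amplitude scaling (correlation-based
#' analyses are scale-free; lengths stay in metres for the spindle
#' model).
#'
#' @param study A [generate_dataset()] result.
#' @param n_phase Number of movement-phase samples (default 100).
#' @return An object of class `study_profiles`: list with tibbles
#'   `emg` (normalized envelopes), `cocontraction`, `lengths` (m),
#'   `angles` (deg), `events` (onset/offset/duration per
#'   participant x task), and `n_phase`.
#' @export
process_study <- function(study, n_phase = 100L) {
  if (!inherits(study, "synthetic_study")) {
    abort("`study` must come from generate_dataset().")
  }
  cfg <- study$config
  fs_kin <- cfg$fs_kin; fs_emg <- cfg$fs_emg
  groups <- study$kinematics %>% distinct(.data$participant, .data$task)

  events <- purrr::pmap_dfr(groups, function(participant, task) {
    ang <- study$kinematics %>%
      filter(.data$participant == !!participant, .data$task == !!task)
    model <- anthropometric_arm(
      study$participants$height_m[study$participants$participant == participant],
      study$participants$weight_kg[study$participants$participant == participant])
    dist <- endpoint_distance(ang, model)
    ev <- detect_onset_offset(dist, fs = fs_kin)
    tibble(participant = participant, task = task,
           onset = ev$onset, offset = ev$offset,
           onset_s = (ev$onset - 1) / fs_kin,
           offset_s = (ev$offset - 1) / fs_kin,
           duration_s = (ev$offset - ev$onset) / fs_kin)
  })

  norm_group <- function(df, value_col, fs, ev) {
    df %>%
      group_by(.data$channel) %>%
      arrange(.data$time_s, .by_group = TRUE) %>%
      dplyr::reframe(
        phase = seq(0, 1, length.out = n_phase),
        value = time_normalize(.data[[value_col]],
                               onset = ev$on, offset = ev$off,
                               n_phase = n_phase)
      )
  }

  len_list <- list(); ang_list <- list(); emg_list <- list()
  for (gi in seq_len(nrow(groups))) {
    pid <- groups$participant[gi]; tk <- groups$task[gi]
    ev <- events %>% filter(.data$participant == pid, .data$task == tk)
    ev_kin <- list(on = ev$onset, off = ev$offset)
    lens <- study$lengths %>%
      filter(.data$participant == pid, .data$task == tk)
    len_list[[gi]] <- norm_group(lens, "length_m", fs_kin, ev_kin) %>%
      mutate(participant = pid, task = tk)
    angs <- study$kinematics %>%
      filter(.data$participant == pid, .data$task == tk) %>%
      rename(channel = "joint")
    ang_list[[gi]] <- norm_group(angs, "angle_deg", fs_kin, ev_kin) %>%
      mutate(participant = pid, task = tk)

    trials <- study$emg %>%
      filter(.data$participant == pid, .data$task == tk)
    on_emg <- round(ev$onset_s * fs_emg) + 1L
    off_emg <- round(ev$offset_s * fs_emg) + 1L
    emg_list[[gi]] <- purrr::map_dfr(seq_len(nrow(trials)), function(ri) {
      m <- trials$emg[[ri]]
      prof <- vapply(seq_len(ncol(m)), function(ci) {
        env <- emg_envelope(m[, ci], fs = fs_emg)
        time_normalize(env, on_emg, min(off_emg, nrow(m)), n_phase)
      }, numeric(n_phase))
      tibble(
        participant = pid, task = tk, trial = trials$trial[ri],
        channel = rep(colnames(m), each = n_phase),
        phase = rep(seq(0, 1, length.out = n_phase), times = ncol(m)),
        value = as.numeric(prof)
      )
    })
  }

  emg_profiles <- average_and_normalize(bind_rows(emg_list))
  coc <- cocontraction_profiles(emg_profiles)

  structure(
    list(
      emg = emg_profiles,
      cocontraction = coc,
      lengths = bind_rows(len_list) %>%
        select("participant", "task", "channel", "phase", "value"),
      angles = bind_rows(ang_list) %>%
        select("participant", "task", "channel", "phase", "value"),
      events = events %>%
        select("participant", "task", "onset_s", "offset_s", "duration_s"),
      n_phase = as.integer(n_phase)
    ),
    class = "study_profiles"
  )
}

# Build per participant x task trees for one profile table.
trees_by_group <- function(profiles, q) {
  profiles %>%
    group_by(.data$participant, .data$task) %>%
    tidyr::nest() %>%
    ungroup() %>%
    mutate(clustering = purrr::map(.data$data, cluster_profiles, q = q)) %>%
    select(-"data")
}

#' Run the full hypothesis suite on a synthetic study
#'
#' Orchestrates the complete analysis: signal processing, Ia
#' simulation under every fusimotor variant, HVE/UPGMA clustering of
#' muscle-length, EMG, and Ia profiles per participant and task, and
#' the tree-comparison statistics:
#'
#' * **H1** -- Ia clusters resemble muscle-length clusters more than
#'   chance (Fowlkes--Mallows index against a leaf-permutation null;
#'   percentile p-values per cluster count, Fisher-combined per
#'   participant, Bonferroni-gated across participants).
#' * **H2** -- Ia clusters resemble EMG clusters more than chance
#'   (same machinery).
#' * **H3** -- EMG and Ia cluster structures change the same way
#'   between tasks (between-task B values per modality, bootstrap
#'   difference test per task pair).
#' * **Fusimotor variants** -- for each static-set corner model and
#'   the EMG-coupled model: similarity of its Ia trees to the
#'   reference-model trees, similarity to the EMG trees, and the
#'   paired difference from the reference model's EMG similarity with
#'   a percentile (location-of-zero) p-value.
#'
#' Also included: cophenetic goodness of fit per tree, task-dynamics
#' descriptors per participant and task, and a per-pair co-contraction
#' summary.
#'
#' @param study A [generate_dataset()] result.
#' @param n_phase Phase samples per profile (default 100).
#' @param q FDR level of the correlation significance gate (0.05).
#' @param n_perm Leaf permutations per null (default 1000).
#' @param n_boot Bootstrap resamples for H3 (default 1000).
#' @param k_min,k_max Cluster-count range for tree comparisons;
#'   defaults to 2 .. half the number of signals (6 for 12 muscles).
#' @param family_alpha Family-wise alpha for the Bonferroni gate
#'   (default 0.05 across participants).
#' @param variants Fusimotor variants to run besides the reference
#'   model; default all four static-set corners plus EMG-coupled.
#' @param seed Integer seed controlling permutation and bootstrap
#'   draws.
#' @return An object of class `study_report` (list of tibbles; see
#'   [write_report()]).
#' @export
run_hypothesis_suite <- function(study, n_phase = 100L, q = 0.05,
                                 n_perm = 1000L, n_boot = 1000L,
                                 k_min = 2L, k_max = NULL,
                                 family_alpha = 0.05,
                                 variants = c("V33-L50", "V33-L400",
                                              "V200-L50", "V200-L400",
                                              "EMG-coupled"),
                                 seed = 1L) {
  profiles <- process_study(study, n_phase = n_phase)
  n_signals <- length(unique(profiles$emg$channel))
  if (is.null(k_max)) k_max <- floor(n_signals / 2)
  ks <- seq.int(k_min, k_max)
  durations <- profiles$events %>%
    select("participant", "task", "duration_s")
  ranges <- muscle_length_ranges(study$config$arms,
                                 study$config$base_lengths)

  ia_all <- purrr::map_dfr(c("Prochazka", variants), function(v) {
    normalize_ia(ia_profiles(profiles$lengths, ranges = ranges,
                             variant = v, emg = profiles$emg,
                             duration_s = durations))
  })

  emg_trees <- trees_by_group(profiles$emg, q = q) %>%
    mutate(modality = "EMG")
  len_trees <- trees_by_group(profiles$lengths, q = q) %>%
    mutate(modality = "length")
  ia_trees <- ia_all %>%
    group_by(.data$variant) %>%
    tidyr::nest(.key = "vdata") %>%
    ungroup() %>%
    mutate(trees = purrr::map(.data$vdata, function(d) {
      trees_by_group(d %>% select("participant", "task", "channel",
                                  "phase", "value"), q = q)
    })) %>%
    select(-"vdata") %>%
    tidyr::unnest("trees") %>%
    mutate(modality = paste0("Ia:", .data$variant))

  all_trees <- bind_rows(emg_trees, len_trees,
                         ia_trees %>% select(-"variant"))
  cophenetic_tbl <- all_trees %>%
    mutate(cophenetic = purrr::map_dbl(.data$clustering, "cophenetic"),
           alpha = purrr::map_dbl(.data$clustering, "alpha")) %>%
    select("participant", "task", "modality", "cophenetic", "alpha")

  get_tree <- function(trees, pid, tk) {
    trees$clustering[trees$participant == pid & trees$task == tk][[1L]]$tree
  }
  ia_ref <- ia_trees %>% filter(.data$variant == "Prochazka")
  groups <- emg_trees %>% select("participant", "task")

  # H1 / H2: observed FM curves and permutation nulls
  compare_with_null <- function(other_trees, label, seed_offset) {
    res <- purrr::pmap_dfr(
      cbind(groups, i = seq_len(nrow(groups))),
      function(participant, task, i) {
        t_ia <- get_tree(ia_ref, participant, task)
        t_other <- get_tree(other_trees, participant, task)
        obs <- fm_curve(t_ia, t_other, k_max = k_max, k_min = k_min)
        null <- permutation_null(
          t_ia, t_other, n_perm = n_perm, k_max = k_max, k_min = k_min,
          seed = child_seed(seed, seed_offset + i))
        obs %>%
          mutate(p = purrr::map2_dbl(.data$k, .data$B, function(kk, bb) {
            percentile_pvalue(bb, null$B[null$k == kk])
          }),
          null_mean = purrr::map_dbl(.data$k, function(kk) {
            mean(null$B[null$k == kk])
          }),
          participant = participant, task = task)
      })
    combined <- res %>%
      group_by(.data$participant, .data$task) %>%
      summarise(p_combined = fisher_combined(.data$p)$p_combined,
                .groups = "drop")
    list(curves = res %>% mutate(comparison = label),
         combined = combined %>% mutate(comparison = label))
  }
  h1 <- compare_with_null(len_trees, "Ia-vs-length", 10000L)
  h2 <- compare_with_null(emg_trees, "Ia-vs-EMG", 20000L)
  alpha_bonf <- bonferroni_alpha(family_alpha,
                                 nrow(study$participants))

  # H3: between-task similarity per modality, bootstrap difference
  task_names <- unique(study$config$tasks$task)
  task_pairs <- utils::combn(task_names, 2, simplify = FALSE)
  between_task_b <- function(trees, modality) {
    purrr::map_dfr(task_pairs, function(tp) {
      purrr::map_dfr(unique(groups$participant), function(pid) {
        fm_curve(get_tree(trees, pid, tp[1]), get_tree(trees, pid, tp[2]),
                 k_max = k_max, k_min = k_min) %>%
          mutate(participant = pid, pair = paste(tp, collapse = "-"),
                 modality = modality)
      })
    })
  }
  b_emg <- between_task_b(emg_trees, "EMG")
  b_ia <- between_task_b(ia_ref, "Ia")
  h3 <- purrr::map_dfr(seq_along(task_pairs), function(pi) {
    pname <- paste(task_pairs[[pi]], collapse = "-")
    be <- b_emg$B[b_emg$pair == pname]
    bi <- b_ia$B[b_ia$pair == pname]
    bt <- bootstrap_difference(bi, be, n_boot = n_boot,
                               seed = child_seed(seed, 30000L + pi))
    tibble(pair = pname, n_b_ia = length(bi) * n_boot,
           n_b_emg = length(be) * n_boot,
           mean_b_ia = mean(bi), mean_b_emg = mean(be),
           mean_diff = bt$mean_diff, p = bt$p)
  })

  # fusimotor-variant suite
  ref_vs_emg <- purrr::pmap_dfr(groups, function(participant, task) {
    fm_curve(get_tree(ia_ref, participant, task),
             get_tree(emg_trees, participant, task),
             k_max = k_max, k_min = k_min) %>%
      mutate(participant = participant, task = task)
  })
  variant_results <- purrr::map_dfr(variants, function(v) {
    vt <- ia_trees %>% filter(.data$variant == v)
    vs_ref <- purrr::pmap_dfr(groups, function(participant, task) {
      fm_curve(get_tree(vt, participant, task),
               get_tree(ia_ref, participant, task),
               k_max = k_max, k_min = k_min) %>%
        mutate(participant = participant, task = task)
    })
    vs_emg <- purrr::pmap_dfr(groups, function(participant, task) {
      fm_curve(get_tree(vt, participant, task),
               get_tree(emg_trees, participant, task),
               k_max = k_max, k_min = k_min) %>%
        mutate(participant = participant, task = task)
    })
    diffs <- dplyr::inner_join(
      ref_vs_emg %>% rename(B_ref = "B"),
      vs_emg %>% rename(B_var = "B"),
      by = c("participant", "task", "k")) %>%
      mutate(diff = .data$B_ref - .data$B_var)
    p_loc <- min(1, 2 * min(mean(diffs$diff <= 0), mean(diffs$diff >= 0)))
    tibble(
      variant = v,
      mean_b_vs_reference = mean(vs_ref$B),
      mean_b_vs_emg = mean(vs_emg$B),
      mean_b_reference_vs_emg = mean(diffs$B_ref),
      mean_diff = mean(diffs$diff),
      p_zero_location = p_loc
    )
  })

  # co-contraction and task-dynamics summaries
  coc_summary <- profiles$cocontraction %>%
    group_by(.data$task, .data$channel) %>%
    summarise(mean_wasted = mean(.data$value), .groups = "drop") %>%
    rename(pair = "channel")
  dyn <- purrr::pmap_dfr(groups, function(participant, task) {
    traj <- study$kinematics %>%
      filter(.data$participant == !!participant, .data$task == !!task)
    model <- anthropometric_arm(
      study$participants$height_m[study$participants$participant == participant],
      study$participants$weight_kg[study$participants$participant == participant])
    ev <- profiles$events %>%
      filter(.data$participant == !!participant, .data$task == !!task)
    task_dynamics(chain_trajectory(traj), model,
                  onset_s = ev$onset_s, offset_s = ev$offset_s) %>%
      mutate(participant = participant, task = task)
  })

  structure(
    list(
      profiles = profiles,
      ia = ia_all,
      trees = all_trees,
      cophenetic = cophenetic_tbl,
      h1_curves = h1$curves, h1_combined = h1$combined,
      h2_curves = h2$curves, h2_combined = h2$combined,
      h3 = h3,
      between_task_b = bind_rows(b_emg, b_ia),
      variants = variant_results,
      cocontraction_summary = coc_summary,
      task_dynamics = dyn,
      alpha_bonferroni = alpha_bonf,
      settings = list(n_phase = n_phase, q = q, n_perm = n_perm,
                      n_boot = n_boot, k_min = k_min, k_max = k_max,
                      seed = as.integer(seed))
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Reaching-study hypothesis suite\n")
  cat("  participants x tasks: ",
      length(unique(x$cophenetic$participant)), " x ",
      length(unique(x$cophenetic$task)), "\n", sep = "")
  cat("  Bonferroni alpha: ", x$alpha_bonferroni, "\n", sep = "")
  cat("  H1 (Ia vs length) combined p <= alpha: ",
      sum(x$h1_combined$p_combined <= x$alpha_bonferroni), "/",
      nrow(x$h1_combined), "\n", sep = "")
  cat("  H2 (Ia vs EMG)    combined p <= alpha: ",
      sum(x$h2_combined$p_combined <= x$alpha_bonferroni), "/",
      nrow(x$h2_combined), "\n", sep = "")
  cat("  H3 task pairs with p <= alpha: ",
      sum(x$h3$p <= x$alpha_bonferroni), "/", nrow(x$h3), "\n", sep = "")
  invisible(x)
}

#' Write a study report to delimited files
#'
#' Serializes every result table of a [run_hypothesis_suite()] report
#' as CSV (deterministic formatting, so a fixed-seed run is
#' byte-stable), the trees as Newick strings, and a JSON manifest of
#' the settings.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "study_report")) {
    abort("`report` must come from run_hypothesis_suite().")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    cophenetic = report$cophenetic,
    h1_curves = report$h1_curves, h1_combined = report$h1_combined,
    h2_curves = report$h2_curves, h2_combined = report$h2_combined,
    h3 = report$h3,
    between_task_b = report$between_task_b,
    variants = report$variants,
    cocontraction_summary = report$cocontraction_summary,
    task_dynamics = report$task_dynamics,
    emg_profiles = report$profiles$emg,
    cocontraction_profiles = report$profiles$cocontraction,
    events = report$profiles$events
  )
  tabs$distances <- report$trees %>%
    mutate(pairs = purrr::map(.data$clustering, tidy)) %>%
    select("participant", "task", "modality", "pairs") %>%
    tidyr::unnest("pairs")
  files <- character(0)
  for (nm in names(tabs)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tabs[[nm]], f)
    files <- c(files, f)
  }
  if (requireNamespace("ape", quietly = TRUE)) {
    trees <- report$trees %>%
      mutate(newick = purrr::map_chr(.data$clustering, export_newick)) %>%
      select("participant", "task", "modality", "newick")
    f <- file.path(dir, "trees.csv")
    readr::write_csv(trees, f)
    files <- c(files, f)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    f <- file.path(dir, "settings.json")
    jsonlite::write_json(
      c(report$settings, list(alpha_bonferroni = report$alpha_bonferroni)),
      f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}
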