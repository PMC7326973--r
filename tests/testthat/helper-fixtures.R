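# Shared fixtures, built in code and memoised per test run.

.fixtures <- new.env(parent = emptyenv())

# A one-participant, few-trial study: fast enough for most pipeline
# tests while exercising every generator stage.
tiny_study <- function() {
  if (is.null(.fixtures$tiny)) {
    cfg <- study_config(n_participants = 1L, n_trials = 4L)
    .fixtures$tiny <- generate_dataset(cfg, seed = 101L)
  }
  .fixtures$tiny
}

tiny_profiles <- function() {
  if (is.null(.fixtures$tiny_prof)) {
    .fixtures$tiny_prof <- suppressWarnings(process_study(tiny_study()))
  }
  .fixtures$tiny_prof
}

# Minimum-jerk displacement with rest padding on both sides.
padded_min_jerk <- function(fs = 480, rest_s = 0.5, dur = 1, amp = 0.3,
                            total = 2) {
  t <- seq(0, total, by = 1 / fs)
  s <- pmin(pmax((t - rest_s) / dur, 0), 1)
  list(t = t, x = amp * (10 * s^3 - 15 * s^4 + 6 * s^5),
       onset_idx = which(t >= rest_s)[1],
       offset_idx = which(t >= rest_s + dur)[1])
}

# Long-format three-joint trajectory from minimum-jerk profiles with
# analytic derivatives (chain convention, radians).
min_jerk_trajectory3 <- function(fs = 480, dur = 1,
                                 start = c(-pi / 2 + 0.2, 0.2, 0),
                                 end = c(0.6, 1.4, 0)) {
  n <- round(dur * fs) + 1L
  joints <- c("shoulder", "elbow", "wrist")
  dplyr::bind_rows(lapply(seq_along(joints), function(i) {
    mj <- minimum_jerk_trajectory(start[i], end[i], dur, n)
    tibble::tibble(time_s = mj$time_s, joint = joints[i],
                   angle_rad = mj$value, velocity_rad_s = mj$velocity,
                   acceleration_rad_s2 = mj$acceleration)
  }))
}

# A deterministic UPGMA tree over n labelled leaves with distinct
# pairwise distances.
labelled_tree <- function(n = 6) {
  set.seed(99)
  m <- matrix(runif(n * n, 0.2, 1.8), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("ch", seq_len(n))
  upgma(m)
}
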