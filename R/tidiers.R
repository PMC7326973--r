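#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a profile correlation into pair rows
#'
#' @param x A `profile_correlation` from [pairwise_correlation()].
#' @param ... Unused.
#' @return A tibble with one row per unordered channel pair: columns
#'   `channel1`, `channel2`, `r`, `p`.
#' @export
tidy.profile_correlation <- function(x, ...) {
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble(
    channel1 = x$channels[idx[, "col"]],
    channel2 = x$channels[idx[, "row"]],
    r = x$r[idx],
    p = x$p[idx]
  )
}

#' @rdname tidy.profile_correlation
#' @export
glance.profile_correlation <- function(x, ...) {
  tibble(n_channels = length(x$channels), n_phase = x$n_phase,
         mean_abs_r = mean(abs(x$r[lower.tri(x$r)])))
}

#' Tidy a profile clustering into pairwise distances
#'
#' @param x A `profile_clustering` from [cluster_profiles()].
#' @param ... Unused.
#' @return A tibble with columns `channel1`, `channel2`, `r`, `p`,
#'   `hve` (the distance fed to the linkage), and `cophenetic` (the
#'   distance implied by the tree).
#' @export
tidy.profile_clustering <- function(x, ...) {
  out <- tidy(x$correlation)
  idx <- which(lower.tri(x$hve), arr.ind = TRUE)
  out$hve <- x$hve[idx]
  coph <- as.matrix(cophenetic(x$tree))[x$channels, x$channels]
  out$cophenetic <- coph[idx]
  out
}

#' @rdname tidy.profile_clustering
#' @export
glance.profile_clustering <- function(x, ...) {
  tibble(
    n_channels = length(x$channels),
    cophenetic = x$cophenetic,
    alpha = x$alpha,
    n_significant = sum(x$hve[lower.tri(x$hve)] != 1)
  )
}

#' Tidy a Fowlkes--Mallows computation
#'
#' @param x An `fm_index` from [fowlkes_mallows()].
#' @param ... Unused.
#' @return A one-row tibble with columns `B`, `T`, `P`, `Q`, `n`,
#'   `k1`, `k2`.
#' @export
tidy.fm_index <- function(x, ...) {
  tibble(B = x$B, T = x$T, P = x$P, Q = x$Q, n = x$n,
         k1 = x$k[1], k2 = x$k[2])
}

#' Tidy a bootstrap difference test
#'
#' @param x An `fm_bootstrap` from [bootstrap_difference()].
#' @param ... Unused.
#' @return A one-row tibble with `mean_diff`, `p`, `n_diff`,
#'   `q025`, `q975` (percentile interval of the difference).
#' @export
tidy.fm_bootstrap <- function(x, ...) {
  qs <- stats::quantile(x$diff, c(0.025, 0.975), names = FALSE)
  tibble(mean_diff = x$mean_diff, p = x$p, n_diff = length(x$diff),
         q025 = qs[1], q975 = qs[2])
}

#' Tidy a study report into hypothesis-level results
#'
#' @param x A `study_report` from [run_hypothesis_suite()].
#' @param ... Unused.
#' @return A tibble with one row per hypothesis-level test: columns
#'   `hypothesis`, `unit` (participant/task or task pair), `p`,
#'   `significant` (against the Bonferroni-adjusted alpha).
#' @export
tidy.study_report <- function(x, ...) {
  bind_rows(
    x$h1_combined %>%
      mutate(hypothesis = "H1: Ia vs length",
             unit = paste(.data$participant, .data$task, sep = "/")) %>%
      select("hypothesis", "unit", p = "p_combined"),
    x$h2_combined %>%
      mutate(hypothesis = "H2: Ia vs EMG",
             unit = paste(.data$participant, .data$task, sep = "/")) %>%
      select("hypothesis", "unit", p = "p_combined"),
    x$h3 %>%
      mutate(hypothesis = "H3: between-task B_Ia vs B_EMG",
             unit = .data$pair) %>%
      select("hypothesis", "unit", "p"),
    x$variants %>%
      mutate(hypothesis = "Variant vs reference (EMG similarity)",
             unit = .data$variant) %>%
      select("hypothesis", "unit", p = "p_zero_location")
  ) %>%
    mutate(significant = .data$p <= x$alpha_bonferroni)
}

#' @rdname tidy.study_report
#' @export
glance.study_report <- function(x, ...) {
  tibble(
    n_participants = length(unique(x$cophenetic$participant)),
    n_tasks = length(unique(x$cophenetic$task)),
    alpha_bonferroni = x$alpha_bonferroni,
    mean_cophenetic = mean(x$cophenetic$cophenetic, na.rm = TRUE),
    h1_supported = sum(x$h1_combined$p_combined <= x$alpha_bonferroni),
    h2_supported = sum(x$h2_combined$p_combined <= x$alpha_bonferroni),
    h3_significant_pairs = sum(x$h3$p <= x$alpha_bonferroni)
  )
}
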