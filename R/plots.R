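#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Dendrogram segment coordinates from an hclust tree (leaf positions
# follow tree$order, heights from the merge sequence).
dendrogram_segments <- function(tree) {
  n <- length(tree$order)
  xpos <- numeric(n)
  xpos[tree$order] <- seq_len(n)
  node_x <- numeric(nrow(tree$merge))
  node_h <- tree$height
  segs <- vector("list", nrow(tree$merge))
  at <- function(id) {
    if (id < 0) c(x = xpos[-id], h = 0) else c(x = node_x[id], h = node_h[id])
  }
  for (i in seq_len(nrow(tree$merge))) {
    a <- at(tree$merge[i, 1]); b <- at(tree$merge[i, 2])
    node_x[i] <- (a["x"] + b["x"]) / 2
    h <- tree$height[i]
    segs[[i]] <- tibble(
      x = c(a["x"], a["x"], b["x"]),
      xend = c(a["x"], b["x"], b["x"]),
      y = c(a["h"], h, b["h"]),
      yend = c(h, h, h)
    )
  }
  list(segments = bind_rows(segs),
       leaves = tibble(x = seq_len(n), label = tree$labels[tree$order]))
}

#' Plot a profile clustering as a dendrogram
#'
#' Dendrogram of the UPGMA tree with the HVE distance on the vertical
#' axis: height 0 means perfectly correlated (significant r = 1),
#' height 1 is the non-significant plateau, height near 2 indicates
#' strong antagonism.
#'
#' @param object A `profile_clustering` from [cluster_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_clustering <- function(object, ...) {
  dd <- dendrogram_segments(object$tree)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = dd$segments,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = dd$leaves$x,
                                labels = dd$leaves$label) +
    ggplot2::labs(x = NULL, y = "HVE distance",
                  title = sprintf("UPGMA tree (cophenetic r = %.2f)",
                                  object$cophenetic)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot normalized phase profiles
#'
#' Line plot of movement-phase profiles, one facet per channel,
#' coloured by task -- the standard view of normalized EMG,
#' co-contraction, or Ia profiles.
#'
#' @param profiles A tibble with columns `task`, `channel`, `phase`,
#'   and `value` (e.g. from [process_study()] or [normalize_ia()]).
#'   Multiple participants are averaged.
#' @param ncol Facet columns (default 4).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, ncol = 4) {
  dat <- profiles %>%
    group_by(.data$task, .data$channel, .data$phase) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phase, y = .data$value,
                                    colour = .data$task)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap("channel", ncol = ncol, scales = "free_y") +
    ggplot2::labs(x = "Movement phase", y = "Normalized amplitude",
                  colour = "Task") +
    ggplot2::theme_minimal()
}

#' Plot Fowlkes--Mallows curves against their permutation null
#'
#' Observed between-tree similarity (mean across participants, with
#' pooled-SD error bars) per cluster count, overlaid on the mean of
#' the leaf-permutation null.
#'
#' @param curves A curve table from a study report (`h1_curves` or
#'   `h2_curves`): columns `participant`, `task`, `k`, `B`,
#'   `null_mean`.
#' @return A ggplot object.
#' @export
plot_fm_curves <- function(curves) {
  summ2 <- curves %>%
    group_by(.data$task, .data$k) %>%
    summarise(mean_B = mean(.data$B), sd_B = sd(.data$B),
              null_B = mean(.data$null_mean), .groups = "drop")
  ggplot2::ggplot(summ2, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_B - .data$sd_B,
                                      ymax = .data$mean_B + .data$sd_B),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_B,
                                    colour = "observed")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_B,
                                    colour = "permutation null"),
                       linetype = 2) +
    ggplot2::facet_wrap("task") +
    ggplot2::labs(x = "Cluster count k", y = "Fowlkes-Mallows B",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
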