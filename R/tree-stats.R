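# Fast Fowlkes-Mallows core: integer cluster id vectors (1..k1 / 1..k2)
# over the same objects. Returns NA when either marginal is degenerate
# (all singletons or a single cluster).
fm_index_core <- function(x, y) {
  n <- length(x)
  k1 <- max(x); k2 <- max(y)
  m <- tabulate((x - 1L) * k2 + y, nbins = k1 * k2)
  Tk <- sum(as.double(m)^2) - n
  rows <- tabulate(x, nbins = k1)
  cols <- tabulate(y, nbins = k2)
  Pk <- sum(as.double(rows)^2) - n
  Qk <- sum(as.double(cols)^2) - n
  if (Pk <= 0 || Qk <= 0) return(NA_real_)
  if (Tk == 0) return(0)
  Tk / sqrt(Pk * Qk)
}

#' Fowlkes--Mallows index between two clusterings
#'
#' Similarity between two hard clusterings of the same objects at a
#' common cluster count k, computed from the k x k match-count matrix
#' `m_ij` (objects shared by cluster i of the first assignment and
#' cluster j of the second):
#' `T = sum(m_ij^2) - n`, `P = sum(rowsums^2) - n`,
#' `Q = sum(colsums^2) - n`, `B = T / sqrt(P * Q)`.
#' `B = 1` indicates identical clusterings; the index is symmetric and
#' invariant to relabeling of the clusters, and it approaches 0 for
#' independent clusterings as n grows, making it less prone to spurious
#' agreement than the Rand index. `B = 0` is returned when `T = 0`.
#'
#' @param a1,a2 Cluster assignments over the same objects: integer or
#'   factor vectors, or named vectors from [cut_tree()] (names are
#'   used for alignment when present on both).
#' @return An object of class `fm_index`: list with elements `B`, `T`,
#'   `P`, `Q`, `m` (match-count matrix), `n`, and `k` (cluster counts).
#' @export
#' @examples
#' fowlkes_mallows(c(1, 1, 2, 2), c(1, 1, 2, 2))$B  # 1
#' fowlkes_mallows(c(1, 1, 2, 2), c(1, 2, 1, 2))$B  # 0
fowlkes_mallows <- function(a1, a2) {
  if (!is.null(names(a1)) && !is.null(names(a2))) {
    if (!setequal(names(a1), names(a2))) {
      abort("Assignments cover different object sets.")
    }
    a2 <- a2[names(a1)]
  }
  if (length(a1) != length(a2)) {
    abort("Assignments cover different object sets.")
  }
  x <- as.integer(factor(a1)); y <- as.integer(factor(a2))
  n <- length(x)
  k1 <- max(x); k2 <- max(y)
  m <- matrix(tabulate((x - 1L) * k2 + y, nbins = k1 * k2),
              nrow = k1, ncol = k2, byrow = TRUE)
  Tk <- sum(as.double(m)^2) - n
  Pk <- sum(as.double(rowSums(m))^2) - n
  Qk <- sum(as.double(colSums(m))^2) - n
  if (Pk <= 0 || Qk <= 0) {
    abort("Fowlkes-Mallows undefined: a marginal is all singletons or one cluster.")
  }
  B <- if (Tk == 0) 0 else Tk / sqrt(Pk * Qk)
  structure(list(B = B, T = Tk, P = Pk, Q = Qk, m = m, n = n,
                 k = c(k1, k2)),
            class = "fm_index")
}

#' @export
print.fm_index <- function(x, ...) {
  cat(sprintf("Fowlkes-Mallows index: B = %.4f (n = %d, k = %d x %d)\n",
              x$B, x$n, x$k[1], x$k[2]))
  invisible(x)
}

#' Fowlkes--Mallows curve across cluster counts
#'
#' Cuts two trees over the same channel set at each k and computes the
#' Fowlkes--Mallows index, up to `k_max` (default half the number of
#' signals). Values of k at which the index is undefined (degenerate
#' marginals) are dropped.
#'
#' @param t1,t2 `hclust` trees (or `profile_clustering` objects) over
#'   the same labels.
#' @param k_max Largest cluster count; defaults to
#'   `floor(n_signals / 2)`.
#' @param k_min Smallest cluster count (default 2).
#' @return A tibble with columns `k` and `B`.
#' @export
fm_curve <- function(t1, t2, k_max = NULL, k_min = 2L) {
  t1 <- as_hclust(t1); t2 <- as_hclust(t2)
  if (!setequal(t1$labels, t2$labels)) {
    abort("Trees are built over different channel sets.")
  }
  n <- length(t1$labels)
  if (is.null(k_max)) k_max <- floor(n / 2)
  ks <- seq.int(max(2L, k_min), min(k_max, n))
  vals <- purrr::map_dbl(ks, function(k) {
    a1 <- cut_tree(t1, k)
    a2 <- cut_tree(t2, k)[names(a1)]
    fm_index_core(as.integer(a1), as.integer(factor(a2)))
  })
  tibble(k = ks, B = vals) %>% filter(is.finite(.data$B))
}

as_hclust <- function(x) {
  if (inherits(x, "profile_clustering")) return(x$tree)
  if (!inherits(x, "hclust")) abort("Expected an hclust tree.")
  x
}

#' Permutation null distribution of the Fowlkes--Mallows index
#'
#' Estimates the distribution of B expected by chance for two trees by
#' uniformly relabeling the leaves of both trees independently on each
#' draw (tree shapes are preserved; signal identity is randomized) and
#' recomputing B at every cluster count.
#'
#' @param t1,t2 Trees as in [fm_curve()].
#' @param n_perm Number of permutations (default 1000).
#' @param k_max,k_min Cluster-count range as in [fm_curve()].
#' @param seed Integer seed for reproducibility.
#' @return A tibble with columns `perm`, `k`, `B`.
#' @export
permutation_null <- function(t1, t2, n_perm = 1000L, k_max = NULL,
                             k_min = 2L, seed = 1L) {
  t1 <- as_hclust(t1); t2 <- as_hclust(t2)
  if (n_perm < 1L) abort("`n_perm` must be at least 1.")
  n <- length(t1$labels)
  if (is.null(k_max)) k_max <- floor(n / 2)
  ks <- seq.int(max(2L, k_min), min(k_max, n))
  cuts1 <- lapply(ks, function(k) as.integer(cut_tree(t1, k)))
  cuts2 <- lapply(ks, function(k) {
    a <- cut_tree(t2, k)[t1$labels]
    as.integer(factor(a))
  })
  set.seed(seed)
  res <- matrix(NA_real_, nrow = n_perm, ncol = length(ks))
  for (i in seq_len(n_perm)) {
    p1 <- sample.int(n); p2 <- sample.int(n)
    for (j in seq_along(ks)) {
      res[i, j] <- fm_index_core(cuts1[[j]][p1], cuts2[[j]][p2])
    }
  }
  out <- tibble(
    perm = rep(seq_len(n_perm), times = length(ks)),
    k = rep(ks, each = n_perm),
    B = as.numeric(res)
  )
  out %>% filter(is.finite(.data$B))
}

#' Percentile-method p-value
#'
#' Upper-tail p-value of an observed statistic within an empirical null
#' distribution, with the add-one finite-sample correction:
#' `p = (1 + #\{null >= observed\}) / (n_null + 1)`, so p is never
#' exactly zero.
#'
#' @param observed Observed statistic (scalar).
#' @param null Numeric vector of null draws.
#' @return p-value in (0, 1\].
#' @export
percentile_pvalue <- function(observed, null) {
  if (!length(null)) abort("Empty null distribution.")
  stopifnot_scalar_number(observed, "observed")
  (1 + sum(null >= observed)) / (length(null) + 1)
}

#' Bootstrap difference test between two collections of B values
#'
#' Resamples each collection with replacement `n_boot` times (each
#' resample the size of its source, independently for the two
#' collections since they come from different signal modalities), forms
#' one difference sample per resample -- the difference of the two
#' resample means, `mean(b1*) - mean(b2*)` -- and locates zero in the
#' resulting distribution: `p = 2 * min(frac <= 0, frac >= 0)`
#' two-sided, with the add-one finite-sample correction, capped at 1.
#'
#' @param b1,b2 Numeric vectors of B values (e.g. per participant and
#'   cluster count).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return An object of class `fm_bootstrap`: list with `diff` (the
#'   `n_boot` mean-difference samples), `b1_boot`, `b2_boot` (matrices
#'   n_boot x length holding every resampled B value), `p`,
#'   `mean_diff`.
#' @export
bootstrap_difference <- function(b1, b2, n_boot = 1000L, seed = 1L) {
  if (!length(b1) || !length(b2)) abort("Both B collections must be non-empty.")
  if (n_boot < 1L) abort("`n_boot` must be at least 1.")
  set.seed(seed)
  n1 <- length(b1); n2 <- length(b2)
  b1_boot <- matrix(sample(b1, n_boot * n1, replace = TRUE), nrow = n_boot)
  b2_boot <- matrix(sample(b2, n_boot * n2, replace = TRUE), nrow = n_boot)
  diffs <- rowMeans(b1_boot) - rowMeans(b2_boot)
  p <- min(1, 2 * min((1 + sum(diffs <= 0)) / (n_boot + 1),
                      (1 + sum(diffs >= 0)) / (n_boot + 1)))
  structure(list(diff = diffs, b1_boot = b1_boot, b2_boot = b2_boot,
                 p = p, mean_diff = mean(diffs)),
            class = "fm_bootstrap")
}

#' @export
print.fm_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap B difference: mean = %.4f, p = %.4g (%d samples)\n",
              x$mean_diff, x$p, length(x$diff)))
  invisible(x)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via `X2 = -2 * sum(log(p))`, referred
#' to a chi-square distribution with `2 * length(p)` degrees of
#' freedom. Zero p-values are clipped to the smallest representable
#' double with a warning.
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @return A list with `statistic`, `df`, and `p_combined`.
#' @export
#' @examples
#' fisher_combined(c(0.05, 0.05))
fisher_combined <- function(p) {
  if (!length(p)) abort("Empty p-value vector.")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  if (any(p == 0)) {
    warn("Zero p-value(s) clipped to the smallest representable double.")
    p <- pmax(p, .Machine$double.xmin)
  }
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = x2, df = df,
       p_combined = pchisq(x2, df = df, lower.tail = FALSE))
}

#' Bonferroni-adjusted per-test alpha
#'
#' Family-wise alpha divided by the number of repeated tests, reported
#' at 4 decimals (e.g. 0.05 over 9 participants gives 0.0056).
#'
#' @param family_alpha Family-wise error level (default 0.05).
#' @param m Number of tests (>= 1).
#' @return Per-test alpha, rounded to 4 decimals.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 9)  # 0.0056
bonferroni_alpha <- function(family_alpha = 0.05, m) {
  if (m < 1) abort("`m` must be at least 1.")
  round(family_alpha / m, 4)
}

#' t-test on cluster-averaged shared variance
#'
#' Compares R-squared values averaged across the members of a cluster,
#' one average per participant, between two conditions. Participants
#' are treated as independent samples; when every participant is
#' present in both conditions the test is paired.
#'
#' @param data A data frame with columns `participant`, `condition`
#'   (two levels), and `r2` (participant-level cluster-averaged R^2).
#' @return A tibble with columns `estimate` (mean difference),
#'   `statistic`, `df`, `p_value`, `method`.
#' @export
cluster_r2_ttest <- function(data) {
  needed <- c("participant", "condition", "r2")
  if (!all(needed %in% names(data))) {
    abort("`data` needs columns participant, condition, r2.")
  }
  conds <- unique(data$condition)
  if (length(conds) != 2L) abort("`condition` must have exactly two levels.")
  a <- data[data$condition == conds[1L], ]
  b <- data[data$condition == conds[2L], ]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    abort("Need at least 2 participants per condition.")
  }
  paired <- setequal(a$participant, b$participant) &&
    !anyDuplicated(a$participant) && !anyDuplicated(b$participant)
  if (paired) {
    b <- b[match(a$participant, b$participant), ]
    d <- a$r2 - b$r2
    if (var(d) == 0) {
      # degenerate: identical (p = 1) or constant nonzero shift (p -> 0)
      return(tibble(
        estimate = mean(d), statistic = ifelse(all(d == 0), 0, Inf),
        df = nrow(a) - 1, p_value = ifelse(all(d == 0), 1, 0),
        method = "paired t (degenerate zero variance)"
      ))
    }
    tt <- t.test(a$r2, b$r2, paired = TRUE)
  } else {
    tt <- t.test(a$r2, b$r2)
  }
  tibble(
    estimate = unname(if (paired) tt$estimate else diff(rev(tt$estimate))),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    method = if (paired) "paired t" else "Welch t"
  )
}

#' Pooled standard deviation across participants
#'
#' Root mean square of per-participant standard deviations,
#' `sqrt(mean(sd^2))` -- the dispersion summary used for error bars on
#' across-participant averages.
#'
#' @param sds Numeric vector of per-participant standard deviations.
#' @return A single pooled SD.
#' @export
#' @examples
#' pooled_sd(c(3, 4))  # sqrt(12.5)
pooled_sd <- function(sds) {
  if (!length(sds)) abort("Empty SD vector.")
  sqrt(mean(sds^2))
}
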