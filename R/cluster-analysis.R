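#' Pairwise Pearson correlations between phase profiles
#'
#' Builds the correlation matrix across channels of a profile table,
#' with two-sided p-values from the t approximation with
#' `n_phase - 2` degrees of freedom (phase samples treated as
#' independent). Channels with zero variance produce undefined
#' correlations; their pairs are returned with `r = 0` and `p = 1`
#' (forced non-significant) and a warning, so the channel set stays
#' aligned across tasks.
#'
#' @param profiles A data frame with columns `channel`, `phase`,
#'   `value` for a single participant x task (or any single grouping),
#'   or a channels x phase numeric matrix with rownames.
#' @return An object of class `profile_correlation`: list with
#'   elements `r` (matrix), `p` (matrix), `n_phase`, and `channels`.
#' @export
pairwise_correlation <- function(profiles) {
  mat <- profile_matrix(profiles)
  n_phase <- ncol(mat)
  if (n_phase < 3L) abort("Need at least 3 phase samples per profile.")
  constant <- apply(mat, 1L, function(x) var(x) == 0 || !is.finite(var(x)))
  if (any(constant)) {
    warn(paste0("Constant profile(s): ",
                paste(rownames(mat)[constant], collapse = ", "),
                "; their correlations are marked non-significant."))
  }
  r <- suppressWarnings(cor(t(mat)))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  tstat <- r * sqrt((n_phase - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n_phase - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  if (any(constant)) {
    r[constant, ] <- 0; r[, constant] <- 0
    p[constant, ] <- 1; p[, constant] <- 1
    diag(r) <- 1; diag(p) <- 0
  }
  structure(
    list(r = r, p = p, n_phase = n_phase, channels = rownames(mat)),
    class = "profile_correlation"
  )
}

# channels x phase matrix from a long profile table (or pass-through).
profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    if (is.null(rownames(profiles))) {
      rownames(profiles) <- paste0("ch", seq_len(nrow(profiles)))
    }
    return(profiles)
  }
  needed <- c("channel", "phase", "value")
  if (!all(needed %in% names(profiles))) {
    abort("`profiles` needs columns channel, phase, value (or be a matrix).")
  }
  extra <- intersect(c("participant", "task"), names(profiles))
  for (col in extra) {
    if (length(unique(profiles[[col]])) > 1L) {
      abort(sprintf(
        "`profiles` spans several values of `%s`; correlate one group at a time.",
        col))
    }
  }
  if (anyDuplicated(profiles[, c("channel", "phase")])) {
    abort("Duplicate channel x phase rows in `profiles`.")
  }
  wide <- tidyr::pivot_wider(profiles[, needed], names_from = "phase",
                             values_from = "value")
  mat <- as.matrix(wide[, -1L])
  rownames(mat) <- wide$channel
  mat
}

#' Two-stage Benjamini--Krieger--Yekutieli FDR procedure
#'
#' Adaptive two-stage linear step-up procedure controlling the false
#' discovery rate at level `q`: stage one runs the BH step-up at
#' `q' = q / (1 + q)` to estimate the number of true nulls
#' `m0 = m - r1`; stage two reruns the step-up at `q' * m / m0`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param q Target FDR level (default 0.05).
#' @return Logical vector marking rejected hypotheses, with attribute
#'   `alpha`: the largest rejected p-value (0 when none), i.e. the
#'   effective per-matrix significance threshold.
#' @references Benjamini, Y., Krieger, A. M., & Yekutieli, D. (2006).
#'   Adaptive linear step-up procedures that control the false
#'   discovery rate. Biometrika 93(3), 491-507.
#' @export
bky_fdr <- function(p, q = 0.05) {
  if (!length(p)) abort("Empty p-value vector.")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  m <- length(p)
  step_up <- function(p, q) {
    o <- order(p)
    thresh <- seq_len(m) * q / m
    ok <- which(p[o] <= thresh)
    rej <- logical(m)
    if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  r1 <- sum(step_up(p, q1))
  if (r1 == 0L) {
    out <- logical(m)
    attr(out, "alpha") <- 0
    return(out)
  }
  if (r1 == m) {
    out <- rep(TRUE, m)
    attr(out, "alpha") <- max(p)
    return(out)
  }
  m0 <- m - r1
  out <- step_up(p, q1 * m / m0)
  attr(out, "alpha") <- if (any(out)) max(p[out]) else 0
  out
}

#' Heterogeneous variance explained (HVE) distance
#'
#' Signed transform of a Pearson correlation into a dissimilarity in
#' \[0, 2\]: significant positive correlations map to `1 - r^2`
#' (agonistic relationships become short distances near 0), significant
#' negative correlations to `1 + r^2` (antagonistic relationships
#' become long distances near 2), and non-significant pairs to 1. An
#' exactly zero significant correlation also maps to 1.
#'
#' @param r Correlation value(s) in \[-1, 1\].
#' @param significant Logical, same length (recycled): whether the
#'   correlation passed the significance gate.
#' @return Numeric distance(s) in \[0, 2\].
#' @export
#' @examples
#' hve(c(1, -1, 0.9), c(TRUE, TRUE, FALSE))  # 0, 2, 1
hve <- function(r, significant) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    abort("Correlations must lie in [-1, 1].")
  }
  r <- pmin(pmax(r, -1), 1)
  out <- rep(1, length(r))
  sig <- rep_len(as.logical(significant), length(r))
  out[sig & r > 0] <- 1 - r[sig & r > 0]^2
  out[sig & r < 0] <- 1 + r[sig & r < 0]^2
  out
}

#' HVE distance matrix from a correlation result
#'
#' Gates the correlation matrix by the two-stage BKY FDR applied to its
#' below-diagonal p-values (one family per matrix) and applies the
#' [hve()] transform.
#'
#' @param corr A `profile_correlation` from [pairwise_correlation()].
#' @param q FDR level for the significance gate (default 0.05).
#' @return A symmetric, zero-diagonal distance matrix with entries in
#'   \[0, 2\] and attribute `alpha` (the effective threshold).
#' @export
hve_matrix <- function(corr, q = 0.05) {
  if (!inherits(corr, "profile_correlation")) {
    abort("`corr` must come from pairwise_correlation().")
  }
  r <- corr$r; p <- corr$p
  low <- lower.tri(r)
  mask <- bky_fdr(p[low], q = q)
  sig <- matrix(FALSE, nrow(r), ncol(r), dimnames = dimnames(r))
  sig[low] <- mask
  sig <- sig | t(sig)
  d <- matrix(hve(r, sig), nrow(r), dimnames = dimnames(r))
  diag(d) <- 0
  attr(d, "alpha") <- attr(mask, "alpha")
  d
}

#' UPGMA hierarchical clustering of an HVE matrix
#'
#' Unweighted pair-group average linkage on a symmetric zero-diagonal
#' dissimilarity matrix (`stats::hclust(method = "average")`). Ties are
#' broken deterministically by `hclust`'s lowest-index rule, so the
#' tree is invariant to channel input order.
#'
#' @param d Symmetric numeric matrix with zero diagonal (e.g. from
#'   [hve_matrix()]), or a `dist` object.
#' @return An `hclust` tree.
#' @export
upgma <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8)) {
      abort("`d` must be symmetric.")
    }
    d <- as.dist(d)
  }
  if (!inherits(d, "dist")) abort("`d` must be a matrix or dist object.")
  hclust(d, method = "average")
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original dissimilarities and the
#' cophenetic distances implied by the dendrogram; values near 1
#' indicate the tree represents the dissimilarity structure faithfully.
#'
#' @param tree An `hclust` tree (e.g. from [upgma()]).
#' @param d The dissimilarity matrix (or `dist`) the tree was built on.
#' @return A single correlation value.
#' @export
cophenetic_coefficient <- function(tree, d) {
  if (is.matrix(d)) d <- as.dist(d)
  if (attr(d, "Size") < 3L) {
    abort("Cophenetic correlation needs at least 3 channels.")
  }
  cor(as.numeric(d), as.numeric(cophenetic(tree)))
}

#' Cut a tree into k clusters
#'
#' Thin wrapper over `stats::cutree` returning the assignment as a
#' named integer vector with exactly `k` non-empty clusters. Cluster
#' ids are arbitrary; all comparisons downstream are label-invariant.
#'
#' @param tree An `hclust` tree.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector of cluster ids.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) abort("`k` must lie between 1 and the leaf count.")
  cutree(tree, k = k)
}

#' Cluster a set of normalized profiles
#'
#' One-shot wrapper running the full distance pipeline for one
#' participant x task group: Pearson correlations, two-stage BKY
#' significance gate, HVE transform, and UPGMA linkage.
#'
#' @param profiles Long profile table or channels x phase matrix (see
#'   [pairwise_correlation()]).
#' @param q FDR level for the significance gate (default 0.05).
#' @return An object of class `profile_clustering`: list with elements
#'   `tree` (`hclust`), `hve` (distance matrix), `correlation`
#'   (`profile_correlation`), `cophenetic` (goodness of fit), `alpha`
#'   (effective significance threshold), `channels`.
#' @export
cluster_profiles <- function(profiles, q = 0.05) {
  corr <- pairwise_correlation(profiles)
  d <- hve_matrix(corr, q = q)
  tree <- upgma(d)
  structure(
    list(
      tree = tree, hve = d, correlation = corr,
      cophenetic = if (length(corr$channels) >= 3L)
        cophenetic_coefficient(tree, d) else NA_real_,
      alpha = attr(d, "alpha"),
      channels = corr$channels
    ),
    class = "profile_clustering"
  )
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat("Profile clustering (HVE / UPGMA)\n")
  cat("  channels: ", length(x$channels), "\n", sep = "")
  cat("  cophenetic correlation: ", format(x$cophenetic, digits = 3),
      "\n", sep = "")
  cat("  significance threshold alpha: ", format(x$alpha, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Export a clustering tree in Newick format
#'
#' Writes the UPGMA dendrogram as a Newick string (via the ape
#' package) for external tree viewers.
#'
#' @param tree An `hclust` tree or a `profile_clustering`.
#' @param file Optional path; when given the string is written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
export_newick <- function(tree, file = NULL) {
  if (inherits(tree, "profile_clustering")) tree <- tree$tree
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export needs the `ape` package.")
  }
  phy <- ape::as.phylo(tree)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}
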