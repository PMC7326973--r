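test_that("pairwise correlations behave at the extremes", {
  phase <- seq(0, 1, length.out = 100)
  prof <- dplyr::bind_rows(
    tibble::tibble(channel = "a", phase = phase, value = sin(pi * phase)),
    tibble::tibble(channel = "b", phase = phase, value = -sin(pi * phase)),
    tibble::tibble(channel = "c", phase = phase, value = 2 * sin(pi * phase))
  )
  corr <- pairwise_correlation(prof)
  expect_equal(diag(corr$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(corr$r["a", "c"], 1)       # scaled copy
  expect_equal(corr$r["a", "b"], -1)      # negation
  expect_equal(corr$p["a", "c"], 0)

  # two independent white-noise profiles: |r| below 0.3 almost surely
  set.seed(33)
  noise <- dplyr::bind_rows(
    tibble::tibble(channel = "n1", phase = phase, value = rnorm(100)),
    tibble::tibble(channel = "n2", phase = phase, value = rnorm(100)))
  rn <- pairwise_correlation(noise)$r["n1", "n2"]
  expect_lt(abs(rn), 0.3)

  # constant profiles are retained but forced non-significant
  const <- dplyr::bind_rows(
    tibble::tibble(channel = "flat", phase = phase, value = 1),
    tibble::tibble(channel = "n1", phase = phase, value = rnorm(100)),
    tibble::tibble(channel = "n2", phase = phase, value = rnorm(100)))
  expect_warning(cc <- pairwise_correlation(const), "Constant")
  expect_equal(cc$p["flat", "n1"], 1)
  expect_equal(cc$r["flat", "n1"], 0)
})

test_that("the two-stage BKY procedure matches its reference cases", {
  # frozen reference (two-stage adaptive step-up at q = 0.05):
  # the four smallest of these six are rejected
  p <- c(0.001, 0.008, 0.039, 0.041, 0.09, 0.7)
  mask <- bky_fdr(p, q = 0.05)
  expect_equal(as.logical(mask), c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(mask, "alpha"), 0.041)

  expect_true(all(bky_fdr(rep(1e-6, 8), 0.05)))
  expect_false(any(bky_fdr(rep(0.9, 8), 0.05)))
  expect_error(bky_fdr(numeric(0)), "Empty")
  expect_error(bky_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the HVE transform maps correlations onto [0, 2] as specified", {
  expect_equal(hve(1, TRUE), 0)
  expect_equal(hve(-1, TRUE), 2)
  expect_equal(hve(0.9, FALSE), 1)
  expect_equal(hve(0.8, TRUE), 0.36)
  expect_equal(hve(0, TRUE), 1)          # r = 0 edge case

  # antisymmetry about 1 and monotonicity for significant correlations
  r <- seq(0.05, 0.95, by = 0.1)
  expect_equal(hve(-r, TRUE), 2 - hve(r, TRUE))
  expect_true(all(diff(hve(r, TRUE)) < 0))
  expect_true(all(hve(seq(-1, 1, by = 0.05), TRUE) >= 0))
  expect_true(all(hve(seq(-1, 1, by = 0.05), TRUE) <= 2))

  expect_error(hve(1.2, TRUE), "-1, 1")
})

test_that("UPGMA reproduces the hand-computed three-point tree", {
  d <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.8,
                0.6, 0.8, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  expect_equal(sort(tree$height), c(0.2, 0.7))   # (0.6 + 0.8) / 2

  # two channels: a single merge at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(upgma(d2)$height, 0.4)

  # cophenetic distances of the hand tree: AB 0.2, AC 0.7, BC 0.7
  coph <- as.matrix(stats::cophenetic(tree))
  expect_equal(coph["A", "B"], 0.2)
  expect_equal(coph["A", "C"], 0.7)
  expect_equal(coph["B", "C"], 0.7)
  # cophenetic correlation vs the original distances, by hand
  expect_equal(cophenetic_coefficient(tree, d),
               cor(c(0.2, 0.6, 0.8), c(0.2, 0.7, 0.7)))

  # cutting the hand tree at k = 2 separates C
  asg <- cut_tree(tree, 2)
  expect_equal(asg[["A"]], asg[["B"]])
  expect_false(asg[["A"]] == asg[["C"]])

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("UPGMA is exact on ultrametric input and order-invariant", {
  # an ultrametric matrix: cophenetic distances reproduce it exactly
  u <- matrix(1, 4, 4)
  u[1, 2] <- u[2, 1] <- 0.3
  u[3, 4] <- u[4, 3] <- 0.5
  diag(u) <- 0
  dimnames(u) <- list(letters[1:4], letters[1:4])
  tree <- upgma(u)
  expect_equal(as.matrix(stats::cophenetic(tree))[letters[1:4], letters[1:4]],
               u, ignore_attr = TRUE)
  expect_equal(cophenetic_coefficient(tree, u), 1)

  # input order does not change the tree's cophenetic structure
  set.seed(12)
  m <- matrix(runif(36, 0.1, 1.9), 6)
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(paste0("c", 1:6), paste0("c", 1:6))
  t1 <- upgma(m)
  perm <- c(4, 1, 6, 2, 5, 3)
  t2 <- upgma(m[perm, perm])
  c1 <- as.matrix(stats::cophenetic(t1))[paste0("c", 1:6), paste0("c", 1:6)]
  c2 <- as.matrix(stats::cophenetic(t2))[paste0("c", 1:6), paste0("c", 1:6)]
  expect_equal(c1, c2)
})

test_that("tree cuts produce k clusters and nested refinements", {
  tree <- labelled_tree(8)
  expect_equal(length(unique(cut_tree(tree, 1))), 1)
  expect_equal(length(unique(cut_tree(tree, 8))), 8)
  for (k in 2:7) {
    expect_equal(length(unique(cut_tree(tree, k))), k)
  }
  # refinement: increasing k never splits channels back together
  for (k in 2:7) {
    a <- cut_tree(tree, k)
    b <- cut_tree(tree, k + 1)
    # same cluster in b implies same cluster in a
    same_b <- outer(b, b, "==")
    same_a <- outer(a, a, "==")
    expect_true(all(same_a[same_b]))
  }
  expect_error(cut_tree(tree, 0), "between")
  expect_error(cut_tree(tree, 9), "between")
})

test_that("the distance pipeline gates by FDR and reports fit quality", {
  phase <- seq(0, 1, length.out = 100)
  set.seed(8)
  prof <- dplyr::bind_rows(
    tibble::tibble(channel = "a1", phase = phase,
                   value = sin(pi * phase) + rnorm(100, sd = 0.05)),
    tibble::tibble(channel = "a2", phase = phase,
                   value = sin(pi * phase) + rnorm(100, sd = 0.05)),
    tibble::tibble(channel = "b1", phase = phase,
                   value = cos(2 * pi * phase) + rnorm(100, sd = 0.05)),
    tibble::tibble(channel = "b2", phase = phase,
                   value = cos(2 * pi * phase) + rnorm(100, sd = 0.05)))
  cl <- cluster_profiles(prof)
  expect_s3_class(cl, "profile_clustering")
  expect_equal(sort(unname(cut_tree(cl$tree, 2)[c("a1", "a2", "b1", "b2")])),
               c(1, 1, 2, 2))
  expect_gt(cl$cophenetic, 0.9)
  expect_true(cl$alpha > 0 && cl$alpha <= 1)
  d <- cl$hve
  expect_true(all(d >= 0 & d <= 2))
  expect_equal(unname(diag(d)), rep(0, 4))

  td <- tidy(cl)
  expect_equal(nrow(td), 6)    # 4 choose 2 pairs
  gl <- glance(cl)
  expect_equal(gl$n_channels, 4)

  nwk <- export_newick(cl)
  expect_match(nwk, "^\\(.*\\);$")
})
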