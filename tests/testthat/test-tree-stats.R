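test_that("Fowlkes-Mallows reproduces hand-computed cases", {
  # identical assignments
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c(1, 1, 2, 2))$B, 1)

  # crossed 4-object case: all match counts 1, T = 0, B = 0
  crossed <- fowlkes_mallows(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(crossed$T, 0)
  expect_equal(crossed$B, 0)
  expect_equal(as.numeric(crossed$m), rep(1, 4))

  # mixed case: T = 2, P = 6, Q = 4, B = 2 / sqrt(24)
  mixed <- fowlkes_mallows(c(1, 1, 1, 2), c(1, 1, 2, 2))
  expect_equal(mixed$T, 2)
  expect_equal(mixed$P, 6)
  expect_equal(mixed$Q, 4)
  expect_equal(mixed$B, 2 / sqrt(24))

  # named assignments align by label
  a <- c(x = 1, y = 1, z = 2, w = 2)
  b <- c(w = 9, z = 9, y = 7, x = 7)   # same partition, scrambled order
  expect_equal(fowlkes_mallows(a, b)$B, 1)

  expect_error(fowlkes_mallows(1:4, 1:5), "different object sets")
  expect_error(fowlkes_mallows(c(1, 2, 3), c(1, 1, 1)), "undefined")
})

test_that("Fowlkes-Mallows is label-invariant, symmetric, and bounded", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    B <- fowlkes_mallows(a, b)$B
    expect_gte(B, 0)
    expect_lte(B, 1)
    expect_equal(fowlkes_mallows(b, a)$B, B)                 # symmetry
    relab <- c(7, 3, 9, 1)[b]                                # relabeling
    expect_equal(fowlkes_mallows(a, relab)$B, B)
  }
})

test_that("FM curves span k = 2 .. n/2 and detect self-identity", {
  tree <- labelled_tree(24)      # e.g. 12 EMG + 12 Ia signals
  cv <- fm_curve(tree, tree)
  expect_equal(cv$k, 2:12)       # floor(24 / 2)
  expect_true(all(cv$B == 1))

  # label noise degrades similarity on average
  set.seed(66)
  base <- cut_tree(tree, 4)
  degrade <- vapply(c(0, 4, 10, 20), function(nflip) {
    mean(vapply(1:40, function(i) {
      noisy <- base
      idx <- sample(seq_along(base), nflip)
      noisy[idx] <- sample(1:4, nflip, replace = TRUE)
      if (length(unique(noisy)) < 2) return(NA_real_)
      fowlkes_mallows(base, noisy)$B
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(degrade) < 0))
})

test_that("permutation nulls are seeded, low, and shrink with n", {
  t1 <- labelled_tree(24)
  null_a <- permutation_null(t1, t1, n_perm = 100, seed = 9)
  null_b <- permutation_null(t1, t1, n_perm = 100, seed = 9)
  expect_identical(null_a, null_b)

  # an observed B of 1 sits far above the null for mixed labels
  p <- percentile_pvalue(1, null_a$B[null_a$k == 4])
  expect_lt(p, 0.01)

  # chance agreement decreases with the number of clustered objects
  # (k explored up to n/2, as in the analysis)
  means <- vapply(c(8, 16, 24), function(n) {
    mk <- function(s) {
      set.seed(s)
      m <- matrix(runif(n * n, 0.2, 1.8), n)
      m <- (m + t(m)) / 2; diag(m) <- 0
      dimnames(m) <- list(paste0("c", 1:n), paste0("c", 1:n))
      upgma(m)
    }
    nl <- permutation_null(mk(n), mk(n + 100), n_perm = 200,
                           k_max = floor(n / 2), seed = 13)
    mean(nl$B)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("percentile p-values follow the add-one convention", {
  null <- seq(0, 0.999, length.out = 999)
  expect_equal(percentile_pvalue(2, null), 1 / 1000)       # above all
  expect_equal(percentile_pvalue(-1, null), 1)             # below all
  p_med <- percentile_pvalue(stats::median(null), null)
  expect_equal(p_med, 0.5, tolerance = 0.01)
  expect_error(percentile_pvalue(1, numeric(0)), "Empty")
})

test_that("bootstrap difference tests locate zero correctly", {
  # identical constant collections: difference identically zero, p = 1
  bt0 <- bootstrap_difference(rep(0.5, 20), rep(0.5, 20), n_boot = 200,
                              seed = 3)
  expect_equal(bt0$p, 1)
  expect_equal(unique(bt0$diff), 0)

  # disjoint supports: zero never inside the difference distribution
  bt1 <- bootstrap_difference(runif(30, 0.8, 0.9), runif(30, 0.1, 0.2),
                              n_boot = 500, seed = 4)
  expect_lte(bt1$p, 2 / 501)   # zero never inside: add-one floor
  expect_gt(bt1$mean_diff, 0.5)

  # clearly shifted distributions produce a small p
  set.seed(5)
  bt2 <- bootstrap_difference(rnorm(40, 0.6, 0.05), rnorm(40, 0.5, 0.05),
                              n_boot = 500, seed = 6)
  expect_lt(bt2$p, 0.05)

  td <- tidy(bt2)
  expect_true(td$q025 < td$q975)
  expect_error(bootstrap_difference(numeric(0), 1), "non-empty")
})

test_that("Fisher's combined probability matches the chi-square form", {
  all_one <- fisher_combined(c(1, 1, 1))
  expect_equal(all_one$statistic, 0)
  expect_equal(all_one$p_combined, 1)

  single <- fisher_combined(0.05)
  expect_equal(single$p_combined, 0.05)    # df = 2 identity

  two <- fisher_combined(c(0.05, 0.05))
  expect_equal(two$statistic, 11.98292909, tolerance = 1e-8)
  expect_equal(two$p_combined, 0.01747866, tolerance = 1e-6)

  expect_warning(z <- fisher_combined(c(0, 0.5)), "clipped")
  expect_true(z$p_combined > 0)
})

test_that("Bonferroni alpha and pooled SD follow their formulas", {
  expect_equal(bonferroni_alpha(0.05, 9), 0.0056)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")

  expect_equal(pooled_sd(rep(2.5, 6)), 2.5)
  expect_equal(pooled_sd(c(3, 4)), sqrt(12.5))
  expect_equal(pooled_sd(7), 7)
})

test_that("cluster-averaged R2 t-tests handle paired and degenerate data", {
  dat <- tibble::tibble(
    participant = rep(sprintf("P%d", 1:9), 2),
    condition = rep(c("emg", "ia"), each = 9),
    r2 = c(rep(0.5, 9), rep(0.5, 9)))
  same <- cluster_r2_ttest(dat)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # constant nonzero shift with zero variance: degenerate limit flagged
  dat2 <- dat
  dat2$r2[dat2$condition == "ia"] <- 0.3
  deg <- cluster_r2_ttest(dat2)
  expect_equal(deg$p_value, 0)
  expect_match(deg$method, "degenerate")

  # a real shift across 9 participants is detected
  set.seed(31)
  dat3 <- dat
  dat3$r2 <- c(rnorm(9, 0.6, 0.05), rnorm(9, 0.35, 0.05))
  shift <- cluster_r2_ttest(dat3)
  expect_lt(shift$p_value, 0.01)
  expect_match(shift$method, "paired")

  expect_error(cluster_r2_ttest(dat[dat$condition == "emg", ]), "two levels")
})
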