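test_that("Mann-Whitney matches the tie-corrected normal approximation", {
  set.seed(41)
  for (i in 1:20) {
    x <- sample(0:15, sample(8:40, 1), replace = TRUE)
    y <- sample(3:20, sample(8:40, 1), replace = TRUE)
    mw <- mann_whitney(x, y)
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(mw$p_value, wt$p.value, tolerance = 1e-12)
    expect_true(mw$p_value >= 0 && mw$p_value <= 1)
    # swapping groups negates Z and preserves p
    mw2 <- mann_whitney(y, x)
    expect_equal(mw2$statistic, -mw$statistic, tolerance = 1e-12)
    expect_equal(mw2$p_value, mw$p_value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney symmetry, small-sample exactness and tie variance", {
  same <- c(3, 5, 5, 9)
  mw <- mann_whitney(same, same)
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 1)

  # fully separated tiny groups: U = 0 for the lower group; with only two
  # observations per group the discrete null has six atoms, so the normal
  # approximation is loose and only a coarse agreement can be asked of it
  mw <- mann_whitney(c(1, 2), c(3, 4), correct = TRUE)
  expect_equal(mw$U, 0)
  expect_lte(abs(mw$p_value - oracle_mw_exact_p(c(1, 2), c(3, 4))), 0.1)

  # the continuity-corrected p stays within 0.05 of exact enumeration for
  # n <= 7 per group (the uncorrected large-sample p can undershoot the
  # discrete tail by more in the smallest groups)
  set.seed(42)
  for (i in 1:25) {
    x <- sample(seq(0, 40, by = 0.25), sample(3:7, 1))
    y <- sample(seq(50, 90, by = 0.25) / 2.3, sample(3:7, 1))
    expect_lte(abs(mann_whitney(x, y, correct = TRUE)$p_value -
                     oracle_mw_exact_p(x, y)), 0.05)
  }

  # ties strictly shrink the variance relative to the tie-free formula
  x <- c(1, 1, 2); y <- c(1, 2, 2)
  n1 <- 3; n2 <- 3
  tie_free <- n1 * n2 * (n1 + n2 + 1) / 12
  expect_lt(oracle_mw_variance(x, y), tie_free)
  expect_equal(mann_whitney(x, y)$statistic,
               (mann_whitney(x, y)$U - n1 * n2 / 2) /
                 sqrt(oracle_mw_variance(x, y)))

  # all observations identical: variance 0, undefined marker (no error)
  mw <- mann_whitney(rep(4, 5), rep(4, 3))
  expect_true(mw$undefined)
  expect_true(is.na(mw$statistic))
})

test_that("Kruskal-Wallis matches base R and the two-group identity", {
  set.seed(43)
  for (i in 1:15) {
    g <- lapply(1:3, function(j) sample(0:20, sample(8:30, 1), replace = TRUE))
    kw <- kruskal_wallis(g)
    kt <- stats::kruskal.test(g)
    expect_equal(kw$statistic, unname(kt$statistic), tolerance = 1e-12)
    expect_equal(kw$p_value, kt$p.value, tolerance = 1e-12)
  }

  expect_equal(kruskal_wallis(list(1:4, 1:4, 1:4))$statistic, 0,
               tolerance = 1e-12)

  # two tie-free groups: H equals Z^2
  set.seed(44)
  for (i in 1:10) {
    x <- sample(seq(1, 400, by = 1), 12)
    y <- sample(seq(1, 400, by = 1) + 0.5, 9)
    expect_equal(kruskal_wallis(list(x, y))$statistic,
                 mann_whitney(x, y)$statistic^2, tolerance = 1e-9)
  }

  expect_true(kruskal_wallis(list(rep(1, 4), rep(1, 6)))$undefined)
})

test_that("2x2 chi-square follows the closed margin formula", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r <- chi_square_2x2(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  tab <- matrix(c(20, 10, 10, 20), 2)
  closed <- sum(tab) * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(c(rowSums(tab), colSums(tab)))
  r <- chi_square_2x2(tab)
  expect_equal(r$statistic, closed)
  expect_equal(r$statistic,
               unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  # fixed proportions: doubling all counts doubles the statistic
  expect_equal(chi_square_2x2(2 * tab)$statistic, 2 * r$statistic)
  # continuity-corrected variant matches base R
  expect_equal(chi_square_2x2(tab, correct = TRUE)$statistic,
               unname(stats::chisq.test(tab, correct = TRUE)$statistic))
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("pairwise ICC matches the ANOVA oracle and its boundary cases", {
  expect_equal(icc_pairwise(cbind(1:6, 1:6))$icc, 1)

  m5 <- cbind(c(10, 14, 22, 30, 35), c(12, 13, 24, 29, 37))
  expect_equal(icc_pairwise(m5)$icc, oracle_icc_a1(m5), tolerance = 1e-12)

  set.seed(45)
  for (i in 1:10) {
    m <- cbind(sample(0:38, 12, TRUE), sample(0:38, 12, TRUE))
    if (stats::var(rowMeans(m)) == 0) next
    expect_equal(icc_pairwise(m)$icc, oracle_icc_a1(m), tolerance = 1e-10)
    # invariant under reordering the videos
    perm <- sample(nrow(m))
    expect_equal(icc_pairwise(m[perm, ])$icc, icc_pairwise(m)$icc,
                 tolerance = 1e-12)
  }

  # noise twice the signal variance drags the ICC well below 0.5
  set.seed(46)
  truth <- rnorm(200, 20, 3)
  noisy <- cbind(truth, truth + rnorm(200, 0, sqrt(2) * 3))
  expect_lt(icc_pairwise(noisy)$icc, 0.5)

  expect_true(icc_pairwise(cbind(rep(5, 4), rep(5, 4)))$undefined)
})

test_that("within-delta agreement and kappa behave as defined", {
  expect_equal(within_delta_agreement(cbind(10, 12)), 1)
  expect_equal(within_delta_agreement(cbind(10, 13)), 0)
  r <- simulated_ratings(400, noise_sd = 2)
  expect_equal(within_delta_agreement(r),
               mean(abs(r[, 1] - r[, 2]) <= 2))

  expect_equal(cohen_kappa(c("a", "b", "a", "c"), c("a", "b", "a", "c")), 1)
  expect_true(is.na(cohen_kappa(rep("a", 5), rep("a", 5))))
  # independent labels: kappa converges to 0
  set.seed(47)
  a <- sample(gm_categories(), 10000, TRUE)
  b <- sample(gm_categories(), 10000, TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
  # kappa is symmetric in the raters
  a2 <- sample(gm_categories(), 300, TRUE)
  b2 <- sample(gm_categories(), 300, TRUE)
  expect_equal(cohen_kappa(a2, b2), cohen_kappa(b2, a2), tolerance = 1e-12)

  # chance-corrected within-delta dichotomy: perfect duplicates give 1
  dup <- cbind(c(5, 15, 25, 35), c(5, 15, 25, 35))
  expect_equal(kappa_within_delta(dup), 1)
})

test_that("the significance policy applies the right family threshold", {
  expect_true(flag_significance(0.03, 1))
  expect_false(flag_significance(0.03, 3))
  expect_true(flag_significance(0.016, 3))
  expect_false(flag_significance(0.017, 3))  # strict inequality
  expect_false(flag_significance(0.05, 1))
  expect_warning(sig <- flag_significance(0.01, 2), "Bonferroni")
  expect_true(sig)
  expect_error(flag_significance(1.2, 1))
})
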