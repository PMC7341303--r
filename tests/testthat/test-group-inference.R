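test_that("Mann-Whitney U handles complete ties and complete separation", {
  tied <- mann_whitney_u(rep(2, 4), rep(2, 5))
  expect_equal(tied$statistic, 4 * 5 / 2)
  expect_equal(tied$p_value, 1)

  sep <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$u1 + sep$u2, 4)

  expect_error(mann_whitney_u(numeric(0), 1:3), class = "focalnet_validation_error")
})

test_that("exact Mann-Whitney p matches enumeration and wilcox.test", {
  set.seed(14)
  for (rep in 1:8) {
    x <- round(stats::rnorm(6), 1)
    y <- round(stats::rnorm(6, mean = 0.5), 1)
    res <- mann_whitney_u(x, y)
    orc <- oracle_mw(x, y)
    expect_equal(res$statistic, orc$u)
    expect_equal(res$u1, orc$u1)
    expect_equal(res$p_value, orc$p)
    if (!any(duplicated(c(x, y)))) {
      wt <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(res$p_value, wt$p.value)
    }
  }
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal tail", {
  set.seed(3)
  x <- stats::rnorm(20)
  y <- stats::rnorm(20, 1)
  res <- mann_whitney_u(x, y)
  expect_equal(res$method, "normal_approximation")
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis H matches the rank formula and gates the post hoc", {
  same <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(nrow(same$pairwise), 0)

  # three singleton groups: ranks 1,2,3 -> H = 2
  singletons <- kruskal_wallis(c(1, 2, 3), c("a", "b", "c"))
  expect_equal(singletons$statistic, 2)
  expect_equal(singletons$df, 2)

  # hand-computed tie-corrected H on a small case
  values <- c(1, 1, 2, 3, 5, 5, 5, 7, 9)
  groups <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  r <- rank(values)
  nn <- length(values)
  h_raw <- 12 / (nn * (nn + 1)) *
    sum(tapply(r, groups, function(g) length(g) * mean(g)^2)) - 3 * (nn + 1)
  ties <- table(r)
  h_corr <- h_raw / (1 - sum(ties^3 - ties) / (nn^3 - nn))
  res <- kruskal_wallis(values, groups)
  expect_equal(res$statistic, h_corr, tolerance = 1e-12)

  expect_error(kruskal_wallis(1:3, rep("a", 3)), class = "focalnet_validation_error")
})

test_that("Holm adjustment is monotone and never below the raw p", {
  set.seed(2)
  values <- c(stats::rnorm(10), stats::rnorm(10, 2), stats::rnorm(10, 4))
  groups <- rep(c("a", "b", "c"), each = 10)
  res <- kruskal_wallis(values, groups)
  expect_gt(nrow(res$pairwise), 0)
  expect_true(all(res$pairwise$p_holm >= res$pairwise$p_value - 1e-15))
  ord <- order(res$pairwise$p_value)
  expect_true(all(diff(res$pairwise$p_holm[ord]) >= -1e-15))
  # Holm rejects a superset of Bonferroni
  bonf <- pmin(1, res$pairwise$p_value * nrow(res$pairwise))
  expect_true(all(res$pairwise$p_holm <= bonf + 1e-15))
})

test_that("Welch t follows the direct formula with the fixed sign convention", {
  expect_equal(welch_t(c(1, 2, 3), c(4, 5, 6)), -3 / sqrt(2 / 3))
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- stats::rnorm(5)
  b <- stats::rnorm(7)
  expect_equal(welch_t(a, b), -welch_t(b, a))
  expect_equal(welch_t(a, b), unname(stats::t.test(a, b)$statistic), tolerance = 1e-12)
  expect_error(welch_t(c(1, 1), c(1, 1)), class = "focalnet_validation_error")
})

test_that("the randomization test is reproducible and matches enumeration", {
  set.seed(8)
  values <- stats::rnorm(16)
  sex <- rep(c("male", "female"), each = 8)
  p1 <- sex_label_permutation_test(values, sex, b = 10000, seed = 99)
  p2 <- sex_label_permutation_test(values, sex, b = 10000, seed = 99)
  expect_equal(p1$p_lower, p2$p_lower)
  expect_equal(p1$p_two_sided, p2$p_two_sided)
  expect_equal(p1$t_observed, welch_t(values[sex == "female"], values[sex == "male"]))

  small_vals <- c(0.1, 0.5, 0.9, 0.2, 0.4, 0.8)
  small_sex <- c("male", "male", "male", "female", "female", "female")
  ex <- sex_label_permutation_test(small_vals, small_sex, exhaustive = TRUE)
  orc <- oracle_perm(small_vals, small_sex)
  expect_equal(ex$b, 20)
  expect_equal(ex$t_observed, orc$t_obs, tolerance = 1e-12)
  expect_equal(ex$p_lower, orc$p_lower)
  expect_equal(ex$p_two_sided, orc$p_two)

  expect_error(
    sex_label_permutation_test(1:4, rep("male", 4)),
    class = "focalnet_validation_error"
  )
})

test_that("sampled permutation p converges to the exhaustive p", {
  set.seed(21)
  values <- stats::rnorm(10)
  sex <- rep(c("male", "female"), each = 5)
  ex <- sex_label_permutation_test(values, sex, exhaustive = TRUE)
  mc <- sex_label_permutation_test(values, sex, b = 40000, seed = 5)
  expect_lt(abs(mc$p_two_sided - ex$p_two_sided), 0.01)
  expect_lt(abs(mc$p_lower - ex$p_lower), 0.01)
})

test_that("rank tests are invariant under monotone transforms, permutation p under affine", {
  set.seed(12)
  x <- stats::rnorm(8)
  y <- stats::rnorm(8, 1)
  f <- function(v) exp(v) # strictly increasing
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(f(x), f(y))$p_value)
  expect_equal(mann_whitney_u(x, y)$statistic, mann_whitney_u(f(x), f(y))$statistic)

  values <- stats::rnorm(12)
  groups <- rep(c("a", "b", "c"), each = 4)
  expect_equal(
    kruskal_wallis(values, groups)$statistic,
    kruskal_wallis(f(values), groups)$statistic
  )

  sex <- rep(c("male", "female"), 6)
  p_raw <- sex_label_permutation_test(values, sex, b = 2000, seed = 7)
  p_aff <- sex_label_permutation_test(3 * values + 10, sex, b = 2000, seed = 7)
  expect_equal(p_raw$p_two_sided, p_aff$p_two_sided)
  expect_equal(p_raw$p_lower, p_aff$p_lower)
})

test_that("bootstrap mode and the plus-one estimator behave as documented", {
  set.seed(4)
  values <- c(stats::rnorm(8), stats::rnorm(8) + 3)
  sex <- rep(c("male", "female"), each = 8)
  boot <- sex_label_permutation_test(values, sex, b = 1000, seed = 1, method = "bootstrap")
  perm <- sex_label_permutation_test(values, sex, b = 1000, seed = 1)
  # bootstrap null is centred near the observed t; the permutation null at zero
  expect_gt(boot$t_observed, 2)
  expect_lt(abs(stats::median(boot$t_resampled) - boot$t_observed), 1.5)
  expect_lt(abs(stats::median(perm$t_resampled)), 1)
  plus <- sex_label_permutation_test(values, sex, b = 500, seed = 2, estimator = "plus_one")
  plain <- sex_label_permutation_test(values, sex, b = 500, seed = 2)
  expect_equal(plus$p_lower, (plain$p_lower * 500 + 1) / 501)
})
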