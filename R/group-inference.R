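#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples,
#' using midranks for ties. The reported statistic is the smaller of the two
#' U statistics (so `U + U' = n1 * n2`). The two-sided p-value is computed
#' by exhaustive enumeration of all group assignments when
#' `n1 + n2 <= exact_limit` (which handles ties exactly), and otherwise by
#' the normal approximation with the tie-corrected variance.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Combined sample size up to which the exact enumeration
#'   is used (default 12).
#' @return An `mw_test` object; see [tidy()] / [glance()].
#' @examples
#' tidy(mann_whitney_u(c(1, 2), c(3, 4)))
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  if (length(x) == 0 || length(y) == 0) {
    validation_error("both samples must be nonempty")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  exact <- n1 + n2 <= exact_limit
  if (exact) {
    assignments <- utils::combn(n1 + n2, n1)
    u_null <- apply(assignments, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_null <= u1 + eps), mean(u_null >= u1 - eps)))
  } else {
    nn <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  structure(
    list(
      statistic = min(u1, u2), u1 = u1, u2 = u2, n1 = n1, n2 = n2,
      p_value = p, method = if (exact) "exact" else "normal_approximation"
    ),
    class = "mw_test"
  )
}

midrank_tie_term <- function(r) {
  ties <- table(r)
  sum(ties^3 - ties)
}

#' Kruskal-Wallis test with Holm-corrected pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H (chi-squared approximation with
#' `k - 1` degrees of freedom) across `k` groups, followed — when the
#' omnibus test is significant at `alpha` — by pairwise Dunn rank
#' comparisons (difference of mean ranks over its standard error, tie
#' corrected) with Holm-adjusted p-values. Pairwise Mann-Whitney tests with
#' Holm adjustment are available as an alternative post hoc.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (coerced to factor) of the same length.
#' @param alpha Significance level gating the post hoc (default 0.05).
#' @param posthoc `"dunn"` (default) or `"mann_whitney"`.
#' @return A `kw_test` object with fields `statistic` (H), `df`, `p_value`
#'   and a `pairwise` tibble (empty when the omnibus is not significant).
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05, posthoc = c("dunn", "mann_whitney")) {
  posthoc <- match.arg(posthoc)
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    validation_error("kruskal_wallis needs at least 2 groups")
  }
  if (any(table(groups) < 1)) {
    validation_error("every group needs at least one value")
  }
  kt <- stats::kruskal.test(values, groups)
  pairwise <- tibble(
    group1 = character(0), group2 = character(0),
    z = double(0), p_value = double(0), p_holm = double(0)
  )
  if (!is.nan(kt$p.value) && kt$p.value < alpha) {
    nn <- length(values)
    r <- rank(values)
    tie_corr <- midrank_tie_term(r) / (12 * (nn - 1))
    mean_rank <- tapply(r, groups, mean)
    sizes <- table(groups)
    combos <- utils::combn(levels(groups), 2)
    z <- map_dbl(seq_len(ncol(combos)), function(i) {
      g1 <- combos[1, i]
      g2 <- combos[2, i]
      se <- sqrt((nn * (nn + 1) / 12 - tie_corr) * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
      (mean_rank[[g1]] - mean_rank[[g2]]) / se
    })
    if (posthoc == "dunn") {
      p_raw <- 2 * stats::pnorm(-abs(z))
    } else {
      p_raw <- map_dbl(seq_len(ncol(combos)), function(i) {
        mann_whitney_u(values[groups == combos[1, i]], values[groups == combos[2, i]])$p_value
      })
    }
    pairwise <- tibble(
      group1 = combos[1, ], group2 = combos[2, ],
      z = z, p_value = p_raw, p_holm = stats::p.adjust(p_raw, method = "holm")
    )
  }
  structure(
    list(
      statistic = unname(kt$statistic), df = unname(kt$parameter),
      p_value = kt$p.value, pairwise = pairwise, alpha = alpha, posthoc = posthoc
    ),
    class = "kw_test"
  )
}

#' Welch's t statistic
#'
#' `t = (mean(a) - mean(b)) / sqrt(var(a)/na + var(b)/nb)` with `n - 1`
#' sample variances. The pipeline calls this with `a` = female scores and
#' `b` = male scores, so a male-dominated quantity yields a negative t.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return The t statistic (scalar).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    validation_error("welch_t needs at least 2 values per sample")
  }
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  diff <- mean(a) - mean(b)
  if (se2 == 0) {
    if (diff == 0) {
      validation_error("welch_t undefined: zero variance in both samples with equal means")
    }
    return(sign(diff) * Inf)
  }
  diff / sqrt(se2)
}

welch_t_quiet <- function(a, b) {
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  d <- mean(a) - mean(b)
  if (se2 == 0) {
    return(if (d == 0) 0 else sign(d) * Inf)
  }
  d / sqrt(se2)
}

#' Sex-label randomization test on per-individual scores
#'
#' Tests for a sex difference in a per-individual quantity (here typically
#' eigenvector centrality) against a null distribution built by permuting
#' the sex labels over the fixed scores. The observed statistic is Welch's t
#' with the female-minus-male convention; each of `b` resamples permutes the
#' labels uniformly without replacement (group sizes preserved) and
#' recomputes t. Reported p-values are the lower-tail fraction
#' `#{t* <= t_obs} / b` (the directional p used when the expected direction
#' is male-dominant) and the two-sided fraction `#{|t*| >= |t_obs|} / b`.
#'
#' With `exhaustive = TRUE` every distinct label assignment is enumerated
#' instead of sampled, giving the exact permutation p. `method =
#' "bootstrap"` resamples scores within each sex with replacement instead of
#' permuting labels (a sensitivity variant; its null is centred at the
#' observed t, not at 0). `estimator = "plus_one"` uses the
#' `(count + 1) / (b + 1)` estimator.
#'
#' Degenerate resamples whose Welch t is 0/0 (zero variance in both groups
#' with equal means, possible only with heavily tied scores) are counted as
#' t* = 0.
#'
#' @param values Numeric vector, one score per individual.
#' @param sex Character vector of `"male"` / `"female"` labels.
#' @param b Number of resamples (default 10000).
#' @param seed Optional seed for reproducibility.
#' @param exhaustive Enumerate all label assignments instead of sampling.
#' @param method `"permutation"` (default) or `"bootstrap"`.
#' @param estimator `"plain"` (default) or `"plus_one"`.
#' @param alpha Significance level carried in the result (default 0.05).
#' @return A `perm_test` object.
#' @export
sex_label_permutation_test <- function(values, sex, b = 10000, seed = NULL,
                                       exhaustive = FALSE,
                                       method = c("permutation", "bootstrap"),
                                       estimator = c("plain", "plus_one"),
                                       alpha = 0.05) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  if (length(values) != length(sex)) {
    validation_error("values and sex must have the same length")
  }
  if (!all(sex %in% SEX_LEVELS) || length(unique(sex)) < 2) {
    validation_error("both sexes must be present among the labels")
  }
  if (b < 1) {
    validation_error("b must be >= 1")
  }
  f <- values[sex == "female"]
  m <- values[sex == "male"]
  t_obs <- welch_t(f, m)
  n_f <- length(f)
  t_star <- with_seed(seed, {
    if (method == "bootstrap") {
      map_dbl(seq_len(b), function(i) {
        welch_t_quiet(sample(f, n_f, replace = TRUE), sample(m, length(m), replace = TRUE))
      })
    } else if (exhaustive) {
      n_assign <- choose(length(values), n_f)
      if (n_assign > 1e6) {
        validation_error("too many label assignments to enumerate exhaustively")
      }
      assignments <- utils::combn(length(values), n_f)
      apply(assignments, 2, function(idx) {
        welch_t_quiet(values[idx], values[-idx])
      })
    } else {
      map_dbl(seq_len(b), function(i) {
        lab <- sample(sex)
        welch_t_quiet(values[lab == "female"], values[lab == "male"])
      })
    }
  })
  b_eff <- length(t_star)
  eps <- 1e-12
  count_lower <- sum(t_star <= t_obs + eps)
  count_two <- sum(abs(t_star) >= abs(t_obs) - eps)
  if (estimator == "plus_one" && !exhaustive) {
    p_lower <- (count_lower + 1) / (b_eff + 1)
    p_two <- (count_two + 1) / (b_eff + 1)
  } else {
    p_lower <- count_lower / b_eff
    p_two <- count_two / b_eff
  }
  structure(
    list(
      t_observed = t_obs, b = b_eff, p_lower = p_lower, p_two_sided = p_two,
      seed = seed, method = method, estimator = estimator,
      exhaustive = exhaustive, alpha = alpha, t_resampled = t_star,
      n_female = n_f, n_male = length(m)
    ),
    class = "perm_test"
  )
}
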