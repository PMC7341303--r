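#' Tidy a proximity-index matrix into dyads
#'
#' @param x A `pi_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per unordered dyad: `id_a`, `id_b`, `pi`.
#' @method tidy pi_matrix
#' @export
tidy.pi_matrix <- function(x, ...) {
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    id_a = rownames(x)[idx[, "row"]],
    id_b = colnames(x)[idx[, "col"]],
    pi = x[idx]
  )
}

#' @method glance pi_matrix
#' @export
glance.pi_matrix <- function(x, ...) {
  v <- pair_values(x)
  tibble(
    n_individuals = nrow(x), n_dyads = length(v),
    mean_pi = mean(v), max_pi = max(v),
    n_zero_dyads = sum(v == 0),
    protocol = attr(x, "protocol") %||% NA_character_
  )
}

#' @method tidy proximity_tally
#' @export
tidy.proximity_tally <- function(x, ...) {
  dplyr::left_join(
    x$t_near,
    dplyr::rename(x$t_focal, t_focal_min = "t_min"),
    by = "focal_id"
  )
}

#' @method tidy filtered_network
#' @export
tidy.filtered_network <- function(x, ...) {
  x$edges
}

#' @method glance filtered_network
#' @export
glance.filtered_network <- function(x, ...) {
  n_pairs <- length(x$nodes) * (length(x$nodes) - 1) / 2
  tibble(
    threshold = x$threshold, quartile = x$quartile,
    n_nodes = length(x$nodes), n_edges = nrow(x$edges),
    prop_retained = nrow(x$edges) / n_pairs,
    n_isolates = sum(!x$nodes %in% c(x$edges$from, x$edges$to))
  )
}

#' @method tidy centrality_result
#' @export
tidy.centrality_result <- function(x, ...) {
  as_tibble(x)
}

#' @method glance centrality_result
#' @export
glance.centrality_result <- function(x, ...) {
  tibble(
    eigenvalue = attr(x, "eigenvalue"),
    method = attr(x, "method"),
    iterations = attr(x, "iterations"),
    weighted = attr(x, "weighted"),
    norm = sqrt(sum(x$centrality^2))
  )
}

#' @method tidy mw_test
#' @export
tidy.mw_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, u1 = x$u1, u2 = x$u2,
    n1 = x$n1, n2 = x$n2, p.value = x$p_value, method = x$method
  )
}

#' @method glance mw_test
#' @export
glance.mw_test <- function(x, ...) tidy(x)

#' @method tidy kw_test
#' @export
tidy.kw_test <- function(x, ...) {
  x$pairwise
}

#' @method glance kw_test
#' @export
glance.kw_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p.value = x$p_value,
    n_pairwise = nrow(x$pairwise), posthoc = x$posthoc
  )
}

#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(t_resampled = x$t_resampled)
}

#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(
    t_observed = x$t_observed, b = x$b,
    p_lower = x$p_lower, p_two_sided = x$p_two_sided,
    method = x$method, estimator = x$estimator, exhaustive = x$exhaustive,
    n_female = x$n_female, n_male = x$n_male
  )
}

#' @method print mw_test
#' @export
print.mw_test <- function(x, ...) {
  cat(
    "Mann-Whitney U test (", x$method, ")\n",
    "U = ", format(x$statistic), ", n1 = ", x$n1, ", n2 = ", x$n2,
    ", p = ", format.pval(x$p_value, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method print kw_test
#' @export
print.kw_test <- function(x, ...) {
  cat(
    "Kruskal-Wallis test\n",
    "chi-squared = ", format(x$statistic, digits = 6), ", df = ", x$df,
    ", p = ", format.pval(x$p_value, digits = 4), "\n",
    sep = ""
  )
  if (nrow(x$pairwise) > 0) {
    cat("Pairwise comparisons (", x$posthoc, ", Holm-adjusted):\n", sep = "")
    print(as.data.frame(x$pairwise), row.names = FALSE)
  }
  invisible(x)
}

#' @method print perm_test
#' @export
print.perm_test <- function(x, ...) {
  cat(
    "Sex-label randomization test (", x$method, ")\n",
    "observed t (female - male) = ", format(x$t_observed, digits = 6),
    ", B = ", x$b, "\n",
    "p_lower = ", format(x$p_lower, digits = 4),
    ", p_two_sided = ", format(x$p_two_sided, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method print proximity_tally
#' @export
print.proximity_tally <- function(x, ...) {
  cat(
    "Proximity tally (", x$protocol, "): ", nrow(x$t_focal), " focals, ",
    nrow(x$t_near), " ordered pairs with nonzero proximity time\n",
    sep = ""
  )
  invisible(x)
}

#' @method print filtered_network
#' @export
print.filtered_network <- function(x, ...) {
  cat(
    "Filtered proximity network: ", length(x$nodes), " nodes, ",
    nrow(x$edges), " edges at threshold ", format(x$threshold, digits = 4),
    " (quartile ", x$quartile, ")\n",
    sep = ""
  )
  invisible(x)
}
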