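#' Activity budget of one focal individual
#'
#' The activity budget is the proportion of instantaneous behavior samples
#' falling in each of the five categories (foraging, traveling, resting,
#' social grooming, others) over the individual's total recorded samples.
#' Foraging is additionally split into collecting / extractive / hunting
#' subtypes, each expressed as a proportion of all samples so the three sum
#' to the foraging proportion. Observation time is sample count times the
#' session's sampling interval; only recorded sampling points count (out-of-
#' view points simply do not appear in the stream).
#'
#' @param behavior Behavior-sample tibble.
#' @param sessions Session tibble (supplies per-session intervals).
#' @param focal_id The individual to summarise.
#' @return One-row tibble: `focal_id`, `n_samples`, `observed_min`, one
#'   column per category, one per foraging subtype, and `foraging_total`.
#' @export
compute_budget <- function(behavior, sessions, focal_id) {
  rows <- behavior[behavior$focal_id == focal_id, ]
  if (nrow(rows) == 0) {
    validation_error(paste0("no behavior samples recorded for focal '", focal_id, "'"))
  }
  interval_s <- stats::setNames(sessions$behavior_interval_s, sessions$session_id)
  if (any(!rows$session_id %in% sessions$session_id)) {
    validation_error("behavior samples reference sessions absent from the session table")
  }
  n <- nrow(rows)
  cat_prop <- map_dbl(BEHAVIOR_CATEGORIES, function(k) sum(rows$category == k) / n)
  names(cat_prop) <- BEHAVIOR_CATEGORIES
  sub_prop <- map_dbl(FORAGING_SUBTYPES, function(k) sum(rows$foraging_subtype == k) / n)
  names(sub_prop) <- FORAGING_SUBTYPES
  out <- tibble(
    focal_id = focal_id,
    n_samples = n,
    observed_min = sum(interval_s[rows$session_id]) / 60,
    abnormal_observed = any(rows$abnormal_flag)
  )
  out <- dplyr::bind_cols(out, as_tibble(as.list(cat_prop)), as_tibble(as.list(sub_prop)))
  out$foraging_total <- sum(sub_prop)
  out
}

#' Activity budgets for a whole group
#'
#' Computes [compute_budget()] for every roster member of a group, in roster
#' order. Individuals without any behavior sample are kept in the output
#' with `sampled = FALSE` and `NA` proportions rather than silently dropped.
#'
#' @param dataset Named list with at least `roster`, `sessions`, `behavior`
#'   (as produced by [simulate_colony()] or assembled from the readers).
#' @param group_id Optional group label to restrict to.
#' @return Tibble with one row per focal, budget columns as in
#'   [compute_budget()], plus a `sampled` flag.
#' @export
group_budgets <- function(dataset, group_id = NULL) {
  roster <- dataset$roster
  if (!is.null(group_id)) {
    roster <- roster[roster$group_id == group_id, ]
  }
  rows <- map(roster$id, function(id) {
    if (!any(dataset$behavior$focal_id == id)) {
      return(tibble(focal_id = id, sampled = FALSE))
    }
    dplyr::bind_cols(
      compute_budget(dataset$behavior, dataset$sessions, id),
      tibble(sampled = TRUE)
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::relocate("sampled", .after = "focal_id")
}

#' Write activity budgets in long form
#'
#' One row per focal and category (including foraging subtypes), with the
#' proportion and the focal's observed minutes.
#'
#' @param budgets Tibble from [group_budgets()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_budgets <- function(budgets, path) {
  long <- budgets |>
    dplyr::filter(.data$sampled) |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(c(BEHAVIOR_CATEGORIES, FORAGING_SUBTYPES, "foraging_total")),
      names_to = "category", values_to = "proportion"
    ) |>
    dplyr::select("focal_id", "category", "proportion", "observed_min")
  readr::write_csv(long, path)
  invisible(path)
}
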