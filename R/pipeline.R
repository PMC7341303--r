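#' Configure an end-to-end analysis run
#'
#' Bundles the inputs and thresholds of a full pipeline run: either a
#' [colony_config()] to simulate from, or a directory of the five CSVs
#' (roster.csv, sessions.csv, behavior.csv, proximity.csv, grooming.csv) to
#' load. Defaults follow the analysis conventions: grooming exclusion below
#' 300 s, third-quartile network filter, `alpha = 0.05`, `B = 10000`
#' resamples.
#'
#' @param colony Optional `colony_config` to simulate the dataset from.
#' @param input_dir Optional directory holding the five CSVs (exactly one of
#'   `colony` / `input_dir` must be given).
#' @param min_total_s Grooming exclusion threshold in seconds.
#' @param excluded_age_categories Age categories excluded from grooming
#'   ratios.
#' @param quartile Network filter quantile (default 0.75).
#' @param alpha Significance level in (0, 1).
#' @param b Resample count for the randomization test.
#' @param seed Master seed; per-stage substreams are derived from it.
#' @param out_dir Output directory for the report bundle (`NULL` to skip
#'   writing files).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(colony = NULL, input_dir = NULL,
                            min_total_s = 300,
                            excluded_age_categories = "juvenile",
                            quartile = 0.75, alpha = 0.05, b = 10000,
                            seed = 1L, out_dir = NULL) {
  if (is.null(colony) == is.null(input_dir)) {
    config_error("exactly one of colony / input_dir must be supplied")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    config_error(paste0("input_dir does not exist: ", input_dir))
  }
  if (alpha <= 0 || alpha >= 1) {
    config_error("alpha must lie strictly between 0 and 1")
  }
  if (b < 1) {
    config_error("b must be >= 1")
  }
  if (quartile <= 0 || quartile >= 1) {
    config_error("quartile must lie strictly between 0 and 1")
  }
  structure(
    list(
      colony = colony, input_dir = input_dir, min_total_s = min_total_s,
      excluded_age_categories = excluded_age_categories, quartile = quartile,
      alpha = alpha, b = b, seed = as.integer(seed), out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

load_dataset <- function(input_dir) {
  roster <- read_roster(file.path(input_dir, "roster.csv"))
  sessions <- read_sessions(file.path(input_dir, "sessions.csv"), roster)
  list(
    roster = roster,
    sessions = sessions,
    behavior = read_samples(file.path(input_dir, "behavior.csv"), roster, sessions),
    proximity = read_samples(file.path(input_dir, "proximity.csv"), roster, sessions),
    grooming = read_samples(file.path(input_dir, "grooming.csv"), roster, sessions)
  )
}

write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_roster(dataset$roster, file.path(dir, "roster.csv"))
  write_sessions(dataset$sessions, file.path(dir, "sessions.csv"))
  write_samples(dataset$behavior, file.path(dir, "behavior.csv"))
  write_samples(dataset$proximity, file.path(dir, "proximity.csv"))
  write_samples(dataset$grooming, file.path(dir, "grooming.csv"))
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Simulates or loads a focal-sampling dataset, validates it, and runs every
#' analysis stage: per-individual activity budgets, grooming summaries with
#' mutual-grooming ratios, the proximity-index matrix, the third-quartile
#' filtered network with eigenvector centralities, the Kruskal-Wallis
#' comparison of dyadic indices across sex combinations (with Holm-corrected
#' Dunn comparisons when significant), and the sex-label randomization test
#' on centralities. Results are returned as a bundle and, when `out_dir` is
#' set, written as budgets.csv, grooming_summary.csv, pi_matrix.csv,
#' network_edges.csv, network.graphml, centrality.csv, stats_report.json and
#' run_log.txt. Runs are deterministic given the seed.
#'
#' Dyadic indices from different proximity protocols are never pooled: one
#' run analyses one group under one protocol.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a named list with every stage result.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config_error("config must be created by pipeline_config()")
  }
  dataset <- if (!is.null(config$colony)) {
    simulate_colony(config$colony)
  } else {
    load_dataset(config$input_dir)
  }

  report <- validate_dataset(
    dataset$roster, dataset$sessions, dataset$behavior,
    dataset$proximity, dataset$grooming
  )
  if (nrow(report) > 0) {
    validation_error(paste0(
      "dataset validation failed at stage 'validate': ",
      nrow(report), " violation(s); first: ",
      paste(report$stream[1], report$rule[1], report$detail[1], collapse = " ")
    ))
  }

  budgets <- group_budgets(dataset)
  grooming_summary <- summarize_grooming(
    dataset$grooming, dataset$roster,
    min_total_s = config$min_total_s,
    excluded_age_categories = config$excluded_age_categories
  )
  tally <- tally_proximity(dataset$proximity, dataset$sessions)
  pi_matrix <- build_pi_matrix(tally, dataset$roster)
  network <- q3_filter(pi_matrix, quartile = config$quartile)
  centrality <- eigenvector_centrality(network)

  pis <- sex_combination_pis(pi_matrix, dataset$roster)
  kw <- kruskal_wallis(pis$pi, pis$sex_combination, alpha = config$alpha)
  sex_of <- stats::setNames(dataset$roster$sex, dataset$roster$id)
  perm <- sex_label_permutation_test(
    centrality$centrality, unname(sex_of[centrality$id]),
    b = config$b, seed = stage_seed(config$seed, "stats"), alpha = config$alpha
  )

  stats_report <- list(
    parameters = list(
      seed = config$seed, alpha = config$alpha, b = config$b,
      quartile = config$quartile, min_total_s = config$min_total_s,
      excluded_age_categories = config$excluded_age_categories,
      protocol = tally$protocol,
      source = if (is.null(config$input_dir)) "simulated" else config$input_dir
    ),
    pi_by_sex_combination = pis |>
      dplyr::group_by(.data$sex_combination) |>
      dplyr::summarise(
        n = dplyr::n(), mean = mean(.data$pi), sd = stats::sd(.data$pi),
        .groups = "drop"
      ),
    kruskal_wallis = c(as.list(glance(kw)), list(pairwise = kw$pairwise)),
    centrality_by_sex = as_tibble(centrality) |>
      dplyr::mutate(sex = unname(sex_of[.data$id])) |>
      dplyr::group_by(.data$sex) |>
      dplyr::summarise(
        n = dplyr::n(), mean = mean(.data$centrality), sd = stats::sd(.data$centrality),
        .groups = "drop"
      ),
    randomization_test = as.list(glance(perm)),
    grooming = list(
      n_excluded = sum(grooming_summary$excluded),
      mean_mutual_ratio = mean(
        grooming_summary$mutual_ratio[!grooming_summary$excluded]
      ),
      any_ghc = any(grooming_summary$ghc_observed)
    )
  )

  bundle <- list(
    dataset = dataset, budgets = budgets, grooming_summary = grooming_summary,
    tally = tally, pi_matrix = pi_matrix, network = network,
    centrality = centrality, sex_combination_pis = pis,
    kruskal_wallis = kw, randomization_test = perm,
    stats_report = stats_report
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_budgets(budgets, out("budgets.csv"))
    write_grooming_summary(grooming_summary, out("grooming_summary.csv"))
    write_pi_matrix(pi_matrix, out("pi_matrix.csv"))
    write_network(network, out("network_edges.csv"), out("network.graphml"))
    readr::write_csv(as_tibble(centrality), out("centrality.csv"))
    jsonlite::write_json(
      stats_report, out("stats_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
    )
    writeLines(
      c(
        paste0("focalnet ", as.character(utils::packageVersion("focalnet"))),
        paste0("seed=", config$seed),
        paste0("alpha=", config$alpha),
        paste0("b=", config$b),
        paste0("quartile=", config$quartile),
        paste0("min_total_s=", config$min_total_s),
        paste0(
          "excluded_age_categories=",
          paste(config$excluded_age_categories, collapse = ",")
        ),
        paste0("protocol=", tally$protocol),
        paste0("centrality_method=", attr(centrality, "method")),
        paste0("centrality_weighted=", attr(centrality, "weighted")),
        paste0("perm_method=", perm$method),
        paste0("perm_estimator=", perm$estimator)
      ),
      out("run_log.txt")
    )
  }
  invisible(bundle)
}
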