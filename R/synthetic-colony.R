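#' Configure a synthetic colony
#'
#' Builds the configuration object for [simulate_colony()]. The generator
#' emulates a focal-sampling study: each focal is followed for `n_sessions`
#' sessions of `session_length_min` minutes; its behavioral state is sampled
#' instantaneously every `behavior_interval_s` seconds i.i.d. from
#' `behavior_probs`; every `proximity_interval_s` seconds each other group
#' member is recorded within the proximity radius independently with the
#' per-interval probability for its sex combination; grooming bouts arrive as
#' a Poisson process per focal with lognormal durations and a clique
#' structure drawn from the mutual / extra-groomer parameters.
#'
#' @param n_males,n_females Group composition.
#' @param behavior_probs Named probability vector over the five behavior
#'   categories (foraging, traveling, resting, social_grooming, others),
#'   summing to 1; may instead be a list with elements `male` and `female`
#'   for sex-specific budgets.
#' @param foraging_subtype_probs Named probability vector over collecting /
#'   extractive / hunting, summing to 1 (conditional on foraging).
#' @param prox_prob Named vector `c(MM=, FF=, MF=)` of per-interval
#'   association probabilities in `[0, 1]`.
#' @param structural_zero_pairs List of length-2 character vectors of ids
#'   never co-present (their association probability is forced to 0).
#' @param groom_rate Expected grooming bouts per focal-hour.
#' @param groom_duration_s Length-2 vector `c(mean, sd)` of the lognormal
#'   bout duration in seconds.
#' @param mutual_prob Probability that a bout is mutual grooming.
#' @param extra_groomer_dist Probability vector over 0:3 additional
#'   individuals grooming the focal beyond the mutual partner (or beyond
#'   none, for one-directional cliques).
#' @param ghc_prob Probability a mutual bout includes a grooming handclasp.
#' @param abnormal_prob Per-sample probability of flagging an abnormal
#'   behavior (default 0).
#' @param behavior_interval_s,proximity_interval_s,proximity_radius_m,proximity_protocol
#'   Sampling protocol shared by all sessions.
#' @param n_sessions Sessions per focal.
#' @param session_length_min Session length in minutes.
#' @param age_categories Optional list with `male` / `female` character
#'   vectors assigning an age category to each individual (default all
#'   adult).
#' @param group_id Group label attached to the roster and sessions.
#' @param seed Integer seed; a fixed seed makes [simulate_colony()] output
#'   fully reproducible.
#' @return A `colony_config` object (named list).
#' @export
colony_config <- function(n_males,
                          n_females,
                          behavior_probs,
                          foraging_subtype_probs,
                          prox_prob,
                          structural_zero_pairs = list(),
                          groom_rate = 1,
                          groom_duration_s = c(300, 200),
                          mutual_prob = 0.1,
                          extra_groomer_dist = c(0.7, 0.2, 0.08, 0.02),
                          ghc_prob = 0,
                          abnormal_prob = 0,
                          behavior_interval_s = 180,
                          proximity_interval_s = 180,
                          proximity_radius_m = 3,
                          proximity_protocol = "instantaneous",
                          n_sessions = 2,
                          session_length_min = 300,
                          age_categories = NULL,
                          group_id = "synthetic",
                          seed = 1L) {
  check_prob_vector <- function(p, what, levels) {
    if (!is.numeric(p) || is.null(names(p)) || !setequal(names(p), levels)) {
      config_error(paste0(what, " must be a named vector over {", paste(levels, collapse = ", "), "}"))
    }
    if (any(p < 0) || any(p > 1)) {
      config_error(paste0(what, " entries must lie in [0, 1]"))
    }
    if (abs(sum(p) - 1) > 1e-12) {
      config_error(paste0(what, " must sum to 1 (got ", format(sum(p), digits = 15), ")"))
    }
    p[levels]
  }
  if (is.list(behavior_probs)) {
    behavior_probs <- list(
      male = check_prob_vector(behavior_probs$male, "behavior_probs$male", BEHAVIOR_CATEGORIES),
      female = check_prob_vector(behavior_probs$female, "behavior_probs$female", BEHAVIOR_CATEGORIES)
    )
  } else {
    behavior_probs <- check_prob_vector(behavior_probs, "behavior_probs", BEHAVIOR_CATEGORIES)
  }
  foraging_subtype_probs <- check_prob_vector(
    foraging_subtype_probs, "foraging_subtype_probs", FORAGING_SUBTYPES
  )
  if (!setequal(names(prox_prob), SEX_COMBINATIONS)) {
    config_error("prox_prob must be a named vector over {MM, FF, MF}")
  }
  if (any(prox_prob < 0) || any(prox_prob > 1)) {
    config_error("prox_prob entries must lie in [0, 1]")
  }
  for (p in c(mutual_prob, ghc_prob, abnormal_prob)) {
    if (p < 0 || p > 1) config_error("probabilities must lie in [0, 1]")
  }
  if (length(extra_groomer_dist) != 4 || any(extra_groomer_dist < 0) ||
    abs(sum(extra_groomer_dist) - 1) > 1e-12) {
    config_error("extra_groomer_dist must be a probability vector over 0:3")
  }
  if (groom_rate < 0) config_error("groom_rate must be >= 0")
  if (any(groom_duration_s <= 0)) config_error("groom_duration_s mean and sd must be positive")
  if (!proximity_protocol %in% PROXIMITY_PROTOCOLS) {
    config_error(paste0("unknown proximity_protocol '", proximity_protocol, "'"))
  }
  if (n_sessions < 1 || session_length_min <= 0) {
    config_error("n_sessions must be >= 1 and session_length_min > 0")
  }
  structure(
    list(
      n_males = as.integer(n_males), n_females = as.integer(n_females),
      behavior_probs = behavior_probs,
      foraging_subtype_probs = foraging_subtype_probs,
      prox_prob = prox_prob[SEX_COMBINATIONS],
      structural_zero_pairs = structural_zero_pairs,
      groom_rate = groom_rate, groom_duration_s = groom_duration_s,
      mutual_prob = mutual_prob, extra_groomer_dist = extra_groomer_dist,
      ghc_prob = ghc_prob, abnormal_prob = abnormal_prob,
      behavior_interval_s = behavior_interval_s,
      proximity_interval_s = proximity_interval_s,
      proximity_radius_m = proximity_radius_m,
      proximity_protocol = proximity_protocol,
      n_sessions = as.integer(n_sessions),
      session_length_min = session_length_min,
      age_categories = age_categories,
      group_id = group_id,
      seed = as.integer(seed)
    ),
    class = "colony_config"
  )
}

#' Wild-group-like preset
#'
#' Sixteen focals (8 males, 8 females) observed under the field protocol:
#' 1-min instantaneous behavior sampling and 5-min one-zero proximity
#' sampling within 10 m, 13 two-hour follows per focal (about 1,560 min
#' each). Male-male per-interval association probability (0.17) exceeds
#' female-female (0.09) and male-female (0.085), the mutual-grooming
#' probability is low (0.067), and mutual bouts can include grooming
#' handclasps — echoing the sex-structured proximity and grooming pattern of
#' a wild multimale-multifemale group.
#'
#' @param seed Integer seed.
#' @return A `colony_config`.
#' @export
wild_like_config <- function(seed = 1L) {
  colony_config(
    n_males = 8, n_females = 8,
    behavior_probs = c(
      foraging = 0.213, traveling = 0.154, resting = 0.430,
      social_grooming = 0.100, others = 0.103
    ),
    foraging_subtype_probs = c(collecting = 0.182, extractive = 0.028, hunting = 0.003) / 0.213,
    prox_prob = c(MM = 0.17, FF = 0.09, MF = 0.085),
    groom_rate = 1.0,
    mutual_prob = 0.067,
    ghc_prob = 1,
    behavior_interval_s = 60,
    proximity_interval_s = 300,
    proximity_radius_m = 10,
    proximity_protocol = "one_zero",
    n_sessions = 13,
    session_length_min = 120,
    age_categories = list(
      male = c(rep("adult", 7), "young"),
      female = rep("adult", 8)
    ),
    group_id = "wild",
    seed = seed
  )
}

#' Captive-group-like preset
#'
#' Sixteen focals (5 males, 11 females) observed under the enclosure
#' protocol: 3-min instantaneous sampling for both behavior and proximity
#' within 3 m, two five-hour follows per focal (about 600 min each).
#' Association probability is equal across sex combinations (no sex
#' structure in the network), the mutual-grooming probability is high
#' (0.268), no grooming handclasps occur, and three managed pairs are never
#' co-present (structural zeros).
#'
#' @param seed Integer seed.
#' @return A `colony_config`.
#' @export
captive_like_config <- function(seed = 1L) {
  colony_config(
    n_males = 5, n_females = 11,
    behavior_probs = c(
      foraging = 0.188, traveling = 0.120, resting = 0.500,
      social_grooming = 0.080, others = 0.112
    ),
    foraging_subtype_probs = c(collecting = 0.114, extractive = 0.074, hunting = 0) / 0.188,
    prox_prob = c(MM = 0.12, FF = 0.12, MF = 0.12),
    structural_zero_pairs = list(c("ma", "mb"), c("fa", "fb"), c("me", "fa")),
    groom_rate = 1.2,
    mutual_prob = 0.268,
    ghc_prob = 0,
    behavior_interval_s = 180,
    proximity_interval_s = 180,
    proximity_radius_m = 3,
    proximity_protocol = "instantaneous",
    n_sessions = 2,
    session_length_min = 300,
    age_categories = list(
      male = c("young", "adult", "young", "young", "juvenile"),
      female = c(rep("adult", 10), "young")
    ),
    group_id = "captive",
    seed = seed
  )
}

colony_roster <- function(config) {
  male_ids <- paste0("m", letters[seq_len(config$n_males)])
  female_ids <- paste0("f", letters[seq_len(config$n_females)])
  cats <- config$age_categories %||% list(
    male = rep("adult", config$n_males),
    female = rep("adult", config$n_females)
  )
  tibble(
    id = c(male_ids, female_ids),
    abbrev = c(male_ids, female_ids),
    sex = c(rep("male", config$n_males), rep("female", config$n_females)),
    age_years = dplyr::case_when(
      c(cats$male, cats$female) == "adult" ~ 20L,
      c(cats$male, cats$female) == "young" ~ 12L,
      TRUE ~ 5L
    ),
    age_category = c(cats$male, cats$female),
    group_id = config$group_id,
    origin = "synthetic"
  )
}

sex_combination <- function(sex_a, sex_b) {
  dplyr::case_when(
    sex_a == "male" & sex_b == "male" ~ "MM",
    sex_a == "female" & sex_b == "female" ~ "FF",
    TRUE ~ "MF"
  )
}

pair_prob_lookup <- function(config, roster) {
  sex_of <- stats::setNames(roster$sex, roster$id)
  zero_key <- map_chr(config$structural_zero_pairs, function(p) paste(sort(p), collapse = "|"))
  function(a, b) {
    key <- paste(pmin(a, b), pmax(a, b), sep = "|")
    p <- unname(config$prox_prob[sex_combination(sex_of[a], sex_of[b])])
    p[key %in% zero_key] <- 0
    p
  }
}

#' Simulate a complete focal-sampling dataset
#'
#' Generates the five tables of a focal-sampling study (roster, sessions,
#' behavior samples, proximity samples, grooming bouts) with the statistical
#' structure described in [colony_config()]. Output is byte-identical for a
#' fixed config (including its seed).
#'
#' @param config A `colony_config`.
#' @return Named list of tibbles: `roster`, `sessions`, `behavior`,
#'   `proximity`, `grooming`.
#' @examples
#' colony <- simulate_colony(captive_like_config(seed = 7))
#' nrow(colony$roster)
#' @export
simulate_colony <- function(config) {
  if (!inherits(config, "colony_config")) {
    config_error("config must be created by colony_config()")
  }
  roster <- colony_roster(config)
  sessions <- colony_sessions(config, roster)
  behavior <- with_seed(
    stage_seed(config$seed, "behavior"),
    simulate_behavior(config, roster, sessions)
  )
  proximity <- with_seed(
    stage_seed(config$seed, "proximity"),
    simulate_proximity(config, roster, sessions)
  )
  grooming <- with_seed(
    stage_seed(config$seed, "grooming"),
    simulate_grooming(config, roster, sessions)
  )
  list(
    roster = roster, sessions = sessions, behavior = behavior,
    proximity = proximity, grooming = grooming
  )
}

colony_sessions <- function(config, roster) {
  grid <- tidyr::expand_grid(focal_id = roster$id, k = seq_len(config$n_sessions))
  tibble(
    session_id = sprintf("S-%s-%02d", grid$focal_id, grid$k),
    group_id = config$group_id,
    date = as.Date("2020-01-01") + (grid$k - 1L),
    focal_id = grid$focal_id,
    behavior_interval_s = config$behavior_interval_s,
    proximity_interval_s = config$proximity_interval_s,
    proximity_radius_m = config$proximity_radius_m,
    proximity_protocol = config$proximity_protocol
  )
}

sampling_points <- function(session_length_min, interval_s) {
  n <- floor(session_length_min * 60 / interval_s)
  seq(0, by = interval_s, length.out = n)
}

simulate_behavior <- function(config, roster, sessions) {
  ts <- sampling_points(config$session_length_min, config$behavior_interval_s)
  sex_of <- stats::setNames(roster$sex, roster$id)
  probs_for <- function(sex) {
    if (is.list(config$behavior_probs)) config$behavior_probs[[sex]] else config$behavior_probs
  }
  rows <- map(seq_len(nrow(sessions)), function(i) {
    focal <- sessions$focal_id[i]
    p <- probs_for(sex_of[focal])
    category <- sample(BEHAVIOR_CATEGORIES, length(ts), replace = TRUE, prob = p)
    subtype <- rep("none", length(ts))
    n_forage <- sum(category == "foraging")
    if (n_forage > 0) {
      subtype[category == "foraging"] <- sample(
        FORAGING_SUBTYPES, n_forage,
        replace = TRUE, prob = config$foraging_subtype_probs
      )
    }
    tibble(
      session_id = sessions$session_id[i],
      timestamp = ts,
      focal_id = focal,
      category = category,
      foraging_subtype = subtype,
      abnormal_flag = stats::runif(length(ts)) < config$abnormal_prob
    )
  })
  dplyr::bind_rows(rows)
}

simulate_proximity <- function(config, roster, sessions) {
  ts <- sampling_points(config$session_length_min, config$proximity_interval_s)
  prob_fn <- pair_prob_lookup(config, roster)
  rows <- map(seq_len(nrow(sessions)), function(i) {
    focal <- sessions$focal_id[i]
    partners <- setdiff(roster$id, focal)
    p <- prob_fn(rep(focal, length(partners)), partners)
    present <- matrix(
      stats::runif(length(ts) * length(partners)) < rep(p, each = length(ts)),
      nrow = length(ts)
    )
    tibble(
      session_id = sessions$session_id[i],
      timestamp = ts,
      focal_id = focal,
      partner_ids = map(seq_along(ts), function(t) sort(partners[present[t, ]]))
    )
  })
  dplyr::bind_rows(rows)
}

lognormal_params <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

simulate_grooming <- function(config, roster, sessions) {
  session_s <- config$session_length_min * 60
  lp <- lognormal_params(config$groom_duration_s[1], config$groom_duration_s[2])
  max_groomers <- min(3L, nrow(roster) - 2L)
  rows <- map(seq_len(nrow(sessions)), function(i) {
    n_bouts <- stats::rpois(1, config$groom_rate * config$session_length_min / 60)
    if (n_bouts == 0) {
      return(NULL)
    }
    dur <- pmin(stats::rlnorm(n_bouts, lp["meanlog"], lp["sdlog"]), session_s / 2)
    start <- sort(stats::runif(n_bouts, 0, session_s - dur))
    end <- start + dur
    keep <- rep(TRUE, n_bouts)
    last_end <- -1
    for (b in seq_len(n_bouts)) {
      if (start[b] < last_end) {
        keep[b] <- FALSE
      } else {
        last_end <- end[b]
      }
    }
    n <- sum(keep)
    mutual <- stats::runif(n) < config$mutual_prob
    focal_grooms <- mutual | (stats::runif(n) < 0.5)
    extra <- sample(0:3, n, replace = TRUE, prob = config$extra_groomer_dist)
    extra <- pmin(extra, max_groomers)
    n_grooming <- ifelse(mutual, 1L + extra, ifelse(focal_grooms, extra, pmax(1L, extra)))
    tibble(
      session_id = sessions$session_id[i],
      focal_id = sessions$focal_id[i],
      start_s = round(start[keep], 1),
      end_s = round(end[keep], 1),
      clique = encode_clique(mutual, focal_grooms, n_grooming),
      ghc_flag = mutual & stats::runif(n) < config$ghc_prob
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      session_id = character(0), focal_id = character(0), start_s = double(0),
      end_s = double(0), clique = character(0), ghc_flag = logical(0)
    )
  }
  out
}

#' Simulate a proximity tally directly
#'
#' Draws the per-pair proximity tallies a full [simulate_colony()] run would
#' induce, without materialising the sample-level records: under the
#' generator each partner is present at each of a focal's sampling points
#' independently with its pair probability, so the focal-side near-count for
#' a pair is Binomial(points, p). This is the fast path for replication
#' studies (e.g. type-I-error calibration of the randomization test) where
#' only the tally-level quantities matter.
#'
#' @param config A `colony_config`.
#' @param seed Optional seed overriding the config seed.
#' @return A `proximity_tally` object as from [tally_proximity()].
#' @export
simulate_proximity_tally <- function(config, seed = NULL) {
  if (!inherits(config, "colony_config")) {
    config_error("config must be created by colony_config()")
  }
  roster <- colony_roster(config)
  n_points <- config$n_sessions * floor(config$session_length_min * 60 / config$proximity_interval_s)
  interval_min <- config$proximity_interval_s / 60
  prob_fn <- pair_prob_lookup(config, roster)
  pairs <- tidyr::expand_grid(focal_id = roster$id, partner_id = roster$id) |>
    dplyr::filter(.data$focal_id != .data$partner_id)
  with_seed(seed %||% stage_seed(config$seed, "proximity"), {
    p <- prob_fn(pairs$focal_id, pairs$partner_id)
    counts <- stats::rbinom(nrow(pairs), n_points, p)
    t_near <- tibble(
      focal_id = pairs$focal_id,
      partner_id = pairs$partner_id,
      t_min = counts * interval_min
    )
    t_focal <- tibble(focal_id = roster$id, t_min = n_points * interval_min)
    new_proximity_tally(t_focal, t_near, config$proximity_protocol)
  })
}
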