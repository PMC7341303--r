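#' Encode a grooming-clique configuration as a three-digit code
#'
#' A grooming clique is the instantaneous configuration of individuals
#' directly connected to the focal by grooming. It is coded by three digits:
#' the leading digit is 1 if the focal is engaged in mutual grooming, the
#' middle digit is 1 if the focal is grooming a partner, and the last digit
#' counts the individuals grooming the focal (including the mutual partner,
#' if any). So `"111"` is a mutual dyad, `"010"` is the focal grooming a
#' non-reciprocating partner, and `"003"` is three individuals
#' simultaneously grooming a passive focal.
#'
#' @param mutual Logical vector: focal engaged in mutual grooming.
#' @param focal_grooms Logical vector: focal is grooming someone.
#' @param n_grooming_focal Integer vector: number of individuals grooming
#'   the focal.
#' @return Character vector of three-digit codes.
#' @examples
#' encode_clique(TRUE, TRUE, 2) # "112"
#' encode_clique(FALSE, FALSE, 3) # "003"
#' @export
encode_clique <- function(mutual, focal_grooms, n_grooming_focal) {
  n <- max(length(mutual), length(focal_grooms), length(n_grooming_focal))
  mutual <- rep_len(as.logical(mutual), n)
  focal_grooms <- rep_len(as.logical(focal_grooms), n)
  n_grooming_focal <- rep_len(as.integer(n_grooming_focal), n)
  if (any(n_grooming_focal < 0)) {
    validation_error("n_grooming_focal must be >= 0")
  }
  if (any(n_grooming_focal > 9)) {
    validation_error("n_grooming_focal > 9 cannot be encoded in a single digit")
  }
  if (any(mutual & !focal_grooms)) {
    validation_error("mutual grooming implies the focal is grooming (invalid config)")
  }
  if (any(mutual & n_grooming_focal < 1)) {
    validation_error("mutual grooming implies at least one individual grooms the focal")
  }
  if (any(!mutual & !focal_grooms & n_grooming_focal == 0)) {
    validation_error("a clique with no grooming at all is not a grooming clique")
  }
  paste0(as.integer(mutual), as.integer(focal_grooms), n_grooming_focal)
}

#' Decode a three-digit grooming-clique code
#'
#' Inverse of [encode_clique()]. The participant count is the focal plus the
#' individuals grooming it, plus one more when a non-mutual focal grooms a
#' partner (who is then a distinct recipient, not one of the focal's
#' groomers); in a mutual clique the focal's partner is already counted among
#' its groomers.
#'
#' @param code Character vector of three-digit codes.
#' @return Tibble with columns `code`, `mutual`, `focal_grooms`,
#'   `n_grooming_focal`, `participants`.
#' @examples
#' decode_clique(c("114", "011", "010"))$participants # 5 3 2
#' @export
decode_clique <- function(code) {
  code <- as.character(code)
  bad <- is.na(code) | !str_detect(code, "^[01][01][0-9]$")
  if (any(bad)) {
    validation_error(paste0(
      "invalid clique code: ", paste(unique(code[bad]), collapse = ", ")
    ))
  }
  mutual <- substr(code, 1, 1) == "1"
  focal_grooms <- substr(code, 2, 2) == "1"
  n_grooming_focal <- as.integer(substr(code, 3, 3))
  if (any(mutual & !focal_grooms)) {
    validation_error(paste0(
      "invalid clique code (mutual without focal grooming): ",
      paste(unique(code[mutual & !focal_grooms]), collapse = ", ")
    ))
  }
  if (any(mutual & n_grooming_focal < 1)) {
    validation_error(paste0(
      "invalid clique code (mutual with nobody grooming the focal): ",
      paste(unique(code[mutual & n_grooming_focal < 1]), collapse = ", ")
    ))
  }
  if (any(!mutual & !focal_grooms & n_grooming_focal == 0)) {
    validation_error("invalid clique code: 000 encodes no grooming interaction")
  }
  tibble(
    code = code,
    mutual = mutual,
    focal_grooms = focal_grooms,
    n_grooming_focal = n_grooming_focal,
    participants = 1L + n_grooming_focal + as.integer(focal_grooms & !mutual)
  )
}

#' Is a clique code mutual grooming?
#'
#' Mutual grooming cliques are exactly those whose leading digit is 1
#' (e.g. 111, 112, 114); all other codes are one-directional grooming.
#'
#' @param code Character vector of valid three-digit clique codes.
#' @return Logical vector.
#' @export
is_mutual <- function(code) {
  decode_clique(code)$mutual
}

#' Per-individual grooming summary and mutual-grooming ratio
#'
#' Accumulates all-occurrence grooming-bout seconds per focal, splits them
#' into mutual and one-directional grooming by clique code, and computes the
#' mutual grooming ratio (mutual seconds / total seconds). Individuals with
#' too little recorded grooming to yield a stable ratio, and individuals in
#' excluded age categories, are flagged `excluded` with a reason; their ratio
#' is still reported when defined, but `NA` when total seconds are zero.
#'
#' @param grooming Grooming-bout tibble (`session_id`, `focal_id`, `start_s`,
#'   `end_s`, `clique`, `ghc_flag`).
#' @param roster Roster tibble; all roster members of the relevant group are
#'   summarized, including those never seen grooming.
#' @param focal_id Optional single id to restrict the summary to.
#' @param min_total_s Exclusion threshold on total grooming seconds
#'   (default 300 s).
#' @param excluded_age_categories Age categories excluded from analysis
#'   (default `"juvenile"`).
#' @return Tibble with columns `focal_id`, `total_s`, `mutual_s`,
#'   `mutual_ratio`, `excluded`, `reason`, `ghc_observed`.
#' @export
summarize_grooming <- function(grooming, roster, focal_id = NULL,
                               min_total_s = 300, excluded_age_categories = "juvenile") {
  ids <- roster$id
  if (!is.null(focal_id)) {
    if (!focal_id %in% ids) {
      validation_error(paste0("focal_id '", focal_id, "' not in roster"))
    }
    ids <- focal_id
  }
  info <- decode_clique(grooming$clique)
  per_bout <- tibble(
    focal_id = grooming$focal_id,
    dur = grooming$end_s - grooming$start_s,
    mutual = info$mutual,
    ghc = grooming$ghc_flag
  )
  totals <- per_bout |>
    dplyr::group_by(.data$focal_id) |>
    dplyr::summarise(
      total_s = sum(.data$dur),
      mutual_s = sum(.data$dur[.data$mutual]),
      ghc_observed = any(.data$ghc),
      .groups = "drop"
    )
  out <- tibble(focal_id = ids) |>
    dplyr::left_join(totals, by = "focal_id") |>
    dplyr::left_join(roster[c("id", "age_category")], by = c(focal_id = "id")) |>
    dplyr::mutate(
      total_s = dplyr::coalesce(.data$total_s, 0),
      mutual_s = dplyr::coalesce(.data$mutual_s, 0),
      ghc_observed = dplyr::coalesce(.data$ghc_observed, FALSE),
      mutual_ratio = dplyr::if_else(.data$total_s > 0, .data$mutual_s / .data$total_s, NA_real_),
      reason = dplyr::case_when(
        .data$age_category %in% excluded_age_categories ~ "age_category_excluded",
        .data$total_s < min_total_s ~ "insufficient_grooming",
        TRUE ~ NA_character_
      ),
      excluded = !is.na(.data$reason)
    ) |>
    dplyr::select(
      "focal_id", "total_s", "mutual_s", "mutual_ratio",
      "excluded", "reason", "ghc_observed"
    )
  out
}

#' Write grooming summaries to CSV
#'
#' @param summary Tibble from [summarize_grooming()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grooming_summary <- function(summary, path) {
  readr::write_csv(summary, path)
  invisible(path)
}
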