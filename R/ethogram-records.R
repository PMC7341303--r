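#' Read and validate an individual roster
#'
#' The roster lists every study subject with its sex, age, age category and
#' group membership. Individuals are the nodes of all downstream analyses
#' (budgets, grooming summaries, proximity networks), so identifiers must be
#' unique and the categorical fields must use the controlled vocabularies
#' (`sex`: male/female; `age_category`: juvenile/young/adult).
#'
#' @param path Path to a CSV file with header
#'   `id,abbrev,sex,age,age_category,group,origin`.
#' @return A tibble with one row per individual and columns `id`, `abbrev`,
#'   `sex`, `age_years`, `age_category`, `group_id`, `origin`.
#' @examples
#' roster <- read_roster(system.file("extdata", "roster.csv", package = "focalnet"))
#' dplyr::count(roster, group_id, sex)
#' @export
read_roster <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  expected <- c("id", "abbrev", "sex", "age", "age_category", "group", "origin")
  if (!identical(names(raw), expected)) {
    validation_error(paste0(
      "roster header must be '", paste(expected, collapse = ","),
      "', got '", paste(names(raw), collapse = ","), "'"
    ))
  }
  roster <- tibble(
    id = raw$id,
    abbrev = raw$abbrev,
    sex = raw$sex,
    age_years = suppressWarnings(as.integer(raw$age)),
    age_category = raw$age_category,
    group_id = raw$group,
    origin = raw$origin
  )
  validate_roster(roster)
  roster
}

validate_roster <- function(roster) {
  dup <- roster$id[duplicated(roster$id)]
  if (length(dup) > 0) {
    validation_error(paste0(
      "duplicate individual id(s) in roster: ", paste(unique(dup), collapse = ", ")
    ))
  }
  bad_sex <- which(!roster$sex %in% SEX_LEVELS)
  if (length(bad_sex) > 0) {
    validation_error(paste0(
      "unknown sex token '", roster$sex[bad_sex[1]], "' at roster row ", bad_sex[1]
    ))
  }
  bad_age <- which(!roster$age_category %in% AGE_CATEGORIES)
  if (length(bad_age) > 0) {
    validation_error(paste0(
      "unknown age_category token '", roster$age_category[bad_age[1]],
      "' at roster row ", bad_age[1]
    ))
  }
  invisible(roster)
}

#' Write a roster to CSV
#'
#' Inverse of [read_roster()]; the round trip is lossless.
#'
#' @param roster Roster tibble as returned by [read_roster()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  out <- tibble(
    id = roster$id, abbrev = roster$abbrev, sex = roster$sex,
    age = roster$age_years, age_category = roster$age_category,
    group = roster$group_id, origin = roster$origin
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read observation sessions
#'
#' A session is one focal follow: one focal individual observed under a fixed
#' sampling design. The behavior stream is sampled instantaneously every
#' `behavior_interval_s` seconds; the proximity stream uses either
#' instantaneous sampling (partners within the radius at the sampling moment)
#' or one-zero sampling (partners within the radius at any time during the
#' interval), every `proximity_interval_s` seconds.
#'
#' @param path CSV with header `session_id,group_id,date,focal_id,`
#'   `behavior_interval_s,proximity_interval_s,proximity_radius_m,proximity_protocol`.
#' @param roster Roster tibble; every `focal_id` must appear in it.
#' @return Tibble of sessions.
#' @export
read_sessions <- function(path, roster) {
  sessions <- readr::read_csv(path, col_types = readr::cols(
    session_id = readr::col_character(),
    group_id = readr::col_character(),
    date = readr::col_date(),
    focal_id = readr::col_character(),
    behavior_interval_s = readr::col_double(),
    proximity_interval_s = readr::col_double(),
    proximity_radius_m = readr::col_double(),
    proximity_protocol = readr::col_character()
  ))
  validate_sessions(sessions, roster)
  sessions
}

validate_sessions <- function(sessions, roster) {
  dup <- sessions$session_id[duplicated(sessions$session_id)]
  if (length(dup) > 0) {
    validation_error(paste0("duplicate session_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(sessions$behavior_interval_s <= 0) || any(sessions$proximity_interval_s <= 0)) {
    validation_error("sampling intervals must be strictly positive")
  }
  bad_proto <- setdiff(unique(sessions$proximity_protocol), PROXIMITY_PROTOCOLS)
  if (length(bad_proto) > 0) {
    validation_error(paste0("unknown proximity_protocol: ", paste(bad_proto, collapse = ", ")))
  }
  missing_focal <- setdiff(sessions$focal_id, roster$id)
  if (length(missing_focal) > 0) {
    validation_error(paste0(
      "session focal_id not in roster: ", paste(missing_focal, collapse = ", ")
    ))
  }
  invisible(sessions)
}

#' @export
write_sessions <- function(sessions, path) {
  readr::write_csv(sessions, path)
  invisible(path)
}

sample_stream_type <- function(columns) {
  if (all(c("category", "foraging_subtype") %in% columns)) {
    "behavior"
  } else if ("partner_ids" %in% columns) {
    "proximity"
  } else if (all(c("start_s", "end_s", "clique") %in% columns)) {
    "grooming"
  } else {
    validation_error(paste0(
      "cannot infer record stream type from columns: ", paste(columns, collapse = ", ")
    ))
  }
}

#' Read a focal-sampling record stream
#'
#' Reads one of the three record streams produced by a focal follow and
#' validates it against the roster and session table. The stream type
#' (behavior, proximity, grooming) is inferred from the CSV header.
#'
#' Behavior samples are instantaneous states, one row per sampling point,
#' with `category` in foraging/traveling/resting/social_grooming/others and a
#' `foraging_subtype` (collecting/extractive/hunting) set exactly when the
#' category is foraging. Proximity samples carry the set of partners within
#' the protocol radius, serialized as a sorted semicolon-joined cell.
#' Grooming bouts are all-occurrence records in seconds with a three-digit
#' clique code (see [encode_clique()]) and a grooming-handclasp flag.
#'
#' @param path CSV path.
#' @param roster Roster tibble for identifier cross-checks.
#' @param sessions Optional session tibble; when supplied, timestamps are
#'   checked for alignment with each session's sampling interval.
#' @return A validated tibble; proximity streams hold `partner_ids` as a
#'   list-column of character vectors.
#' @export
read_samples <- function(path, roster, sessions = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  type <- sample_stream_type(names(raw))
  records <- switch(type,
    behavior = tibble(
      session_id = raw$session_id,
      timestamp = as.double(raw$timestamp),
      focal_id = raw$focal_id,
      category = raw$category,
      foraging_subtype = dplyr::if_else(raw$foraging_subtype %in% c("", "none", NA), "none", raw$foraging_subtype),
      abnormal_flag = as.logical(raw$abnormal_flag)
    ),
    proximity = tibble(
      session_id = raw$session_id,
      timestamp = as.double(raw$timestamp),
      focal_id = raw$focal_id,
      partner_ids = map(raw$partner_ids, parse_partner_cell)
    ),
    grooming = tibble(
      session_id = raw$session_id,
      focal_id = raw$focal_id,
      start_s = as.double(raw$start_s),
      end_s = as.double(raw$end_s),
      clique = raw$clique,
      ghc_flag = as.logical(raw$ghc_flag)
    )
  )
  validate_samples(records, roster, sessions, type)
  records
}

parse_partner_cell <- function(cell) {
  if (is.na(cell) || cell == "") {
    return(character(0))
  }
  sort(str_split(cell, ";")[[1]])
}

validate_samples <- function(records, roster, sessions = NULL, type = sample_stream_type(names(records))) {
  missing_focal <- setdiff(records$focal_id, roster$id)
  if (length(missing_focal) > 0) {
    validation_error(paste0(
      type, " sample focal_id not in roster: ", paste(missing_focal, collapse = ", ")
    ))
  }
  if (type == "behavior") {
    bad_cat <- setdiff(unique(records$category), BEHAVIOR_CATEGORIES)
    if (length(bad_cat) > 0) {
      validation_error(paste0("unknown behavior category: ", paste(bad_cat, collapse = ", ")))
    }
    bad_sub <- setdiff(unique(records$foraging_subtype), c(FORAGING_SUBTYPES, "none"))
    if (length(bad_sub) > 0) {
      validation_error(paste0("unknown foraging subtype: ", paste(bad_sub, collapse = ", ")))
    }
    inconsistent <- xor(records$category == "foraging", records$foraging_subtype != "none")
    if (any(inconsistent)) {
      validation_error(paste0(
        "foraging_subtype must be set iff category is foraging (first bad row ",
        which(inconsistent)[1], ")"
      ))
    }
  }
  if (type == "proximity") {
    self <- map2_lgl(records$focal_id, records$partner_ids, function(f, p) f %in% p)
    if (any(self)) {
      validation_error(paste0(
        "proximity sample lists the focal as its own partner (first bad row ",
        which(self)[1], ")"
      ))
    }
    unknown <- setdiff(unique(unlist(records$partner_ids)), roster$id)
    if (length(unknown) > 0) {
      validation_error(paste0("partner id not in roster: ", paste(unknown, collapse = ", ")))
    }
  }
  if (type == "grooming") {
    if (any(records$end_s <= records$start_s)) {
      validation_error("grooming bout must have end_s > start_s")
    }
    decode_clique(unique(records$clique)) # errors on invalid codes
  }
  if (!is.null(sessions) && type %in% c("behavior", "proximity")) {
    interval_col <- if (type == "behavior") "behavior_interval_s" else "proximity_interval_s"
    joined <- dplyr::left_join(
      records[c("session_id", "timestamp")],
      sessions[c("session_id", interval_col)],
      by = "session_id"
    )
    orphan <- is.na(joined[[interval_col]])
    if (any(orphan)) {
      validation_error(paste0(
        type, " sample references unknown session: ",
        paste(unique(records$session_id[orphan]), collapse = ", ")
      ))
    }
    misaligned <- joined$timestamp %% joined[[interval_col]] != 0
    if (any(misaligned)) {
      i <- which(misaligned)[1]
      validation_error(paste0(
        type, " timestamp ", joined$timestamp[i], " s is not a multiple of the ",
        joined[[interval_col]][i], " s sampling interval (session ",
        joined$session_id[i], ")"
      ))
    }
  }
  invisible(records)
}

#' Write a record stream to CSV
#'
#' Inverse of [read_samples()]; the stream type is inferred from the columns
#' and the write/read round trip is lossless. Proximity partner sets are
#' serialized as a sorted, semicolon-joined cell so each sampling point stays
#' on one row.
#'
#' @param records Behavior, proximity, or grooming tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(records, path) {
  type <- sample_stream_type(names(records))
  out <- records
  if (type == "proximity") {
    out$partner_ids <- map_chr(records$partner_ids, function(p) paste(sort(p), collapse = ";"))
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Validate a complete dataset
#'
#' Cross-checks the five tables of a focal-sampling dataset and returns a
#' violation report rather than raising: an empty report means the dataset is
#' clean. Checks include roster uniqueness, orphan session references,
#' timestamp alignment, foraging-subtype consistency, self-proximity,
#' non-positive or overlapping grooming bouts, and invalid clique codes. The
#' report is independent of row order in the inputs.
#'
#' @param roster,sessions,behavior,proximity,grooming The five tables (any of
#'   the record streams may be `NULL` to skip).
#' @return Tibble with columns `stream`, `rule`, `session_id`, `focal_id`,
#'   `detail`; zero rows iff no violations.
#' @export
validate_dataset <- function(roster, sessions, behavior = NULL, proximity = NULL, grooming = NULL) {
  violations <- list()
  note <- function(stream, rule, session_id = NA_character_, focal_id = NA_character_, detail = "") {
    violations[[length(violations) + 1]] <<- tibble(
      stream = stream, rule = rule, session_id = session_id,
      focal_id = focal_id, detail = detail
    )
  }

  dup <- unique(roster$id[duplicated(roster$id)])
  for (d in dup) note("roster", "duplicate_id", focal_id = d)

  for (i in which(!sessions$focal_id %in% roster$id)) {
    note("sessions", "focal_not_in_roster", sessions$session_id[i], sessions$focal_id[i])
  }
  for (i in which(sessions$behavior_interval_s <= 0 | sessions$proximity_interval_s <= 0)) {
    note("sessions", "nonpositive_interval", sessions$session_id[i], sessions$focal_id[i])
  }

  check_common <- function(records, type, interval_col) {
    for (f in sort(unique(setdiff(records$focal_id, roster$id)))) {
      note(type, "focal_not_in_roster", focal_id = f)
    }
    for (sid in sort(unique(setdiff(records$session_id, sessions$session_id)))) {
      note(type, "orphan_session", session_id = sid)
    }
    known <- records$session_id %in% sessions$session_id
    interval <- sessions[[interval_col]][match(records$session_id, sessions$session_id)]
    bad <- known & records$timestamp %% interval != 0
    for (sid in sort(unique(records$session_id[bad]))) {
      note(type, "misaligned_timestamp", session_id = sid,
        detail = paste0("not a multiple of ", interval_col)
      )
    }
  }
  if (!is.null(behavior)) {
    check_common(behavior, "behavior", "behavior_interval_s")
    inconsistent <- xor(behavior$category == "foraging", behavior$foraging_subtype != "none")
    for (sid in sort(unique(behavior$session_id[inconsistent]))) {
      note("behavior", "subtype_category_mismatch", session_id = sid)
    }
  }
  if (!is.null(proximity)) {
    check_common(proximity, "proximity", "proximity_interval_s")
    self <- map2_lgl(proximity$focal_id, proximity$partner_ids, function(f, p) f %in% p)
    selfed <- unique(proximity[self, c("session_id", "focal_id")])
    for (i in seq_len(nrow(selfed))) {
      note("proximity", "self_proximity", selfed$session_id[i], selfed$focal_id[i])
    }
    unknown <- sort(setdiff(unique(unlist(proximity$partner_ids)), roster$id))
    for (p in unknown) note("proximity", "partner_not_in_roster", detail = p)
  }

  if (!is.null(grooming)) {
    nonpos <- which(grooming$end_s <= grooming$start_s)
    for (i in nonpos) {
      note("grooming", "nonpositive_duration", grooming$session_id[i], grooming$focal_id[i],
        detail = paste0("start_s=", grooming$start_s[i], " end_s=", grooming$end_s[i])
      )
    }
    ok <- setdiff(seq_len(nrow(grooming)), nonpos)
    by_focal <- split(grooming[ok, ], grooming$focal_id[ok])
    for (g in by_focal) {
      for (sid in unique(g$session_id)) {
        b <- dplyr::arrange(g[g$session_id == sid, ], .data$start_s)
        if (nrow(b) > 1 && any(b$start_s[-1] < b$end_s[-nrow(b)])) {
          note("grooming", "overlapping_bouts", sid, b$focal_id[1])
        }
      }
    }
    bad_code <- tryCatch(
      {
        decode_clique(unique(grooming$clique))
        NULL
      },
      focalnet_validation_error = function(e) conditionMessage(e)
    )
    if (!is.null(bad_code)) note("grooming", "invalid_clique_code", detail = bad_code)
    orphan <- setdiff(unique(grooming$session_id), sessions$session_id)
    for (sid in orphan) note("grooming", "orphan_session", sid)
  }

  report <- dplyr::bind_rows(violations)
  if (nrow(report) == 0) {
    report <- tibble(
      stream = character(0), rule = character(0), session_id = character(0),
      focal_id = character(0), detail = character(0)
    )
  }
  dplyr::arrange(report, .data$stream, .data$rule, .data$session_id, .data$focal_id, .data$detail)
}
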