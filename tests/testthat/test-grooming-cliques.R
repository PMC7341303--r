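# The nine clique configurations observed in the study, with their
# participant counts.
printed_cliques <- tibble::tribble(
  ~code, ~mutual, ~focal_grooms, ~n_grooming_focal, ~participants,
  "001", FALSE, FALSE, 1L, 2L,
  "010", FALSE, TRUE, 0L, 2L,
  "111", TRUE, TRUE, 1L, 2L,
  "011", FALSE, TRUE, 1L, 3L,
  "002", FALSE, FALSE, 2L, 3L,
  "112", TRUE, TRUE, 2L, 3L,
  "003", FALSE, FALSE, 3L, 4L,
  "012", FALSE, TRUE, 2L, 4L,
  "114", TRUE, TRUE, 4L, 5L
)

test_that("encode/decode reproduce every printed clique configuration", {
  expect_equal(
    encode_clique(
      printed_cliques$mutual, printed_cliques$focal_grooms,
      printed_cliques$n_grooming_focal
    ),
    printed_cliques$code
  )
  dec <- decode_clique(printed_cliques$code)
  expect_equal(dec$mutual, printed_cliques$mutual)
  expect_equal(dec$focal_grooms, printed_cliques$focal_grooms)
  expect_equal(dec$n_grooming_focal, printed_cliques$n_grooming_focal)
  expect_equal(dec$participants, printed_cliques$participants)
})

test_that("mutual grooming is exactly the leading-digit-1 codes", {
  expect_true(all(is_mutual(c("111", "112", "114"))))
  expect_false(any(is_mutual(c("001", "010", "011", "002", "003", "012"))))
})

test_that("invalid codes and configurations are rejected", {
  expect_error(decode_clique("101"), class = "focalnet_validation_error")
  expect_error(decode_clique("110"), class = "focalnet_validation_error")
  expect_error(decode_clique("000"), class = "focalnet_validation_error")
  expect_error(decode_clique("21x"), class = "focalnet_validation_error")
  expect_error(encode_clique(TRUE, FALSE, 1), class = "focalnet_validation_error")
  expect_error(encode_clique(FALSE, TRUE, 10), class = "focalnet_validation_error")
})

test_that("encode and decode are mutually inverse on all valid configs", {
  grid <- expand.grid(
    mutual = c(TRUE, FALSE), focal_grooms = c(TRUE, FALSE),
    n_grooming_focal = 0:4
  )
  valid <- with(grid, !(mutual & !focal_grooms) & !(mutual & n_grooming_focal < 1) &
    !(!mutual & !focal_grooms & n_grooming_focal == 0))
  grid <- grid[valid, ]
  codes <- encode_clique(grid$mutual, grid$focal_grooms, grid$n_grooming_focal)
  dec <- decode_clique(codes)
  expect_equal(dec$mutual, grid$mutual)
  expect_equal(dec$focal_grooms, grid$focal_grooms)
  expect_equal(dec$n_grooming_focal, grid$n_grooming_focal)
  expect_equal(encode_clique(dec$mutual, dec$focal_grooms, dec$n_grooming_focal), codes)
})

make_bouts <- function(focal_id, durations, cliques, ghc = FALSE) {
  starts <- cumsum(c(0, durations[-length(durations)] + 10))
  tibble::tibble(
    session_id = "S1", focal_id = focal_id,
    start_s = starts, end_s = starts + durations,
    clique = cliques, ghc_flag = rep_len(ghc, length(durations))
  )
}

test_that("mutual ratio is mutual seconds over total seconds", {
  roster <- toy_roster()
  bouts <- make_bouts("m1", c(120, 360), c("111", "001"))
  s <- summarize_grooming(bouts, roster, focal_id = "m1", min_total_s = 300)
  expect_equal(s$total_s, 480)
  expect_equal(s$mutual_s, 120)
  expect_equal(s$mutual_ratio, 0.25)
  expect_false(s$excluded)

  one_dir <- summarize_grooming(
    make_bouts("m1", c(200, 200), c("010", "002")), roster, "m1", min_total_s = 300
  )
  expect_equal(one_dir$mutual_ratio, 0)
})

test_that("exclusion rules flag sparse groomers and excluded age categories", {
  roster <- toy_roster()
  roster$age_category[roster$id == "f2"] <- "juvenile"
  bouts <- dplyr::bind_rows(
    make_bouts("m1", c(400), "111"),
    make_bouts("m2", c(219), "010"),
    make_bouts("f2", c(500), "111")
  )
  s <- summarize_grooming(bouts, roster, min_total_s = 300)
  expect_false(s$excluded[s$focal_id == "m1"])
  expect_true(s$excluded[s$focal_id == "m2"])
  expect_equal(s$reason[s$focal_id == "m2"], "insufficient_grooming")
  expect_true(s$excluded[s$focal_id == "f2"])
  expect_equal(s$reason[s$focal_id == "f2"], "age_category_excluded")
  # never observed grooming at all: zero seconds, ratio undefined
  f1 <- s[s$focal_id == "f1", ]
  expect_true(f1$excluded)
  expect_equal(f1$total_s, 0)
  expect_true(is.na(f1$mutual_ratio))
})

test_that("mutual seconds agree between the code path and the config path", {
  colony <- simulate_colony(tiny_colony_config(seed = 13, mutual_prob = 0.4))
  via_code <- colony$grooming |>
    dplyr::mutate(dur = end_s - start_s, mutual = is_mutual(clique)) |>
    dplyr::group_by(focal_id) |>
    dplyr::summarise(mutual_s = sum(dur[mutual]), .groups = "drop")
  via_config <- colony$grooming |>
    dplyr::mutate(
      dur = end_s - start_s,
      mutual = decode_clique(clique)$mutual
    ) |>
    dplyr::group_by(focal_id) |>
    dplyr::summarise(mutual_s = sum(dur[mutual]), .groups = "drop")
  expect_equal(via_code, via_config)
  s <- summarize_grooming(colony$grooming, colony$roster)
  joined <- dplyr::left_join(s, via_code, by = "focal_id", suffix = c("", "_direct"))
  expect_equal(joined$mutual_s, dplyr::coalesce(joined$mutual_s_direct, 0))
})

test_that("the ratio is invariant to splitting bouts into contiguous pieces", {
  roster <- toy_roster()
  whole <- make_bouts("m1", c(600, 300), c("111", "010"))
  split_first <- tibble::tibble(
    session_id = "S1", focal_id = "m1",
    start_s = c(0, 250, 610), end_s = c(250, 600, 910),
    clique = c("111", "111", "010"), ghc_flag = FALSE
  )
  expect_equal(
    summarize_grooming(whole, roster, "m1")$mutual_ratio,
    summarize_grooming(split_first, roster, "m1")$mutual_ratio
  )
})

test_that("grooming handclasp presence follows the generator flag", {
  with_ghc <- simulate_colony(tiny_colony_config(seed = 3, mutual_prob = 0.6, ghc_prob = 1))
  s1 <- summarize_grooming(with_ghc$grooming, with_ghc$roster)
  expect_true(any(s1$ghc_observed))
  no_ghc <- simulate_colony(tiny_colony_config(seed = 3, mutual_prob = 0.6, ghc_prob = 0))
  s0 <- summarize_grooming(no_ghc$grooming, no_ghc$roster)
  expect_false(any(s0$ghc_observed))
})
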