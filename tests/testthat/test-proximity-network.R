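test_that("tallies convert sample counts to minutes by protocol interval", {
  roster <- toy_roster()
  sessions <- toy_sessions(roster) # 180 s instantaneous
  n <- 40
  prox <- tibble::tibble(
    session_id = "S-m1",
    timestamp = seq(0, by = 180, length.out = n),
    focal_id = "m1",
    partner_ids = c(rep(list("f1"), 10), rep(list(character(0)), n - 10))
  )
  tal <- tally_proximity(prox, sessions)
  expect_equal(focalnet:::tally_time(tal, "m1"), 120) # 40 x 3 min
  expect_equal(focalnet:::tally_near(tal, "m1", "f1"), 30) # 10 x 3 min
  expect_equal(focalnet:::tally_near(tal, "m1", "f2"), 0)

  always <- dplyr::mutate(prox, partner_ids = list("f1"))
  tal2 <- tally_proximity(always, sessions)
  expect_equal(
    focalnet:::tally_near(tal2, "m1", "f1"),
    focalnet:::tally_time(tal2, "m1")
  )

  mixed <- dplyr::bind_rows(
    sessions,
    dplyr::mutate(toy_sessions(roster, protocol = "one_zero"),
      session_id = paste0(session_id, "-b")
    )
  )
  expect_error(tally_proximity(prox, mixed), "protocol", class = "focalnet_validation_error")
})

test_that("the proximity index is the paired ratio of near time to observation time", {
  tal <- make_tally(
    t_focal = tibble::tibble(focal_id = c("a", "b"), t_min = c(100, 200)),
    t_near = tibble::tibble(
      focal_id = c("a", "b"), partner_id = c("b", "a"), t_min = c(30, 50)
    )
  )
  expect_equal(proximity_index(tal, "a", "b"), 80 / 300)
  expect_equal(proximity_index(tal, "b", "a"), 80 / 300)

  none <- make_tally(
    tibble::tibble(focal_id = c("a", "b"), t_min = c(100, 100)),
    tibble::tibble(focal_id = character(0), partner_id = character(0), t_min = double(0))
  )
  expect_equal(proximity_index(none, "a", "b"), 0)

  maximal <- make_tally(
    tibble::tibble(focal_id = c("a", "b"), t_min = c(100, 200)),
    tibble::tibble(focal_id = c("a", "b"), partner_id = c("b", "a"), t_min = c(100, 200))
  )
  expect_equal(proximity_index(maximal, "a", "b"), 1)

  unobserved <- make_tally(
    tibble::tibble(focal_id = "c", t_min = 0),
    tibble::tibble(focal_id = character(0), partner_id = character(0), t_min = double(0))
  )
  expect_error(proximity_index(unobserved, "c", "d"), class = "focalnet_validation_error")
})

test_that("PI matrices are symmetric, bounded, and follow roster order", {
  colony <- simulate_colony(tiny_colony_config(seed = 21))
  tal <- tally_proximity(colony$proximity, colony$sessions)
  m <- build_pi_matrix(tal, colony$roster)
  expect_equal(rownames(m), colony$roster$id)
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(diag(m) == 0))

  perm <- sample(nrow(colony$roster))
  m_perm <- build_pi_matrix(tal, colony$roster[perm, ])
  expect_equal(unclass(m_perm), unclass(m)[perm, perm], ignore_attr = TRUE)
})

test_that("the quartile threshold is the interpolated order statistic", {
  ids <- c("a", "b", "c", "d")
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m[upper.tri(m)] <- c(0.1, 0.2, 0.3, 0.4, 0.15, 0.25)
  m <- m + t(m)
  net <- q3_filter(m)
  expect_equal(net$threshold, unname(stats::quantile(m[upper.tri(m)], 0.75)))

  # four distinct pair values: Q3 interpolates to 0.325, only 0.4 survives
  m2 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m2[cbind(c(1, 1, 1, 2), c(2, 3, 4, 3))] <- c(0.1, 0.2, 0.3, 0.4)
  m2 <- m2 + t(m2)
  net2 <- q3_filter(m2, include_zeros = FALSE)
  expect_equal(net2$threshold, 0.325)
  expect_equal(net2$edges$weight, 0.4)

  # ties at the threshold are kept (inclusive rule)
  m3 <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  diag(m3) <- 0
  net3 <- q3_filter(m3)
  expect_equal(nrow(net3$edges), 6)

  zeros <- matrix(0, 4, 4, dimnames = list(ids, ids))
  expect_warning(net0 <- q3_filter(zeros), "no edges")
  expect_equal(net0$threshold, 0)
  expect_equal(nrow(net0$edges), 0)
})

test_that("the filter keeps about a quarter of dyads and Q1 contains Q3", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(8:16, 1)
    ids <- sprintf("i%02d", 1:n)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
    m <- m + t(m)
    n_pairs <- n * (n - 1) / 2
    q3 <- q3_filter(m)
    expect_gte(nrow(q3$edges) / n_pairs, 0.24)
    expect_lte(nrow(q3$edges) / n_pairs, 0.30)
    q1 <- q3_filter(m, quartile = 0.25)
    key <- function(e) paste(e$from, e$to)
    expect_true(all(key(q3$edges) %in% key(q1$edges)))
  }
  # a 16-individual group ranks 120 dyadic values
  expect_equal(16 * 15 / 2, 120)
})

test_that("power-iteration centrality matches the dense eigen oracle", {
  set.seed(11)
  for (rep in 1:50) {
    net <- random_connected_network(sample(4:12, 1))
    cen <- eigenvector_centrality(net)
    expect_lt(max(abs(cen$centrality - oracle_centrality(net))), 1e-8)
    expect_equal(sum(cen$centrality^2), 1, tolerance = 1e-9)
    expect_true(all(cen$centrality >= 0))
  }
})

test_that("centrality handles symmetry, isolates and empty networks", {
  ids <- c("a", "b", "c", "d")
  complete <- structure(
    list(
      edges = tibble::tibble(
        from = c("a", "a", "a", "b", "b", "c"),
        to = c("b", "c", "d", "c", "d", "d"),
        weight = 0.5
      ),
      threshold = 0, nodes = ids, quartile = 0.75, protocol = NULL
    ),
    class = "filtered_network"
  )
  cen <- eigenvector_centrality(complete)
  expect_equal(cen$centrality, rep(0.5, 4), tolerance = 1e-9)

  with_isolate <- structure(
    list(
      edges = tibble::tibble(
        from = c("a", "a", "b"), to = c("b", "c", "c"), weight = c(0.4, 0.3, 0.5)
      ),
      threshold = 0, nodes = c(ids, "e"), quartile = 0.75, protocol = NULL
    ),
    class = "filtered_network"
  )
  cen_iso <- eigenvector_centrality(with_isolate)
  expect_equal(cen_iso$centrality[cen_iso$id == "e"], 0)
  expect_equal(cen_iso$centrality[cen_iso$id == "d"], 0)
  expect_true(all(cen_iso$centrality[cen_iso$id %in% c("a", "b", "c")] > 0))

  empty <- structure(
    list(
      edges = tibble::tibble(from = character(0), to = character(0), weight = double(0)),
      threshold = 0, nodes = ids, quartile = 0.75, protocol = NULL
    ),
    class = "filtered_network"
  )
  expect_error(eigenvector_centrality(empty), class = "focalnet_validation_error")
})

test_that("centrality agrees with igraph as an independent implementation", {
  set.seed(5)
  net <- random_connected_network(10)
  cen <- eigenvector_centrality(net)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes))
  ig <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  ig <- ig[cen$id] / sqrt(sum(ig^2))
  expect_equal(cen$centrality, unname(ig), tolerance = 1e-6)
})

test_that("dyads are labeled by sex combination with complete coverage", {
  roster <- toy_roster(n_males = 8, n_females = 8)
  n <- 16
  m <- matrix(stats::runif(n * n), n, n, dimnames = list(roster$id, roster$id))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  labeled <- sex_combination_pis(m, roster)
  counts <- table(labeled$sex_combination)
  expect_equal(unname(counts[["MM"]]), 28)
  expect_equal(unname(counts[["FF"]]), 28)
  expect_equal(unname(counts[["MF"]]), 64)
  expect_equal(nrow(labeled), 120)

  # invariant to roster row order
  labeled2 <- sex_combination_pis(m, roster[sample(nrow(roster)), ])
  j <- dplyr::inner_join(labeled, labeled2, by = c("id_a", "id_b"))
  expect_equal(nrow(j), 120)
  expect_equal(j$sex_combination.x, j$sex_combination.y)

  males <- toy_roster(n_males = 5, n_females = 0)
  m5 <- matrix(0.1, 5, 5, dimnames = list(males$id, males$id))
  diag(m5) <- 0
  expect_true(all(sex_combination_pis(m5, males)$sex_combination == "MM"))
})
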