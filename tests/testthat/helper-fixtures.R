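# Small fixtures built in code, plus independent oracles used across tests.

toy_roster <- function(n_males = 2, n_females = 2, group_id = "toy") {
  ids <- c(sprintf("m%d", seq_len(n_males)), sprintf("f%d", seq_len(n_females)))
  tibble::tibble(
    id = ids,
    abbrev = ids,
    sex = c(rep("male", n_males), rep("female", n_females)),
    age_years = 20L,
    age_category = "adult",
    group_id = group_id,
    origin = "test"
  )
}

toy_sessions <- function(roster, behavior_interval_s = 180,
                         proximity_interval_s = 180,
                         protocol = "instantaneous") {
  tibble::tibble(
    session_id = paste0("S-", roster$id),
    group_id = roster$group_id,
    date = as.Date("2020-01-01"),
    focal_id = roster$id,
    behavior_interval_s = behavior_interval_s,
    proximity_interval_s = proximity_interval_s,
    proximity_radius_m = 3,
    proximity_protocol = protocol
  )
}

# Build a proximity tally directly from per-focal times (minutes).
make_tally <- function(t_focal, t_near, protocol = "instantaneous") {
  focalnet:::new_proximity_tally(t_focal, t_near, protocol)
}

tiny_colony_config <- function(seed = 1, ...) {
  defaults <- list(
    n_males = 3, n_females = 3,
    behavior_probs = c(
      foraging = 0.2, traveling = 0.2, resting = 0.4,
      social_grooming = 0.1, others = 0.1
    ),
    foraging_subtype_probs = c(collecting = 0.6, extractive = 0.3, hunting = 0.1),
    prox_prob = c(MM = 0.2, FF = 0.1, MF = 0.1),
    groom_rate = 2,
    n_sessions = 2,
    session_length_min = 60,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(colony_config, args)
}

# Exhaustive Mann-Whitney oracle: U from the pair-count definition,
# two-sided p by enumerating all group assignments of the pooled values.
oracle_mw <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u1_obs <- u_stat(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x))
  u_null <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(u_null <= u1_obs + eps), mean(u_null >= u1_obs - eps)))
  list(u = min(u1_obs, length(x) * length(y) - u1_obs), u1 = u1_obs, p = p)
}

# Exhaustive sex-label permutation oracle using stats::t.test for Welch t.
oracle_perm <- function(values, sex) {
  n_f <- sum(sex == "female")
  t_obs <- unname(stats::t.test(
    values[sex == "female"], values[sex == "male"]
  )$statistic)
  idx <- utils::combn(length(values), n_f)
  t_null <- apply(idx, 2, function(i) {
    unname(stats::t.test(values[i], values[-i])$statistic)
  })
  eps <- 1e-12
  list(
    t_obs = t_obs,
    p_lower = mean(t_null <= t_obs + eps),
    p_two = mean(abs(t_null) >= abs(t_obs) - eps)
  )
}

# Random connected weighted graph as a filtered_network (tree + extra edges).
random_connected_network <- function(n) {
  nodes <- sprintf("n%02d", seq_len(n))
  from <- integer(0)
  to <- integer(0)
  for (i in 2:n) {
    from <- c(from, sample(i - 1, 1))
    to <- c(to, i)
  }
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- sample(nrow(extra), size = rbinom(1, nrow(extra), 0.3))
  from <- c(from, extra[pick, "row"])
  to <- c(to, extra[pick, "col"])
  edges <- tibble::tibble(
    from = nodes[from], to = nodes[to],
    weight = stats::runif(length(from), 0.1, 1)
  ) |> dplyr::distinct(from, to, .keep_all = TRUE)
  structure(
    list(edges = edges, threshold = 0, nodes = nodes, quartile = 0.75, protocol = NULL),
    class = "filtered_network"
  )
}

# Dense eigen-solver oracle for eigenvector centrality (independent of the
# package's power iteration).
oracle_centrality <- function(network, weighted = TRUE) {
  nodes <- network$nodes
  a <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  w <- if (weighted) network$edges$weight else 1
  a[cbind(network$edges$from, network$edges$to)] <- w
  a[cbind(network$edges$to, network$edges$from)] <- w
  v <- eigen(a, symmetric = TRUE)$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v / sqrt(sum(v^2))
}
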