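new_proximity_tally <- function(t_focal, t_near, protocol) {
  structure(
    list(t_focal = t_focal, t_near = t_near, protocol = protocol),
    class = "proximity_tally"
  )
}

#' Tally observation and proximity time
#'
#' Converts proximity samples into time tallies: for each focal `A`, the
#' total proximity observation time `T(A)` (sampling points times the
#' session's proximity interval), and for each ordered pair `(A, B)` the
#' time `T_A(B)` that `B` was recorded within the radius while `A` was the
#' focal. Under the instantaneous protocol a sampling point contributes its
#' interval when the partner is present at the sampling moment; under the
#' one-zero protocol an interval contributes when the partner was within the
#' radius at any time during it. Both reduce to counting scored points.
#'
#' @param proximity Proximity-sample tibble (with `partner_ids` list-column).
#' @param sessions Session tibble; supplies each session's interval and
#'   protocol. All sessions must use a single protocol (mixed-protocol
#'   tallies are refused because the resulting times are not comparable).
#' @return A `proximity_tally` object: list with `t_focal` (focal_id, t_min),
#'   `t_near` (focal_id, partner_id, t_min) and the protocol tag.
#' @export
tally_proximity <- function(proximity, sessions) {
  proto <- unique(sessions$proximity_protocol)
  if (length(proto) > 1) {
    validation_error(paste0(
      "sessions mix proximity protocols (", paste(proto, collapse = ", "),
      "); tally each protocol separately"
    ))
  }
  if (!all(proximity$session_id %in% sessions$session_id)) {
    validation_error("proximity samples reference sessions absent from the session table")
  }
  interval_min <- stats::setNames(sessions$proximity_interval_s / 60, sessions$session_id)
  t_focal <- proximity |>
    dplyr::count(.data$focal_id, .data$session_id) |>
    dplyr::mutate(t_min = .data$n * interval_min[.data$session_id]) |>
    dplyr::group_by(.data$focal_id) |>
    dplyr::summarise(t_min = sum(.data$t_min), .groups = "drop")
  t_near <- proximity |>
    dplyr::select("session_id", "focal_id", "partner_ids") |>
    tidyr::unnest(cols = "partner_ids", keep_empty = FALSE) |>
    dplyr::rename(partner_id = "partner_ids") |>
    dplyr::count(.data$focal_id, .data$partner_id, .data$session_id) |>
    dplyr::mutate(t_min = .data$n * interval_min[.data$session_id]) |>
    dplyr::group_by(.data$focal_id, .data$partner_id) |>
    dplyr::summarise(t_min = sum(.data$t_min), .groups = "drop")
  new_proximity_tally(t_focal, t_near, proto)
}

tally_time <- function(tally, id) {
  t <- tally$t_focal$t_min[match(id, tally$t_focal$focal_id)]
  dplyr::coalesce(t, 0)
}

tally_near <- function(tally, a, b) {
  key <- paste(tally$t_near$focal_id, tally$t_near$partner_id, sep = "\r")
  t <- tally$t_near$t_min[match(paste(a, b, sep = "\r"), key)]
  dplyr::coalesce(t, 0)
}

#' Dyadic proximity index
#'
#' The proximity index between individuals `A` and `B` is the simple
#' proximity ratio
#' `PI(A,B) = (T_A(B) + T_B(A)) / (T_A + T_B)`,
#' where `T_A` is the total observation time of focal `A` and `T_A(B)` the
#' time `B` was within the radius while `A` was observed. It is symmetric by
#' construction and lies in `[0, 1]`.
#'
#' @param tally A `proximity_tally` from [tally_proximity()].
#' @param a,b Individual ids.
#' @return The index, a number in `[0, 1]`.
#' @examples
#' # T(A)=100 with 30 near, T(B)=200 with 50 near -> 80/300
#' @export
proximity_index <- function(tally, a, b) {
  ta <- tally_time(tally, a)
  tb <- tally_time(tally, b)
  denom <- ta + tb
  if (any(denom == 0)) {
    validation_error("proximity index undefined: neither individual was observed")
  }
  (tally_near(tally, a, b) + tally_near(tally, b, a)) / denom
}

#' Build the symmetric proximity-index matrix
#'
#' Evaluates the proximity index for every unordered pair in the roster and
#' assembles the square symmetric adjacency matrix used for network
#' construction. The diagonal is undefined and stored as 0.
#'
#' @param tally A `proximity_tally`.
#' @param roster Roster tibble; row/column order follows it.
#' @return A `pi_matrix`: numeric matrix with ids as dimnames and the
#'   protocol tag as an attribute.
#' @export
build_pi_matrix <- function(tally, roster) {
  ids <- roster$id
  n <- length(ids)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  vals <- proximity_index(tally, ids[pairs[, "row"]], ids[pairs[, "col"]])
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[pairs] <- vals
  m[pairs[, c(2, 1)]] <- vals
  structure(m, class = c("pi_matrix", "matrix"), protocol = tally$protocol)
}

#' Read / write a proximity-index matrix
#'
#' `pi_matrix_from_csv()` is the entry point for an externally supplied
#' square matrix (first column holds ids, header holds the same ids), e.g. a
#' published per-pair matrix; `write_pi_matrix()` writes the same layout.
#'
#' @param path CSV path.
#' @param protocol Protocol tag to attach (`"instantaneous"` or
#'   `"one_zero"`).
#' @return A `pi_matrix`.
#' @export
pi_matrix_from_csv <- function(path, protocol = "instantaneous") {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double(),
    id = readr::col_character()
  ))
  ids <- raw$id
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) {
    validation_error("PI matrix CSV must have identical row and column ids")
  }
  if (max(abs(m - t(m))) > 1e-9) {
    validation_error("PI matrix must be symmetric")
  }
  diag(m) <- 0
  structure(m, class = c("pi_matrix", "matrix"), protocol = protocol)
}

#' @rdname pi_matrix_from_csv
#' @param m A `pi_matrix`.
#' @export
write_pi_matrix <- function(m, path) {
  out <- as_tibble(unclass(m))
  out <- dplyr::bind_cols(tibble(id = rownames(m)), out)
  readr::write_csv(out, path)
  invisible(path)
}

pair_values <- function(m) {
  m[upper.tri(m)]
}

#' Third-quartile network filter
#'
#' When a stable group is observed long enough every pair has nonzero
#' association and the raw network is complete, hiding structure. The filter
#' keeps only dyads whose index is at or above the third quartile of all
#' dyadic values (zeros included), i.e. roughly the strongest 25% of pairs
#' (more with ties at the threshold). The quartile is the linearly
#' interpolated order statistic at position `0.75 * (n - 1)` (0-based), so
#' the threshold is bit-reproducible.
#'
#' @param m A `pi_matrix` (or plain symmetric matrix with id dimnames).
#' @param quartile Quantile level of the threshold (default 0.75; 0.25 gives
#'   the more permissive Q1 filter).
#' @param include_zeros Include zero-valued dyads in the threshold
#'   computation (default `TRUE`).
#' @return A `filtered_network`: list with `edges` (from, to, weight),
#'   `threshold`, `nodes` (full roster — isolates kept), `quartile`,
#'   `protocol`.
#' @export
q3_filter <- function(m, quartile = 0.75, include_zeros = TRUE) {
  vals <- pair_values(m)
  if (!include_zeros) {
    vals <- vals[vals > 0]
  }
  if (length(vals) < 4) {
    validation_error("quartile filtering needs at least 4 dyadic values")
  }
  threshold <- unname(stats::quantile(vals, quartile, type = 7))
  if (all(pair_values(m) == 0)) {
    warn("all proximity indices are zero; the filtered network has no edges")
  }
  idx <- which(upper.tri(m) & m >= threshold & m > 0, arr.ind = TRUE)
  edges <- tibble(
    from = rownames(m)[idx[, "row"]],
    to = colnames(m)[idx[, "col"]],
    weight = m[idx]
  ) |>
    dplyr::arrange(.data$from, .data$to)
  structure(
    list(
      edges = edges, threshold = threshold, nodes = rownames(m),
      quartile = quartile, protocol = attr(m, "protocol")
    ),
    class = "filtered_network"
  )
}

network_adjacency <- function(network, weighted = TRUE) {
  nodes <- network$nodes
  a <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- network$edges
  w <- if (weighted) e$weight else rep(1, nrow(e))
  a[cbind(e$from, e$to)] <- w
  a[cbind(e$to, e$from)] <- w
  a
}

#' Eigenvector centrality of a filtered network
#'
#' Scores each individual by the principal eigenvector of the (weighted)
#' adjacency matrix of the filtered network: an individual is central when
#' it is strongly associated with other central individuals. Scores are
#' nonnegative and normalised to unit Euclidean norm over the full node set;
#' isolates outside the dominant component score 0.
#'
#' The default method is power iteration (to relative tolerance `tol`); a
#' dense eigendecomposition (`method = "eigen"`) is provided as an exact
#' alternative and the two agree to well below `1e-8` on connected graphs.
#'
#' @param network A `filtered_network` from [q3_filter()].
#' @param weighted Use edge weights (default) or the binarized network.
#' @param method `"power"` (default) or `"eigen"`.
#' @param tol Relative convergence tolerance for power iteration.
#' @param max_iter Iteration cap for power iteration.
#' @return A `centrality_result`: tibble (`id`, `centrality`) with the
#'   dominant eigenvalue, method and iteration count as attributes.
#' @export
eigenvector_centrality <- function(network, weighted = TRUE,
                                   method = c("power", "eigen"),
                                   tol = 1e-12, max_iter = 100000L) {
  method <- match.arg(method)
  a <- network_adjacency(network, weighted = weighted)
  if (all(a == 0)) {
    validation_error("eigenvector centrality undefined: the network has no edges")
  }
  if (method == "power") {
    # Shift by the max row sum so the dominant eigenvalue of a + shift*I is
    # unique and positive (Perron); otherwise bipartite graphs, whose
    # spectrum is symmetric, make the iteration oscillate between the +/-
    # lambda eigenvectors.
    shift <- max(rowSums(abs(a)))
    as <- a + diag(shift, nrow(a))
    x <- rep(1 / sqrt(nrow(a)), nrow(a))
    iter <- 0L
    repeat {
      iter <- iter + 1L
      y <- drop(as %*% x)
      y <- y / sqrt(sum(y^2))
      if (sqrt(sum((y - x)^2)) < tol || iter >= max_iter) {
        x <- y
        break
      }
      x <- y
    }
    lambda <- drop(crossprod(x, a %*% x))
    scores <- pmax(x, 0)
    scores <- scores / sqrt(sum(scores^2))
  } else {
    dec <- eigen(a, symmetric = TRUE)
    v <- dec$vectors[, 1]
    if (sum(v) < 0) v <- -v
    scores <- pmax(v, 0)
    scores <- scores / sqrt(sum(scores^2))
    lambda <- dec$values[1]
    iter <- NA_integer_
  }
  scores[scores < 1e-12] <- 0
  scores <- scores / sqrt(sum(scores^2))
  structure(
    tibble(id = rownames(a), centrality = unname(scores)),
    class = c("centrality_result", class(tibble())),
    eigenvalue = lambda, method = method, iterations = iter,
    weighted = weighted
  )
}

#' Label dyads by sex combination
#'
#' Assigns every unordered dyad of the roster to one of the three sex
#' combinations (male-male `MM`, female-female `FF`, male-female `MF`) and
#' returns its proximity index, the grouping used for the within-group
#' comparison of association strength by sex.
#'
#' @param m A `pi_matrix`.
#' @param roster Roster tibble with a `sex` column.
#' @return Tibble with columns `id_a`, `id_b`, `pi`, `sex_combination`.
#' @export
sex_combination_pis <- function(m, roster) {
  ids <- rownames(m)
  sex_of <- stats::setNames(roster$sex, roster$id)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    id_a = ids[idx[, "row"]],
    id_b = ids[idx[, "col"]],
    pi = m[idx],
    sex_combination = sex_combination(sex_of[ids[idx[, "row"]]], sex_of[ids[idx[, "col"]]])
  )
}

#' Export a filtered network
#'
#' Writes the weighted edge list as CSV (with the threshold recorded in a
#' comment header line) and, optionally, as GraphML for network software.
#'
#' @param network A `filtered_network`.
#' @param path Output CSV path.
#' @param graphml_path Optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, graphml_path = NULL) {
  header <- paste0(
    "# q3_threshold=", format(network$threshold, digits = 15),
    " quartile=", network$quartile,
    " protocol=", network$protocol %||% "unknown"
  )
  writeLines(c(header, "from,to,weight"), path)
  readr::write_csv(network$edges, path, append = TRUE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges,
      directed = FALSE,
      vertices = data.frame(name = network$nodes)
    )
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}
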