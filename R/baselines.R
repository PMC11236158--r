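#' Subset betweenness centrality from drivers to responses
#'
#' Computes, for every vertex `k`, the sum over driver-response pairs
#' `(j, i)` with `i != k` and `j != k` of the fraction of shortest
#' directed paths from `j` to `i` that pass through `k`. Edges are
#' unweighted; ppi edges are traversable in both directions. Implemented
#' Brandes-style with subset accumulation so that path endpoints receive
#' no credit for paths they terminate. Vertices on no shortest path
#' score 0 and share tied ranks at the end of the list.
#'
#' @param network a `netpert_network`.
#' @param drivers,responses source and target sets; default to the
#'   network's.
#' @return A `netpert_bc` tibble with columns `gene`, `bc_score`,
#'   `on_path` (whether the vertex carries any shortest-path credit)
#'   and `rank` (average ranks on ties).
#' @export
betweenness_subset <- function(network, drivers = network$drivers,
                               responses = network$responses) {
  stopifnot(inherits(network, "netpert_network"))
  n <- length(network$vertices)
  d_idx <- vertex_index(network, drivers)
  r_idx <- vertex_index(network, responses)
  succ <- successor_list(network$activation)
  score <- numeric(n)
  is_target <- rep(FALSE, n)
  is_target[r_idx] <- TRUE

  for (s in d_idx) {
    # BFS from s: sigma = shortest-path counts, preds = predecessor lists
    dist <- rep(NA_integer_, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    order_visited <- integer(0)
    dist[s] <- 0L
    sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0L) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in succ[[v]]) {
          if (is.na(dist[w])) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (!is.na(dist[w]) && dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    # accumulate pair dependencies for targets in R, interior credit only
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      credit <- delta[w] + if (is_target[w] && w != s) 1 else 0
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * credit
      }
    }
    delta[s] <- 0
    score <- score + delta
  }

  out <- tibble::tibble(
    gene = network$vertices,
    bc_score = score,
    on_path = score > 0,
    rank = rank_weights(score)
  )
  out <- dplyr::arrange(out, .data$rank, .data$gene)
  structure(out, class = c("netpert_bc", class(out)))
}

#' Tied diffusion (TieDIE) linking scores
#'
#' Re-implementation of the tied diffusion comparison method with the
#' heat-kernel relevance function. A forward diffusion from the driver
#' (initial score 1 on the driver) runs under `exp[(A - D) t']`; a
#' backward diffusion from the response genes (initial score `1/|R|`
#' each) runs under the reversed operator `exp[(A^T - U) t']` with
#' `u_i = sum_j a_ij`. The linking score is the elementwise minimum of
#' the two relevance vectors. The total diffusion time `2 t'` is
#' identified with the response time `t`, so the branch time is
#' `t' = t/2`. All vertices are scored; no threshold or edge filter is
#' applied because neither affects the linking scores.
#'
#' @param network a `netpert_network`.
#' @param t response time; defaults to the relaxation time `tau_r`.
#' @param r escaped-density fraction used when `t` is not given.
#' @param drivers single driver symbol; multiple drivers are not
#'   supported by this baseline (collapse them first with
#'   [add_super_source()]).
#' @param responses response set; defaults to the network's.
#' @return A `netpert_tiedie` tibble with columns `gene`, `forward`,
#'   `backward`, `linking` and `rank`; attribute `branch_time` records
#'   `t'`.
#' @export
tiedie_scores <- function(network, t = NULL, r = 0.5,
                          drivers = network$drivers,
                          responses = network$responses) {
  stopifnot(inherits(network, "netpert_network"))
  if (length(drivers) != 1L) {
    stop("tiedie_scores supports a single driver; collapse multiple drivers ",
         "with add_super_source() first")
  }
  if (is.null(t)) t <- relaxation_time(network, r, drivers = drivers)$tau
  if (t < 0) stop("response time must be nonnegative")
  t_branch <- t / 2
  n <- length(network$vertices)
  d_idx <- vertex_index(network, drivers)
  r_idx <- vertex_index(network, responses)

  H <- time_evolution_operator(network)
  x0 <- numeric(n); x0[d_idx] <- 1
  forward <- as.numeric(as.matrix(Matrix::expm(H * t_branch)) %*% x0)

  A <- network$activation
  u <- Matrix::rowSums(A)
  H_rev <- Matrix::t(A) - Matrix::Diagonal(x = u)
  y0 <- numeric(n); y0[r_idx] <- 1 / length(r_idx)
  backward <- as.numeric(as.matrix(Matrix::expm(H_rev * t_branch)) %*% y0)

  linking <- pmin(forward, backward)
  out <- tibble::tibble(
    gene = network$vertices,
    forward = forward,
    backward = backward,
    linking = linking,
    rank = rank_weights(linking)
  )
  out <- dplyr::arrange(out, .data$rank, .data$gene)
  structure(out, class = c("netpert_tiedie", class(out)),
            branch_time = t_branch, t = t)
}

#' Short-time analytic weights (length-2 path counts)
#'
#' In the short-time limit the perturbation weight of vertex `k` is
#' `(t^3/6) * sum_{i in R, i != k} sum_{j in D, j != k} a_ik a_kj + O(t^4)`:
#' the coefficient counts endpoint-excluding length-2 driver-to-response
#' paths through `k`. Vertices only on longer paths have counts 0 here
#' (their leading order is `t^4` or higher) but still receive nonzero
#' weight from [netpert_weights()] at finite `t`.
#'
#' @param network a `netpert_network`.
#' @param drivers,responses vertex sets; default to the network's.
#' @return A tibble with columns `gene`, `path2_count` and `rank`.
#' @export
short_time_weights <- function(network, drivers = network$drivers,
                               responses = network$responses) {
  stopifnot(inherits(network, "netpert_network"))
  A <- network$activation
  n <- length(network$vertices)
  d_idx <- vertex_index(network, drivers)
  r_idx <- vertex_index(network, responses)

  # responses i != k with a_ik = 1, drivers j != k with a_kj = 1
  # (the i = k and j = k terms vanish because the diagonal of A is zero)
  into_r <- Matrix::colSums(A[r_idx, , drop = FALSE])
  from_d <- Matrix::rowSums(A[, d_idx, drop = FALSE])
  counts <- into_r * from_d

  out <- tibble::tibble(
    gene = network$vertices,
    path2_count = as.numeric(counts),
    rank = rank_weights(as.numeric(counts))
  )
  dplyr::arrange(out, .data$rank, .data$gene)
}
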