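#' Sensitivity of one Green's-function element to a vertex perturbation
#'
#' The sensitivity `s_k;ij(t)` is the first derivative of `g_ij(t)` with
#' respect to a diagonal perturbation of the time-evolution operator at
#' vertex `k`. It equals the convolution
#' `integral_0^t g_ik(t - t') g_kj(t') dt'`,
#' approximated here by the composite trapezoid rule on `n_t + 1`
#' equally spaced nodes built from one base-step matrix exponential
#' (see [propagator_grid()]). The quadrature error decreases as
#' `O(n_t^-2)`.
#'
#' @param network a `netpert_network`.
#' @param k perturbed vertex (symbol or index).
#' @param i,j response and source vertices (symbol or index).
#' @param t response time, nonnegative.
#' @param n_t number of quadrature intervals.
#' @return Scalar sensitivity value.
#' @export
sensitivity <- function(network, k, i, j, t, n_t = 64) {
  k <- as_vertex(network, k)
  i <- as_vertex(network, i)
  j <- as_vertex(network, j)
  grid <- propagator_grid(network, t, n_t)
  dt <- t / n_t
  vals <- vapply(0:n_t, function(p) {
    grid[[n_t - p + 1L]][i, k] * grid[[p + 1L]][k, j]
  }, numeric(1))
  trapezoid_sum(vals, dt)
}

as_vertex <- function(network, v) {
  if (is.character(v)) vertex_index(network, v) else as.integer(v)
}

trapezoid_sum <- function(vals, dt) {
  w <- rep(1, length(vals))
  w[1] <- 0.5
  w[length(vals)] <- 0.5
  dt * sum(w * vals)
}

#' Per-vertex perturbation weights over driver-response pairs
#'
#' The weight of vertex `k` at response time `t` sums the sensitivities
#' `s_k;ij(t)` over all response genes `i` and drivers `j`. By default
#' self-terms with `i = k` or `j = k` are excluded, which removes the
#' strong bias that otherwise pushes driver and response genes to the
#' top of the ranking; `include_endpoints = TRUE` keeps them (the
#' endpoints variant). For vertices that are neither drivers nor
#' responses the two variants coincide.
#'
#' The double sum factorizes through forward vectors
#' `f(t') = G(t') chi_D` and backward vectors `b(t - t') = G(t - t')^T chi_R`,
#' with the excluded self-terms subtracted explicitly for `k` in the
#' driver or response set; the trapezoid quadrature then integrates
#' `b_k(t - t') f_k(t')` over the grid. With endpoint exclusion the
#' integrand vanishes at `t' = 0` and `t' = t` (the identity propagator
#' contributes only excluded diagonal terms), so `n_t = 2` collapses to
#' a single midpoint evaluation.
#'
#' @param network a `netpert_network`.
#' @param t response time; defaults to the relaxation time `tau_r`.
#' @param r escaped-density fraction used when `t` is not given.
#' @param n_t number of quadrature intervals (default 2).
#' @param include_endpoints keep self-terms with `i = k` or `j = k`.
#' @param drivers,responses vertex sets; default to the network's.
#' @return A `netpert_weights` tibble with columns `gene`, `weight`,
#'   `log10_weight` (NA where the weight is not positive) and `rank`
#'   (1 = largest weight, average ranks on ties), ordered by rank then
#'   symbol. Attributes record `t`, `r`, `n_t` and `include_endpoints`.
#' @examples
#' net <- make_motif("chain3")
#' netpert_weights(net, t = 1, n_t = 64)
#' @export
netpert_weights <- function(network, t = NULL, r = 0.5, n_t = 2,
                            include_endpoints = FALSE,
                            drivers = network$drivers,
                            responses = network$responses) {
  stopifnot(inherits(network, "netpert_network"))
  if (length(drivers) == 0L || length(responses) == 0L) {
    stop("drivers and responses must be nonempty")
  }
  if (is.null(t)) t <- relaxation_time(network, r, drivers = drivers)$tau
  if (t < 0) stop("response time must be nonnegative")
  d_idx <- vertex_index(network, drivers)
  r_idx <- vertex_index(network, responses)
  n <- length(network$vertices)

  grid <- propagator_grid(network, t, n_t)
  dt <- t / n_t
  chi_d <- numeric(n); chi_d[d_idx] <- 1
  chi_r <- numeric(n); chi_r[r_idx] <- 1
  in_d <- chi_d > 0
  in_r <- chi_r > 0

  integrand <- matrix(0, nrow = n, ncol = n_t + 1L)
  for (p in 0:n_t) {
    Gf <- grid[[p + 1L]]          # G(p dt)
    Gb <- grid[[n_t - p + 1L]]    # G(t - p dt)
    fwd <- as.numeric(Gf %*% chi_d)     # sum_j g_kj(t')
    bwd <- as.numeric(crossprod(Gb, chi_r))  # sum_i g_ik(t - t')
    if (!include_endpoints) {
      fwd[in_d] <- fwd[in_d] - diag(Gf)[in_d]
      bwd[in_r] <- bwd[in_r] - diag(Gb)[in_r]
    }
    integrand[, p + 1L] <- bwd * fwd
  }
  w <- rep(1, n_t + 1L)
  w[c(1L, n_t + 1L)] <- 0.5
  weights <- as.numeric(integrand %*% w) * dt

  out <- tibble::tibble(
    gene = network$vertices,
    weight = weights,
    log10_weight = ifelse(weights > 0, log10(weights), NA_real_),
    rank = rank_weights(weights)
  )
  out <- dplyr::arrange(out, .data$rank, .data$gene)
  structure(out,
            class = c("netpert_weights", class(out)),
            t = t, r = r, n_t = n_t,
            include_endpoints = include_endpoints)
}

#' Rank scores in descending order with average ties
#'
#' Rank 1 is the largest score; tied scores receive the average of the
#' ranks they span, the convention assumed by Spearman correlation.
#'
#' @param weights numeric vector (names preserved).
#' @return Numeric rank vector.
#' @examples
#' rank_weights(c(3, 1, 2))   # 1 3 2
#' rank_weights(c(2, 2, 1))   # 1.5 1.5 3
#' @export
rank_weights <- function(weights) {
  if (any(!is.finite(weights))) stop("weights must be finite")
  rank(-weights, ties.method = "average")
}

#' @method glance netpert_weights
#' @export
glance.netpert_weights <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x),
    t = attr(x, "t"),
    r = attr(x, "r"),
    n_t = attr(x, "n_t"),
    include_endpoints = attr(x, "include_endpoints"),
    max_weight = max(x$weight),
    n_zero_weight = sum(x$weight <= 0)
  )
}
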