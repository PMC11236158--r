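#' Time evolution operator of the network dynamics
#'
#' Returns `H = A - D` where `A` is the activation matrix (unit rates)
#' and `D = diag(d_j)` the decay matrix with `d_j = sum_i a_ij`, i.e. the
#' negative graph Laplacian of the directed network. Every column of `H`
#' sums to zero, so the dynamics conserve total density and `x_i(t)` can
#' be read as the occupation probability of a continuous-time random
#' walker.
#'
#' With `normalized = TRUE` the operator is `A D^{-1} - I` instead, where
#' each vertex forwards density at total rate 1 split across its targets.
#' The unnormalized form is the default: reaction rates are more
#' plausibly per-reaction than per-target, and the unnormalized
#' stationary state is uniform rather than degree-biased. Vertices with
#' out-degree zero are left decay-free in both forms so density is
#' conserved.
#'
#' @param network a `netpert_network`.
#' @param normalized use the degree-normalized operator (comparison only).
#' @return A sparse square matrix with zero column sums.
#' @export
time_evolution_operator <- function(network, normalized = FALSE) {
  stopifnot(inherits(network, "netpert_network"))
  A <- network$activation
  d <- network$out_degree
  if (normalized) {
    inv <- ifelse(d > 0, 1 / d, 0)
    A %*% Matrix::Diagonal(x = inv) - Matrix::Diagonal(x = as.numeric(d > 0))
  } else {
    A - Matrix::Diagonal(x = d)
  }
}

#' Green's function (propagator) of the network dynamics
#'
#' Computes `G(t) = exp(Ht)` by matrix exponential. Entry `g_ij(t)` is
#' the density at vertex `i` at time `t` given a unit of density at `j`
#' at time 0; it is also the linear response of `x_i(t)` to a change in
#' `x_j(0)`. Columns of `G(t)` sum to 1 (conservation) and all entries
#' are nonnegative up to numerical tolerance.
#'
#' @param network a `netpert_network`.
#' @param t nonnegative time.
#' @param normalized passed to [time_evolution_operator()].
#' @return A dense base matrix with vertex dimnames and attribute `time`.
#' @export
propagator <- function(network, t, normalized = FALSE) {
  if (t < 0) stop("propagation time must be nonnegative")
  H <- time_evolution_operator(network, normalized = normalized)
  G <- as.matrix(Matrix::expm(H * t))
  dimnames(G) <- list(network$vertices, network$vertices)
  attr(G, "time") <- t
  G
}

#' Grid of propagators at equally spaced times
#'
#' Builds `G(p t / n_t)` for `p = 0, ..., n_t` from a single matrix
#' exponential of the base step `G(t / n_t)` followed by repeated
#' multiplication, the scheme used for the convolution quadrature.
#'
#' @param network a `netpert_network`.
#' @param t total time, nonnegative.
#' @param n_t number of intervals, at least 1.
#' @return A list of `n_t + 1` dense matrices; element `p + 1` is
#'   `G(p t / n_t)` and element 1 is the identity.
#' @export
propagator_grid <- function(network, t, n_t) {
  if (t < 0) stop("propagation time must be nonnegative")
  n_t <- as.integer(n_t)
  if (n_t < 1L) stop("n_t must be at least 1")
  n <- length(network$vertices)
  base <- propagator(network, t / n_t)
  grid <- vector("list", n_t + 1L)
  grid[[1L]] <- diag(n)
  dimnames(grid[[1L]]) <- list(network$vertices, network$vertices)
  for (p in seq_len(n_t)) {
    grid[[p + 1L]] <- if (p == 1L) base else grid[[p]] %*% base
    attr(grid[[p + 1L]], "time") <- p * t / n_t
  }
  attr(grid[[1L]], "time") <- 0
  grid
}

#' Relaxation time for a requested escaped-density fraction
#'
#' The relaxation time `tau_r` is the first time at which a fraction `r`
#' of the density initially placed on the driver(s) has escaped to the
#' rest of the network. For a single driver with out-degree `d_i` the
#' non-returning approximation gives the closed form
#' `tau_r = -(1/d_i) log(1 - r)`; with `r = 1/2`, `tau = log(2)/d_i`.
#' For multiple drivers (density `1/|D|` on each) the exact retained
#' density `1 - escaped_density(t)` is inverted numerically.
#'
#' @param network a `netpert_network`.
#' @param r escaped-density fraction in `[0, 1)`.
#' @param drivers driver symbols; defaults to the network's drivers.
#' @param exact force numeric inversion of the exact Green's-function
#'   density even for a single driver.
#' @return A one-row tibble with columns `r`, `tau`, `driver_out_degree`
#'   (NA when more than one driver) and `method`
#'   (`"non_returning"` or `"exact"`).
#' @export
relaxation_time <- function(network, r = 0.5, drivers = network$drivers,
                            exact = FALSE) {
  stopifnot(inherits(network, "netpert_network"))
  if (r < 0 || r >= 1) stop("r must be in [0, 1)")
  d_idx <- vertex_index(network, drivers)
  if (r == 0) {
    return(tibble::tibble(
      r = 0, tau = 0,
      driver_out_degree = if (length(d_idx) == 1L) unname(network$out_degree[d_idx]) else NA_real_,
      method = "exact"
    ))
  }
  if (length(d_idx) == 1L && !exact) {
    d_i <- unname(network$out_degree[d_idx])
    if (d_i == 0) stop("driver has out-degree 0: density can never escape")
    return(tibble::tibble(
      r = r, tau = -log(1 - r) / d_i,
      driver_out_degree = d_i, method = "non_returning"
    ))
  }
  if (all(network$out_degree[d_idx] == 0)) {
    stop("driver set has no outgoing edges: density can never escape")
  }
  f <- function(t) escaped_density(network, t, drivers = drivers) - r
  upper <- 1
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 2
  if (f(upper) < 0) stop("requested escaped density r = ", r, " is not reachable")
  root <- stats::uniroot(f, lower = 0, upper = upper, tol = 1e-12)
  tibble::tibble(r = r, tau = root$root,
                 driver_out_degree = NA_real_, method = "exact")
}

#' Fraction of driver density that has escaped by time t
#'
#' With density `1/|D|` placed on each driver at time 0, returns
#' `1 - (1/|D|) * sum_{i,j in D} g_ij(t)` from the exact propagator.
#' This is the diagnostic used to check the non-returning approximation
#' behind [relaxation_time()].
#'
#' @param network a `netpert_network`.
#' @param t time (vectorized).
#' @param drivers driver symbols; defaults to the network's drivers.
#' @return Numeric vector of escaped fractions in `[0, 1]`.
#' @export
escaped_density <- function(network, t, drivers = network$drivers) {
  stopifnot(inherits(network, "netpert_network"))
  if (any(t < 0)) stop("time must be nonnegative")
  d_idx <- vertex_index(network, drivers)
  vapply(t, function(tt) {
    G <- propagator(network, tt)
    1 - sum(G[d_idx, d_idx, drop = FALSE]) / length(d_idx)
  }, numeric(1))
}

#' Total density at the response genes at time t
#'
#' Drivers are initialized with density `1/|D|` each; the result is the
#' sum over response vertices of `G(t) x(0)`. On large networks this
#' typically rises as density washes over the responses and then falls
#' as it randomizes over all vertices.
#'
#' @param network a `netpert_network`.
#' @param t time (vectorized).
#' @param drivers,responses vertex sets; default to the network's.
#' @return Numeric vector of response-gene densities.
#' @export
response_density <- function(network, t, drivers = network$drivers,
                             responses = network$responses) {
  stopifnot(inherits(network, "netpert_network"))
  if (any(t < 0)) stop("time must be nonnegative")
  d_idx <- vertex_index(network, drivers)
  r_idx <- vertex_index(network, responses)
  x0 <- numeric(length(network$vertices))
  x0[d_idx] <- 1 / length(d_idx)
  vapply(t, function(tt) {
    G <- propagator(network, tt)
    sum((G %*% x0)[r_idx])
  }, numeric(1))
}

#' Escaped- and response-density diagnostics over a time grid
#'
#' Convenience wrapper evaluating [escaped_density()], its non-returning
#' approximation, and [response_density()] on a vector of times, in the
#' shape used for diffusion-time diagnostics.
#'
#' @param network a `netpert_network`.
#' @param times numeric vector of times.
#' @return A tibble with columns `time`, `escaped`, `escaped_approx`
#'   (single driver only, else NA) and `response_density`.
#' @export
density_profile <- function(network, times) {
  d_idx <- vertex_index(network, network$drivers)
  approx <- if (length(d_idx) == 1L && network$out_degree[d_idx] > 0) {
    1 - exp(-unname(network$out_degree[d_idx]) * times)
  } else {
    rep(NA_real_, length(times))
  }
  tibble::tibble(
    time = times,
    escaped = escaped_density(network, times),
    escaped_approx = approx,
    response_density = response_density(network, times)
  )
}

#' Collapse multiple drivers into a single super-source vertex
#'
#' Adds a new vertex with a fast directed edge to each driver, so that
#' pipelines restricted to a single driver can still be applied to a
#' driver set. The source-to-driver rate is large relative to network
#' rates so the injection delay is negligible compared to other network
#' timescales.
#'
#' @param network a `netpert_network` with one or more drivers.
#' @param rate activation rate of each source-to-driver edge; default
#'   `1000 * max(out_degree)`.
#' @param name symbol for the new vertex.
#' @return A new `netpert_network` whose single driver is the
#'   super-source.
#' @export
add_super_source <- function(network, rate = NULL, name = ".SOURCE") {
  stopifnot(inherits(network, "netpert_network"))
  if (name %in% network$vertices) stop("vertex ", name, " already exists")
  if (is.null(rate)) rate <- 1000 * max(network$out_degree)
  vertices <- c(network$vertices, name)
  n <- length(vertices)
  At <- methods::as(network$activation, "TsparseMatrix")
  d_idx <- vertex_index(network, network$drivers)
  activation <- Matrix::sparseMatrix(
    i = c(At@i + 1L, d_idx),
    j = c(At@j + 1L, rep(n, length(d_idx))),
    x = c(At@x, rep(rate, length(d_idx))),
    dims = c(n, n), dimnames = list(vertices, vertices)
  )
  out_degree <- Matrix::colSums(activation)
  names(out_degree) <- vertices
  structure(
    list(vertices = vertices, activation = activation,
         out_degree = out_degree, drivers = name,
         responses = network$responses,
         dropped_responses = network$dropped_responses),
    class = "netpert_network"
  )
}
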