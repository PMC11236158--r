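# Closed forms and brute-force oracles used across the test files.
# The oracles are kept independent of the package's computational paths:
# they use direct matrix exponentials, exhaustive path enumeration via
# igraph, and definitional double sums.

# chain3 motif (D -> k -> R, unit rates): closed-form Green's functions
# from solving the 3x3 linear system, and the sensitivity s_k;RD(t)
# obtained by integrating the exact convolution.
chain3_g_DD <- function(t) exp(-t)
chain3_g_kD <- function(t) t * exp(-t)
chain3_g_RD <- function(t) 1 - exp(-t) - t * exp(-t)
chain3_s_kRD <- function(t) 1 - exp(-t) * (1 + t + t^2 / 2)

# direct matrix exponential, independent of propagator(): uses the
# eigen/scaling route of Matrix::expm on a freshly built dense operator
direct_expm <- function(network, t) {
  A <- as.matrix(network$activation)
  H <- A - diag(colSums(A))
  as.matrix(Matrix::expm(Matrix::Matrix(H * t)))
}

# igraph view of the directed activation structure (edge j -> i for
# a_ij = 1), for path-enumeration oracles
as_igraph <- function(network) {
  edges <- tidy(network)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = network$vertices)
}

# brute-force subset betweenness: enumerate every shortest path for
# every driver-response pair and count interior memberships
brute_force_bc <- function(network) {
  g <- as_igraph(network)
  score <- setNames(numeric(length(network$vertices)), network$vertices)
  for (d in network$drivers) {
    for (r in network$responses) {
      if (d == r) next
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = d, to = r, mode = "out")$vpaths
      )
      if (length(paths) == 0L) next
      sigma <- length(paths)
      for (p in paths) {
        interior <- setdiff(names(p), c(d, r))
        score[interior] <- score[interior] + 1 / sigma
      }
    }
  }
  score
}

# exhaustive simple-path enumeration for length-2 / length-3 membership
brute_force_path_membership <- function(network) {
  g <- as_igraph(network)
  n <- length(network$vertices)
  on2 <- setNames(rep(FALSE, n), network$vertices)
  on3 <- setNames(rep(FALSE, n), network$vertices)
  for (d in network$drivers) {
    for (r in network$responses) {
      paths <- igraph::all_simple_paths(g, from = d, to = r,
                                        mode = "out", cutoff = 3)
      for (p in paths) {
        len <- length(p) - 1L
        interior <- setdiff(names(p), c(d, r))
        if (len == 2L) on2[interior] <- TRUE
        if (len == 3L) on3[interior] <- TRUE
      }
    }
  }
  list(on2 = on2, on3 = on3)
}

# definitional perturbation weight: double sum of scalar sensitivities
definitional_weight <- function(network, k, t, n_t, include_endpoints = FALSE) {
  total <- 0
  k_sym <- if (is.character(k)) k else network$vertices[k]
  for (i in network$responses) {
    for (j in network$drivers) {
      if (!include_endpoints && (i == k_sym || j == k_sym)) next
      total <- total + sensitivity(network, k_sym, i, j, t, n_t)
    }
  }
  total
}

# full sensitivity matrix by trapezoid convolution of grid propagators
# (matrix analogue of sensitivity(); used against the FD oracle)
conv_sensitivity_matrix <- function(network, k, t, n_t) {
  k <- if (is.character(k)) match(k, network$vertices) else k
  grid <- propagator_grid(network, t, n_t)
  dt <- t / n_t
  n <- length(network$vertices)
  S <- matrix(0, n, n)
  for (p in 0:n_t) {
    wt <- if (p == 0 || p == n_t) 0.5 else 1
    S <- S + wt * (grid[[n_t - p + 1L]][, k] %o% grid[[p + 1L]][k, ])
  }
  S * dt
}

# one-vertex degenerate network (no edges): g(t) = 1 identically
single_vertex_network <- function(symbol = "X") {
  structure(
    list(
      vertices = symbol,
      activation = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                        x = numeric(0), dims = c(1, 1),
                                        dimnames = list(symbol, symbol)),
      out_degree = setNames(0, symbol),
      drivers = character(0), responses = character(0),
      dropped_responses = character(0)
    ),
    class = "netpert_network"
  )
}

# small seeded random fixture wrapper used by property tests
small_fixture <- function(seed, n = 8, ppi = 7, reg = 4) {
  random_network(n_vertices = n, n_ppi = ppi, n_regulatory = reg,
                 n_drivers = 1, n_responses = 2, seed = seed)$network
}

expect_rank_agreement <- function(rank_a, rank_b, genes) {
  expect_equal(rank_a[order(genes)], rank_b[order(genes)],
               tolerance = 1e-12, ignore_attr = TRUE)
}
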