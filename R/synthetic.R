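#' Small motif networks with known closed forms
#'
#' Deterministic fixtures (at most 10 vertices) used throughout the
#' tests, each with drivers and responses assigned:
#' \describe{
#'   \item{chain3}{`D -> k -> R`, unit rates. Closed forms:
#'     `g_DD = exp(-t)`, `g_kD = t exp(-t)`,
#'     `g_RD = 1 - exp(-t) - t exp(-t)`,
#'     `s_k;RD(t) = 1 - exp(-t)(1 + t + t^2/2)`.}
#'   \item{chain4}{`D -> k1 -> k2 -> R` (leading weight order `t^4`).}
#'   \item{parallel2}{two disjoint length-2 paths `D -> k1 -> R`,
#'     `D -> k2 -> R`.}
#'   \item{dir_motif}{`D -> A` and `A -> R1, R2, R3` (a DIR vertex
#'     feeding three responses).}
#'   \item{diir_motif}{`D -> A -> R` plus `D -> B1 -> B2 -> R`
#'     (A is DIR; B1, B2 are DIIR).}
#'   \item{cluster_klmn}{a densely ppi-connected cluster K, L, M, N fed
#'     by a directed edge `D -> K`, with no directed-respecting route
#'     into the response; the response is reached only through
#'     `D -> A -> R`. The cluster contributes nothing to the response
#'     function despite its connectivity.}
#'   \item{offpath_c}{`D -> A -> R` with `C` attached to `A` by an
#'     undirected ppi edge. C is on no shortest driver-response path
#'     (betweenness 0) but reaches the response through returning
#'     walks, so its perturbation weight is positive.}
#'   \item{disconnected_u}{`D -> A -> R` plus a disconnected ppi pair
#'     `X - Y`; the response list also names an unconnected gene `U`,
#'     which is dropped with a warning when the network is built.}
#' }
#'
#' @param name motif name.
#' @return A `netpert_network` with attribute `motif`.
#' @examples
#' make_motif("chain3")
#' @export
make_motif <- function(name = c("chain3", "chain4", "parallel2", "dir_motif",
                                "diir_motif", "cluster_klmn", "offpath_c",
                                "disconnected_u")) {
  name <- match.arg(name)
  reg <- function(s, t) tibble::tibble(source = s, target = t, kind = "regulatory")
  ppi <- function(s, t) tibble::tibble(source = s, target = t, kind = "ppi")
  spec <- switch(
    name,
    chain3 = list(edges = reg(c("D", "k"), c("k", "R")),
                  drivers = "D", responses = "R"),
    chain4 = list(edges = reg(c("D", "k1", "k2"), c("k1", "k2", "R")),
                  drivers = "D", responses = "R"),
    parallel2 = list(edges = reg(c("D", "D", "k1", "k2"), c("k1", "k2", "R", "R")),
                     drivers = "D", responses = "R"),
    dir_motif = list(edges = reg(c("D", "A", "A", "A"), c("A", "R1", "R2", "R3")),
                     drivers = "D", responses = c("R1", "R2", "R3")),
    diir_motif = list(edges = reg(c("D", "A", "D", "B1", "B2"),
                                  c("A", "R", "B1", "B2", "R")),
                      drivers = "D", responses = "R"),
    cluster_klmn = list(
      edges = dplyr::bind_rows(
        reg(c("D", "A", "D"), c("A", "R", "K")),
        ppi(c("K", "K", "K", "L", "L", "M"),
            c("L", "M", "N", "M", "N", "N"))
      ),
      drivers = "D", responses = "R"
    ),
    offpath_c = list(
      edges = dplyr::bind_rows(reg(c("D", "A"), c("A", "R")), ppi("A", "C")),
      drivers = "D", responses = "R"
    ),
    disconnected_u = list(
      edges = dplyr::bind_rows(reg(c("D", "A"), c("A", "R")), ppi("X", "Y")),
      drivers = "D", responses = c("R", "U")
    )
  )
  net <- build_network(spec$edges, drivers = spec$drivers,
                       responses = spec$responses)
  attr(net, "motif") <- name
  net
}

#' Seeded random driver-response network
#'
#' Generates a synthetic network emulating the shape of real inputs: an
#' undirected ppi backbone with a long-tailed degree distribution
#' (static power-law model, exponent 2.5) plus uniformly random directed
#' regulatory edges, then samples disjoint driver and response sets from
#' connected vertices. The driver is guaranteed at least one outgoing
#' edge. The same seed reproduces the identical edge set.
#'
#' @param n_vertices number of vertices.
#' @param n_ppi number of undirected ppi edges.
#' @param n_regulatory number of directed regulatory edges.
#' @param n_drivers,n_responses sizes of the driver and response sets.
#' @param seed integer seed driving all sampling.
#' @return A list with elements `network` (a `netpert_network`),
#'   `interactions` (the edge tibble) and `spec` (the generating
#'   parameters).
#' @export
random_network <- function(n_vertices = 100, n_ppi = 200, n_regulatory = 60,
                           n_drivers = 1, n_responses = 10, seed = 1) {
  if (n_drivers + n_responses >= n_vertices) {
    stop("driver and response sets must leave at least one intermediate")
  }
  max_ppi <- n_vertices * (n_vertices - 1) / 2
  if (n_ppi > max_ppi) stop("n_ppi exceeds the number of vertex pairs")
  set.seed(seed)
  symbols <- sprintf("G%04d", seq_len(n_vertices))

  g <- igraph::sample_fitness_pl(n_vertices, n_ppi, exponent.out = 2.5)
  ppi_pairs <- igraph::as_edgelist(g, names = FALSE)
  ppi <- tibble::tibble(
    source = symbols[ppi_pairs[, 1]],
    target = symbols[ppi_pairs[, 2]],
    kind = "ppi"
  )

  # uniformly random directed regulator -> target pairs, deduplicated
  reg_pairs <- matrix(integer(0), 0, 2)
  while (nrow(reg_pairs) < n_regulatory) {
    need <- n_regulatory - nrow(reg_pairs)
    cand <- cbind(sample.int(n_vertices, 2 * need + 8, replace = TRUE),
                  sample.int(n_vertices, 2 * need + 8, replace = TRUE))
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
    reg_pairs <- unique(rbind(reg_pairs, cand))
  }
  reg_pairs <- reg_pairs[seq_len(n_regulatory), , drop = FALSE]
  reg <- tibble::tibble(
    source = symbols[reg_pairs[, 1]],
    target = symbols[reg_pairs[, 2]],
    kind = "regulatory"
  )
  interactions <- dplyr::bind_rows(ppi, reg)

  connected <- sort(unique(c(interactions$source, interactions$target)))
  # drivers need an outgoing edge (undirected ppi counts both ways)
  out_ok <- unique(c(interactions$source,
                     interactions$target[interactions$kind == "ppi"]))
  if (length(out_ok) < n_drivers) stop("not enough vertices with outgoing edges")
  drivers <- sample(out_ok, n_drivers)
  responses <- sample(setdiff(connected, drivers), n_responses)

  network <- build_network(interactions, drivers = drivers, responses = responses)
  list(
    network = network,
    interactions = interactions,
    spec = list(n_vertices = n_vertices, n_ppi = n_ppi,
                n_regulatory = n_regulatory, n_drivers = n_drivers,
                n_responses = n_responses, seed = seed)
  )
}

#' Propagator of a diagonally perturbed operator
#'
#' Exact matrix exponential `exp[(H + Lambda) t]` for a diagonal
#' perturbation `Lambda`. `H` and `Lambda` do not commute in general,
#' so this is not `exp(Ht) exp(Lambda t)`; it is the reference object
#' the first-order sensitivities differentiate.
#'
#' @param network a `netpert_network`.
#' @param lambda named numeric vector of diagonal perturbations
#'   (vertices not named get 0).
#' @param t time, nonnegative.
#' @return Dense matrix `exp[(H + Lambda) t]`.
#' @export
perturbed_propagator <- function(network, lambda, t) {
  if (t < 0) stop("time must be nonnegative")
  n <- length(network$vertices)
  lam <- numeric(n)
  if (length(lambda) > 0) {
    if (is.null(names(lambda))) {
      if (length(lambda) != n) stop("unnamed lambda must cover every vertex")
      lam <- as.numeric(lambda)
    } else {
      lam[vertex_index(network, names(lambda))] <- as.numeric(lambda)
    }
  }
  H <- time_evolution_operator(network) + Matrix::Diagonal(x = lam)
  out <- as.matrix(Matrix::expm(H * t))
  dimnames(out) <- list(network$vertices, network$vertices)
  out
}

#' Finite-difference oracle for the sensitivity matrix
#'
#' Central-difference approximation of the derivative of the perturbed
#' propagator with respect to the diagonal perturbation at vertex `k`:
#' `[exp((H + eps 1_kk) t) - exp((H - eps 1_kk) t)] / (2 eps)`.
#' Its truncation error is `O(eps^2)`; the default `eps = 1e-6`
#' balances truncation against round-off on unit-rate networks. Used as
#' an independent check of the convolution-based [sensitivity()].
#'
#' @param network a `netpert_network`.
#' @param k perturbed vertex (symbol or index).
#' @param t time.
#' @param epsilon finite-difference step.
#' @return Dense matrix approximating the sensitivity matrix `S_k(t)`.
#' @export
finite_difference_sensitivity <- function(network, k, t, epsilon = 1e-6) {
  stopifnot(epsilon > 0)
  k <- as_vertex(network, k)
  lam <- stats::setNames(epsilon, network$vertices[k])
  (perturbed_propagator(network, lam, t) -
      perturbed_propagator(network, -lam, t)) / (2 * epsilon)
}

#' Synthetic compound assay table with planted signal
#'
#' Emulates a drug screen against a known ground truth of pathway
#' membership: a vertex is a planted pathway member when it lies on a
#' directed driver-to-response route of total length at most 4 (shortest
#' driver-to-vertex plus vertex-to-response distance), whether or not
#' that route is a shortest path. Members get true inhibition score 20,
#' the driver and responses 36, everything else 100 (% of vehicle
#' control; low = strong inhibition). Membership deliberately includes
#' genes on longer-than-shortest routes, the regime where shortest-path
#' methods tie everything at the end of the list. Compounds draw 1-3
#' targets from the tested vertices; a compound's score is the most
#' potent of its targets' true scores plus Gaussian noise, clamped to
#' `[0, 100]`.
#'
#' @param network a `netpert_network`.
#' @param n_compounds number of compounds.
#' @param n_tested number of distinct testable target vertices.
#' @param noise_sd Gaussian noise added to compound scores.
#' @param seed integer seed.
#' @return A tibble with columns `compound`, `targets` (`;`-separated)
#'   and `score`; attribute `truth` maps each vertex to its true score.
#' @export
synthetic_assay <- function(network, n_compounds = 40, n_tested = 30,
                            noise_sd = 10, seed = 1) {
  stopifnot(inherits(network, "netpert_network"))
  set.seed(seed)
  g <- igraph::graph_from_data_frame(tidy(network), directed = TRUE,
                                     vertices = network$vertices)
  d_from <- suppressWarnings(igraph::distances(
    g, v = network$drivers, to = igraph::V(g), mode = "out"))
  d_to <- suppressWarnings(igraph::distances(
    g, v = network$responses, to = igraph::V(g), mode = "in"))
  path_len <- apply(d_from, 2, min) + apply(d_to, 2, min)
  involvement <- ifelse(is.finite(path_len) & path_len <= 4, 1, 0)
  names(involvement) <- network$vertices
  involvement[c(network$drivers, network$responses)] <- 0.8
  truth <- 100 - 80 * involvement

  n_tested <- min(n_tested, length(network$vertices))
  tested <- sample(network$vertices, n_tested)
  compounds <- purrr::map(seq_len(n_compounds), function(i) {
    targets <- sample(tested, sample(1:3, 1))
    score <- min(truth[targets]) + stats::rnorm(1, sd = noise_sd)
    tibble::tibble(
      compound = sprintf("cmpd%03d", i),
      targets = paste(targets, collapse = ";"),
      score = min(max(score, 0), 100)
    )
  }) |> purrr::list_rbind()
  attr(compounds, "truth") <- truth
  compounds
}
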