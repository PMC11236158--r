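test_that("time evolution operator is activation minus out-degree decay", {
  net <- make_motif("chain3")
  H <- as.matrix(time_evolution_operator(net))
  expect_equal(H["D", "D"], -1)
  expect_equal(H["k", "k"], -1)
  expect_equal(H["R", "R"], 0)
  expect_equal(H["k", "D"], 1)
  expect_equal(H["R", "k"], 1)

  # symmetric two-vertex ppi network
  edges <- tibble::tibble(source = "A", target = "B", kind = "ppi")
  net2 <- build_network(edges, drivers = "A", responses = "B")
  H2 <- as.matrix(time_evolution_operator(net2))
  expect_equal(unname(H2), matrix(c(-1, 1, 1, -1), 2))
})

test_that("columns of H sum to zero for any built network", {
  for (seed in 1:5) {
    net <- small_fixture(seed, n = 12, ppi = 14, reg = 6)
    H <- time_evolution_operator(net)
    expect_lt(max(abs(Matrix::colSums(H))), 1e-12)
    Hn <- time_evolution_operator(net, normalized = TRUE)
    expect_lt(max(abs(Matrix::colSums(Hn))), 1e-12)
  }
})

test_that("propagator matches closed forms and rejects negative times", {
  net <- make_motif("chain3")
  expect_equal(unname(propagator(net, 0)), diag(3), ignore_attr = TRUE)
  G <- propagator(net, 1)
  expect_equal(G["k", "D"], chain3_g_kD(1), tolerance = 1e-12)
  expect_equal(G["D", "D"], chain3_g_DD(1), tolerance = 1e-12)
  expect_equal(G["R", "D"], chain3_g_RD(1), tolerance = 1e-12)
  expect_error(propagator(net, -1), "nonnegative")
})

test_that("propagator satisfies conservation, nonnegativity and semigroup", {
  fixtures <- c(lapply(1:3, small_fixture),
                list(make_motif("cluster_klmn"), make_motif("parallel2")))
  for (net in fixtures) {
    for (t in c(0.3, 1, 4)) {
      G <- propagator(net, t)
      expect_lt(max(abs(colSums(G) - 1)), 1e-9)
      expect_gt(min(G), -1e-12)
    }
    G_half <- propagator(net, 0.5)
    expect_lt(max(abs(propagator(net, 1) - G_half %*% G_half)), 1e-9)
  }
})

test_that("propagator grid equals powers of the base step and the direct exponential", {
  net <- small_fixture(3, n = 15, ppi = 18, reg = 8)
  grid <- propagator_grid(net, t = 2, n_t = 4)
  expect_equal(length(grid), 5L)
  expect_equal(unname(grid[[1]]), diag(length(net$vertices)), ignore_attr = TRUE)
  expect_lt(max(abs(grid[[3]] - propagator(net, 1))), 1e-10)   # midpoint
  expect_lt(max(abs(grid[[5]] - direct_expm(net, 2))), 1e-8)
  g1 <- propagator_grid(net, t = 2, n_t = 1)
  expect_equal(length(g1), 2L)
  expect_lt(max(abs(g1[[2]] - direct_expm(net, 2))), 1e-8)
})

test_that("relaxation time follows the non-returning closed form", {
  net <- make_motif("chain3")
  expect_equal(relaxation_time(net, 0)$tau, 0)
  tau <- relaxation_time(net, 0.5)
  expect_equal(tau$tau, log(2), tolerance = 1e-12)
  expect_equal(tau$driver_out_degree, 1)
  expect_equal(tau$method, "non_returning")

  # driver with out-degree 5
  star <- build_network(
    tibble::tibble(source = "D", target = paste0("k", 1:5), kind = "regulatory"),
    drivers = "D", responses = "k1"
  )
  expect_equal(relaxation_time(star, 0.5)$tau, log(2) / 5, tolerance = 1e-12)
  expect_error(relaxation_time(net, -0.1), "\\[0, 1\\)")

  # strictly increasing in r
  taus <- vapply(c(0.1, 0.3, 0.5, 0.7), function(r) relaxation_time(net, r)$tau,
                 numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("a driver with no outgoing edges cannot relax", {
  edges <- tibble::tibble(source = "X", target = "D", kind = "regulatory")
  net <- build_network(edges, drivers = "D", responses = "X")
  expect_error(relaxation_time(net, 0.5), "out-degree 0")
  expect_equal(relaxation_time(net, 0)$tau, 0)
})

test_that("multi-driver relaxation inverts the exact retained density", {
  res <- random_network(n_vertices = 20, n_ppi = 30, n_regulatory = 8,
                        n_drivers = 3, n_responses = 4, seed = 11)
  net <- res$network
  tau <- relaxation_time(net, 0.4)
  expect_equal(tau$method, "exact")
  expect_equal(escaped_density(net, tau$tau), 0.4, tolerance = 1e-8)
})

test_that("escaped density matches the chain closed form and the uniform limit", {
  net <- make_motif("chain3")
  expect_equal(escaped_density(net, 0), 0)
  # the chain driver has no incoming edges, so g_DD(t) = exp(-t) exactly
  expect_equal(escaped_density(net, log(2)), 0.5, tolerance = 1e-12)

  # connected undirected network: stationary density is uniform
  ring <- build_network(
    tibble::tibble(source = c("a", "b", "c", "d"),
                   target = c("b", "c", "d", "a"), kind = "ppi"),
    drivers = "a", responses = "c"
  )
  expect_equal(escaped_density(ring, 200), 1 - 1 / 4, tolerance = 1e-9)
})

test_that("response density follows the chain closed form and can be non-monotone", {
  net <- make_motif("chain3")
  expect_equal(response_density(net, 0), 0)
  for (t in c(0.5, 1, 2)) {
    expect_equal(response_density(net, t), chain3_g_RD(t), tolerance = 1e-12)
  }
  # on the chain, R is absorbing: monotone rise
  ts <- seq(0, 5, by = 0.5)
  expect_true(all(diff(response_density(net, ts)) > 0))

  # on a directed 4-cycle the response density overshoots its stationary value
  cyc <- build_network(
    tibble::tibble(source = c("D", "a", "b", "c"),
                   target = c("a", "b", "c", "D"), kind = "regulatory"),
    drivers = "D", responses = "b"
  )
  vals <- response_density(cyc, seq(0, 30, length.out = 120))
  expect_gt(max(vals), vals[length(vals)] + 1e-4)
})

test_that("density profile reports the non-returning approximation", {
  net <- make_motif("chain3")
  prof <- density_profile(net, c(0, log(2), 2))
  expect_equal(prof$escaped, prof$escaped_approx, tolerance = 1e-12)
  expect_named(prof, c("time", "escaped", "escaped_approx", "response_density"))
})

test_that("super-source transform injects density into the former drivers", {
  res <- random_network(n_vertices = 15, n_ppi = 20, n_regulatory = 6,
                        n_drivers = 2, n_responses = 3, seed = 7)
  net <- res$network
  aug <- add_super_source(net)
  expect_equal(length(aug$drivers), 1L)
  expect_equal(length(aug$vertices), length(net$vertices) + 1L)
  # almost all density reaches the former drivers essentially instantly
  G <- propagator(aug, 1e-3)
  d_idx <- match(net$drivers, aug$vertices)
  s_idx <- match(aug$drivers, aug$vertices)
  expect_gt(sum(G[d_idx, s_idx]), 0.9)
  # conservation still holds with the non-unit rates
  expect_lt(max(abs(colSums(propagator(aug, 0.5)) - 1)), 1e-9)
})

test_that("normalized dynamics conserve density but bias the stationary state", {
  # star ppi: hub h attached to 3 leaves; unnormalized stationary is uniform
  star <- build_network(
    tibble::tibble(source = "h", target = c("l1", "l2", "l3"), kind = "ppi"),
    drivers = "h", responses = "l1"
  )
  Gn <- as.matrix(Matrix::expm(time_evolution_operator(star, normalized = TRUE) * 300))
  expect_lt(max(abs(colSums(Gn) - 1)), 1e-9)
  h <- match("h", star$vertices)
  # degree-proportional stationary density: hub holds 3/6 of the mass
  expect_equal(unname(Gn[h, h]), 0.5, tolerance = 1e-6)
  Gu <- propagator(star, 300)
  expect_equal(unname(Gu[h, h]), 0.25, tolerance = 1e-6)
})
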