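test_that("subset betweenness credits interior vertices of shortest paths", {
  chain <- make_motif("chain3")
  b <- betweenness_subset(chain)
  expect_equal(b$bc_score[b$gene == "k"], 1)
  expect_equal(b$bc_score[b$gene %in% c("D", "R")], c(0, 0))

  par2 <- make_motif("parallel2")
  bp <- betweenness_subset(par2)
  expect_equal(bp$bc_score[bp$gene == "k1"], 0.5)
  expect_equal(bp$bc_score[bp$gene == "k2"], 0.5)
})

test_that("off-shortest-path genes score zero and share tied last ranks", {
  net <- make_motif("offpath_c")
  b <- betweenness_subset(net)
  expect_equal(b$bc_score[b$gene == "C"], 0)
  expect_false(b$on_path[b$gene == "C"])
  zero_ranks <- b$rank[b$bc_score == 0]
  expect_equal(length(unique(zero_ranks)), 1L)  # all tied
  expect_equal(unique(zero_ranks), mean(2:4))   # average of the last ranks
  # NetPert still gives C a positive weight through returning walks
  w <- netpert_weights(net, t = 1, n_t = 16)
  expect_gt(w$weight[w$gene == "C"], 0)
})

test_that("betweenness equals brute-force shortest-path enumeration", {
  fixtures <- c(
    lapply(c(1, 2, 6, 13), function(s) small_fixture(s, n = 9, ppi = 10, reg = 5)),
    list(make_motif("diir_motif"), make_motif("cluster_klmn"),
         make_motif("parallel2"))
  )
  for (net in fixtures) {
    b <- betweenness_subset(net)
    oracle <- brute_force_bc(net)
    expect_equal(setNames(b$bc_score, b$gene)[names(oracle)], oracle,
                 tolerance = 1e-12)
  }
})

test_that("tied diffusion matches closed-form branch exponentials on the chain", {
  net <- make_motif("chain3")
  z <- tiedie_scores(net, t = 1)
  expect_equal(attr(z, "branch_time"), 0.5)
  # forward branch at t' = 1/2: g_kD(1/2) = (1/2) exp(-1/2)
  expect_equal(z$forward[z$gene == "k"], 0.5 * exp(-0.5), tolerance = 1e-12)
  # reversed operator on the chain mirrors the forward one
  expect_equal(z$backward[z$gene == "k"], 0.5 * exp(-0.5), tolerance = 1e-12)
  expect_equal(z$linking[z$gene == "k"], 0.5 * exp(-0.5), tolerance = 1e-12)
  expect_true(all(z$linking <= z$forward + 1e-15))
  expect_true(all(z$linking <= z$backward + 1e-15))
})

test_that("vertices unreachable from the driver have zero linking score", {
  suppressWarnings(net <- make_motif("disconnected_u"))
  z <- tiedie_scores(net, t = 1)
  expect_equal(z$linking[z$gene %in% c("X", "Y")], c(0, 0))
})

test_that("linking scores are invariant to unreachable vertices", {
  core <- build_network(
    tibble::tibble(source = c("D", "A"), target = c("A", "R"),
                   kind = "regulatory"),
    drivers = "D", responses = "R"
  )
  suppressWarnings(padded <- make_motif("disconnected_u"))
  z_core <- tiedie_scores(core, t = 1)
  z_pad <- tiedie_scores(padded, t = 1)
  merged <- dplyr::inner_join(z_core, z_pad, by = "gene",
                              suffix = c("_core", "_pad"))
  expect_equal(merged$linking_core, merged$linking_pad, tolerance = 1e-12)
})

test_that("tied diffusion requires a single driver", {
  res <- random_network(n_vertices = 12, n_ppi = 16, n_regulatory = 5,
                        n_drivers = 2, n_responses = 3, seed = 2)
  expect_error(tiedie_scores(res$network, t = 1), "single driver")
})

test_that("short-time linking approaches min(a_kD t, |R|^-1 sum a_ik t)", {
  net <- make_motif("dir_motif")
  t <- 1e-4
  z <- tiedie_scores(net, t = 2 * t)  # branch time t
  a_kD <- 1
  expected_A <- min(a_kD * t, 3 / 3 * t)
  expect_equal(z$linking[z$gene == "A"], expected_A, tolerance = 1e-4)
})

test_that("short-time weights count endpoint-excluding length-2 paths", {
  expect_equal(
    short_time_weights(make_motif("chain3"))$path2_count[
      short_time_weights(make_motif("chain3"))$gene == "k"], 1)
  st <- short_time_weights(make_motif("dir_motif"))
  expect_equal(st$path2_count[st$gene == "A"], 3)
  st4 <- short_time_weights(make_motif("chain4"))
  expect_equal(st4$path2_count[st4$gene %in% c("k1", "k2")], c(0, 0))
})

test_that("DIR intermediates rank identically under the three short-time views", {
  # fan motif with distinct length-2 path counts: A feeds 3 responses,
  # B feeds 2, C feeds 1 -> counts 3 > 2 > 1, no ties
  fan <- build_network(
    tibble::tibble(
      source = c("D", "D", "D", "A", "A", "A", "B", "B", "C"),
      target = c("A", "B", "C", "R1", "R2", "R3", "R1", "R2", "R1"),
      kind = "regulatory"
    ),
    drivers = "D", responses = c("R1", "R2", "R3")
  )
  dir_genes <- c("A", "B", "C")
  t <- 1e-3
  w <- netpert_weights(fan, t = t, n_t = 8)
  st <- short_time_weights(fan)
  z <- tiedie_scores(fan, t = t)
  w_dir <- setNames(w$weight, w$gene)[dir_genes]
  st_dir <- setNames(st$path2_count, st$gene)[dir_genes]
  z_dir <- setNames(z$linking, z$gene)[dir_genes]
  expect_equal(st_dir, c(A = 3, B = 2, C = 1))
  expect_equal(rank_weights(w_dir), rank_weights(st_dir))
  expect_equal(rank_weights(z_dir), rank_weights(st_dir))
})

test_that("short-time ordering respects path counts pairwise on random fixtures", {
  # DIR genes with strictly larger length-2 path counts must outrank
  # those with smaller counts at small t (equal counts may tie-break
  # either way through higher-order path terms)
  compared <- 0L
  for (seed in c(7, 20, 36)) {
    net <- small_fixture(seed, n = 14, ppi = 20, reg = 8)
    cats <- categorize(net)
    dir_genes <- cats$gene[cats$category == "DIR"]
    t <- 1e-3
    w <- setNames(netpert_weights(net, t = t, n_t = 8)$weight,
                  netpert_weights(net, t = t, n_t = 8)$gene)[dir_genes]
    st <- short_time_weights(net)
    counts <- setNames(st$path2_count, st$gene)[dir_genes]
    z <- setNames(tiedie_scores(net, t = t)$linking,
                  tiedie_scores(net, t = t)$gene)[dir_genes]
    for (a in dir_genes) {
      for (b in dir_genes) {
        if (counts[a] > counts[b]) {
          compared <- compared + 1L
          expect_gt(w[a], w[b])
          expect_gt(z[a], z[b])
        }
      }
    }
  }
  expect_gte(compared, 1L)
})

test_that("the highly connected cluster contributes nothing to the response", {
  net <- make_motif("cluster_klmn")
  w <- netpert_weights(net, t = 1, n_t = 16)
  cluster <- c("K", "L", "M", "N")
  # no directed-respecting route from the cluster interior into R
  expect_equal(unname(setNames(w$weight, w$gene)[cluster]), rep(0, 4))
  expect_gt(w$weight[w$gene == "A"], 0)
})
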