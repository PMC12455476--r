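model <- mpipi_model()

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

test_that("interaction graphs apply the energetic threshold exactly", {
  # pair energy -3.5 kcal/mol at 300 K: edge at m = 5 (threshold ~ -2.98),
  # no edge at m = 10 (threshold ~ -5.96)
  E <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  E[1, 2] <- E[2, 1] <- -3.5
  g5 <- interaction_graph_from_energies(E, m = 5, T = 300)
  g10 <- interaction_graph_from_energies(E, m = 10, T = 300)
  expect_equal(igraph::ecount(g5$graph), 1)
  expect_equal(igraph::ecount(g10$graph), 0)
})

test_that("interaction graph equals the brute-force all-pairs construction", {
  conf <- random_test_config(n_chains = 8, n_beads = 6, box = 45, seed = 13)
  g <- build_interaction_graph(conf, model, T = 300, m = 1)
  kT <- thermal_energy(300)
  ids <- sort(unique(conf$chain))
  adj_oracle <- matrix(0, 8, 8)
  for (a in 1:7) for (b in (a + 1):8) {
    e <- brute_chain_pair_energy(conf, ids[a], ids[b], model)
    adj_oracle[a, b] <- adj_oracle[b, a] <- as.integer(e < -1 * kT)
  }
  expect_equal(unname(igraph::as_adjacency_matrix(g$graph, sparse = FALSE)),
               adj_oracle)
})

test_that("edge count is monotonically non-increasing in the threshold multiple", {
  conf <- random_test_config(n_chains = 10, n_beads = 8, box = 50, seed = 21)
  ms <- c(0.5, 1, 2, 5, 10)
  counts <- vapply(ms, function(m)
    igraph::ecount(build_interaction_graph(conf, model, T = 300, m = m)$graph),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("betweenness matches hand-computable topologies", {
  star <- graph_from_adj(rbind(c(0, 1, 1, 1, 1), c(1, 0, 0, 0, 0),
                               c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0),
                               c(1, 0, 0, 0, 0)))
  b <- betweenness_centrality(star)
  expect_equal(unname(b), c(1, 0, 0, 0, 0))
  path3 <- graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))
  expect_error(betweenness_centrality(graph_from_adj(matrix(0, 2, 2))),
               "at least 3")
})

test_that("betweenness matches exhaustive shortest-path enumeration on random graphs", {
  set.seed(99)
  for (trial in 1:8) {
    n <- sample(5:9, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.4)
    adj <- adj + t(adj)
    b_pkg <- betweenness_centrality(graph_from_adj(adj))
    expect_equal(unname(b_pkg), brute_betweenness(adj), tolerance = 1e-10)
  }
})

test_that("non-normalized betweenness of a path equals the pair-separation count", {
  n <- 7
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
  b <- betweenness_centrality(graph_from_adj(adj)) * choose(n - 1, 2)
  # interior node i separates (i-1) * (n-i) pairs
  expect_equal(unname(b), vapply(1:n, function(i) (i - 1) * (n - i), numeric(1)))
})

test_that("hub selection takes the top centralities with id tie-breaks", {
  star <- graph_from_adj(rbind(c(0, 1, 1, 1, 1), c(1, 0, 0, 0, 0),
                               c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0),
                               c(1, 0, 0, 0, 0)))
  expect_equal(identify_hubs(star, n_h = 1)$hubs, "1")
  # all-equal centralities: lowest ids win
  ring <- graph_from_adj(rbind(c(0, 1, 0, 0, 1), c(1, 0, 1, 0, 0),
                               c(0, 1, 0, 1, 0), c(0, 0, 1, 0, 1),
                               c(1, 0, 0, 1, 0)))
  expect_equal(identify_hubs(ring, n_h = 3)$hubs, c("1", "2", "3"))
  h <- identify_hubs(star, n_h = 10)
  expect_true(h$truncated)
  expect_equal(length(h$hubs), 5)
  # agrees with a sort-then-slice oracle on a random graph
  set.seed(3)
  adj <- matrix(0, 9, 9)
  adj[upper.tri(adj)] <- rbinom(36, 1, 0.5)
  adj <- adj + t(adj)
  g <- graph_from_adj(adj)
  cb <- betweenness_centrality(g)
  oracle <- names(sort(-rank(cb, ties.method = "first")))  # not id-aware; use order
  oracle <- names(cb)[order(-cb, as.numeric(names(cb)))][1:4]
  expect_equal(identify_hubs(g, cb, n_h = 4)$hubs, oracle)
})

test_that("clique reporting follows size order and the overlap rule", {
  # disjoint K5 (nodes 1-5) and K4 (6-9) plus isolated vertices
  adj <- matrix(0, 11, 11)
  adj[1:5, 1:5] <- 1; adj[6:9, 6:9] <- 1
  diag(adj) <- 0
  cl <- identify_cliques(graph_from_adj(adj))
  expect_equal(length(cl$cliques), 2)
  expect_equal(sort(as.integer(cl$cliques[[1]])), 1:5)
  expect_equal(sort(as.integer(cl$cliques[[2]])), 6:9)
  # two K6 sharing exactly 3 vertices: only the first is reported
  adj2 <- matrix(0, 9, 9)
  adj2[1:6, 1:6] <- 1; adj2[4:9, 4:9] <- 1
  diag(adj2) <- 0
  cl2 <- identify_cliques(graph_from_adj(adj2))
  expect_equal(length(cl2$cliques), 1)
  expect_equal(length(cl2$cliques[[1]]), 6)
})

test_that("reported cliques agree with exhaustive enumeration and stay <= max_shared overlapping", {
  set.seed(17)
  for (trial in 1:5) {
    n <- sample(8:12, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.55)
    adj <- adj + t(adj)
    g <- graph_from_adj(adj)
    found <- lapply(igraph::max_cliques(g, min = 3),
                    function(v) sort(as.integer(v)))
    oracle <- lapply(brute_max_cliques(adj, 3), sort)
    keyify <- function(l) sort(vapply(l, paste, "", collapse = ","))
    expect_equal(keyify(found), keyify(oracle))
    cl <- identify_cliques(g, n_c = 5, max_shared = 2)
    if (length(cl$cliques) > 1) {
      for (i in 1:(length(cl$cliques) - 1)) for (j in (i + 1):length(cl$cliques)) {
        expect_lte(length(intersect(cl$cliques[[i]], cl$cliques[[j]])), 2)
      }
    }
  }
})

test_that("the lattice reference preserves degrees and perfects regular rings", {
  rl <- generate_reference_graph("ring_lattice", n = 60, k = 6, seed = 1)
  set.seed(2)
  latt <- lattice_reference(rl)
  expect_equal(sort(igraph::degree(latt)), sort(igraph::degree(rl)))
  expect_equal(igraph::transitivity(latt, type = "localaverage", isolates = "zero"),
               igraph::transitivity(rl, type = "localaverage", isolates = "zero"))
  er <- generate_reference_graph("ER", n = 300, m = 1200, seed = 4)
  set.seed(5)
  latt_er <- lattice_reference(er)
  expect_equal(sort(igraph::degree(latt_er)), sort(igraph::degree(er)))
  # latticization raises clustering far above the random level
  expect_gt(igraph::transitivity(latt_er, type = "localaverage", isolates = "zero"),
            5 * igraph::transitivity(er, type = "localaverage", isolates = "zero"))
})

test_that("small-world estimators hit their family limits", {
  # these use reduced sizes relative to the headline benchmark for speed;
  # the acceptance suite runs the full n = 2000 versions
  er <- generate_reference_graph("ER", n = 1000, m = 4000, seed = 8)
  s_er <- small_world_stats(er, n_ref = 5, seed = 1)
  expect_equal(s_er$sigma, 1, tolerance = 0.25)
  expect_gt(s_er$omega, 0.9)
  rl <- generate_reference_graph("ring_lattice", n = 1000, k = 8, seed = 1)
  s_rl <- small_world_stats(rl, n_ref = 5, seed = 2)
  expect_lt(s_rl$omega, -0.9)
  ws <- generate_reference_graph("watts_strogatz", n = 1000, k = 10, p = 0.1,
                                 seed = 9)
  s_ws <- small_world_stats(ws, n_ref = 5, seed = 3)
  expect_gte(s_ws$omega, -0.3)
  expect_lte(s_ws$omega, 0.3)
  expect_gt(s_ws$sigma, 1)
  # omega ordering: lattice < watts-strogatz < ER
  expect_true(s_rl$omega < s_ws$omega && s_ws$omega < s_er$omega)
})

test_that("small-world stats reject degenerate graphs", {
  tiny <- graph_from_adj(matrix(0, 5, 5))
  expect_error(small_world_stats(tiny), "no edges")
  small <- generate_reference_graph("ring_lattice", n = 8, k = 2, seed = 1)
  expect_error(small_world_stats(small), "fewer than 10")
})
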