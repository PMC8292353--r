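test_that("complete graphs score zero everywhere with a reported argmax tie", {
  g <- k5()
  th <- assign_thresholds(g, "absolute", 2)
  expect_message(cc <- complex_centrality(g, th), "tie")
  expect_equal(as.numeric(cc), rep(0, 5))
  expect_equal(attr(cc, "top"), "1")
})

test_that("a high-degree hub with an edgeless neighbourhood loses to the clique chain", {
  g <- hub_vs_clique_chain()
  th <- assign_thresholds(g, "absolute", 2)
  cc <- complex_centrality(g, th)
  deg <- igraph::degree(g)
  expect_equal(names(which.max(deg)), "hub")
  expect_equal(unname(cc["hub"]), 0)
  chain_nodes <- as.character(1:14)
  expect_gt(max(cc[chain_nodes]), 0)
  expect_true(attr(cc, "top") %in% chain_nodes)
})

test_that("baseline centralities reproduce textbook values on a star", {
  g <- star_graph(5)
  tab <- baseline_centralities(g, measures = c("degree", "k_core",
                                               "betweenness", "eigenvector"))
  expect_equal(tab$degree[tab$node == "c"], 5)
  expect_true(all(tab$degree[tab$node != "c"] == 1))
  expect_true(all(tab$k_core == 1))
  expect_equal(tab$betweenness[tab$node == "c"], choose(5, 2))
  expect_equal(max(tab$eigenvector), tab$eigenvector[tab$node == "c"])
})

test_that("percolation score follows the reduced-degree formula", {
  p <- path_graph(c("a", "b", "c"))
  tab <- baseline_centralities(p, measures = "percolation", d = 1)
  # (deg-1) * sum of (deg-1) at distance exactly 1: all terms vanish
  expect_equal(tab$percolation, c(0, 0, 0))
  p5 <- path_graph(c("a", "b", "c", "d", "e"))
  tab2 <- baseline_centralities(p5, measures = "percolation", d = 1)
  # c: (2-1) * ((deg b - 1) + (deg d - 1)) = 2
  expect_equal(tab2$percolation[tab2$node == "c"], 2)
})

test_that("closeness and reach follow their definitions on a path", {
  p <- path_graph(c("a", "b", "c", "d", "e"))
  tab <- baseline_centralities(p, measures = c("closeness", "reach"),
                               reach_radius = 2)
  expect_equal(tab$closeness[tab$node == "c"], 1 / mean(c(2, 1, 1, 2)))
  expect_equal(tab$reach[tab$node == "a"], 2)  # b and c
  expect_equal(tab$reach[tab$node == "c"], 4)
})

test_that("vertex-transitive graphs give constant scores for every measure", {
  g <- generate_rewired_lattice(12, 4, 0)
  tab <- baseline_centralities(
    g, measures = c("degree", "betweenness", "eigenvector", "k_core",
                    "percolation", "closeness", "reach"), d = 2)
  for (m in setdiff(names(tab), "node")) {
    expect_lt(diff(range(tab[[m]])), 1e-8)
  }
  th <- assign_thresholds(g, "absolute", 2)
  expect_message(cc <- complex_centrality(g, th), "tie")
  expect_lt(diff(range(cc)), 1e-12)
})

test_that("eigenvector centrality on a disconnected graph works per component", {
  g <- graph_from_pairs("a", "b", "b", "c", "x", "y")
  expect_message(tab <- baseline_centralities(g, measures = "eigenvector"),
                 "component")
  expect_true(all(is.finite(tab$eigenvector)))
  expect_gt(tab$eigenvector[tab$node == "b"], tab$eigenvector[tab$node == "a"])
})

test_that("ensemble complex centrality is the mean over threshold regimes", {
  g <- hub_vs_clique_chain(n_cliques = 3, n_leaves = 4)
  single <- vapply(2:3, function(tv) {
    th <- assign_thresholds(g, "absolute", tv)
    unname(suppressMessages(complex_centrality(g, th))[igraph::V(g)$name])
  }, numeric(igraph::vcount(g)))
  ens <- suppressMessages(ensemble_complex_centrality(g, t_values = 2:3))
  expect_equal(unname(ens[igraph::V(g)$name]), rowMeans(single))
  th2 <- assign_thresholds(g, "absolute", 2)
  expect_equal(as.numeric(suppressMessages(ensemble_complex_centrality(g, t_values = 2))),
               as.numeric(suppressMessages(complex_centrality(g, th2))))
})

test_that("T = 1 complex centrality ranks like mean shortest-path closeness", {
  g <- random_connected_graph(30, 0.12, 9)
  th <- assign_thresholds(g, "absolute", 1)
  cc <- complex_centrality(g, th)
  nm <- igraph::V(g)$name
  dmat <- igraph::distances(g)
  oracle <- vapply(nm, function(i) {
    targets <- setdiff(nm, c(i, names(igraph::neighbors(g, i))))
    if (length(targets) == 0) return(0)
    mean(dmat[i, targets] + 1)
  }, numeric(1))
  expect_equal(order(-cc[nm], nm), order(-oracle[nm], nm))
})

test_that("greedy ranking ties on symmetric graphs and reproduces under seed", {
  g <- k5()
  th <- assign_thresholds(g, "absolute", 2)
  expect_message(r1 <- greedy_seed_selection(g, th, budget = 1, trials = 1,
                                             rng_seed = 4), "tie")
  expect_true(all(r1$expected_adoption == 1))
  r2 <- suppressMessages(
    greedy_seed_selection(g, th, budget = 1, trials = 1, rng_seed = 4))
  expect_identical(r1, r2)
})

test_that("greedy ranking prefers the clique chain over the hub at T = 2", {
  g <- hub_vs_clique_chain(n_cliques = 4, n_leaves = 6)
  th <- assign_thresholds(g, "absolute", 2)
  r <- suppressWarnings(suppressMessages(
    greedy_seed_selection(g, th, budget = 1, trials = 2, rng_seed = 1)))
  expect_true(r$node[1] %in% as.character(1:10))
  expect_gt(r$expected_adoption[1],
            r$expected_adoption[r$node == "hub"])
})
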