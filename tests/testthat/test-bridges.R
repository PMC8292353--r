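test_that("complete-graph bridge is the whole vertex set", {
  g <- k5()
  th <- assign_thresholds(g, "absolute", 2)
  br <- bridge_report(g, "1", "2", th)
  expect_setequal(br$overlap, as.character(1:5))
  expect_length(br$disjoint, 0)
  expect_length(br$reinforcement, 0)
  expect_equal(br$width, 5)
  expect_true(br$sufficient)
})

test_that("path-graph bridges match hand enumeration", {
  g <- path_graph(c("a", "b", "c", "d", "e"))
  th2 <- assign_thresholds(g, "absolute", 2)
  br <- bridge_report(g, "b", "d", th2)
  expect_setequal(br$overlap, "c")
  expect_setequal(br$disjoint, c("d", "e"))
  expect_length(br$reinforcement, 0)  # E(N[b]) shares no edge with E(N[d]) or E(N[e])
  expect_equal(br$width, 1)
  expect_false(br$sufficient)
  th1 <- assign_thresholds(g, "absolute", 1)
  expect_true(bridge_report(g, "b", "d", th1)$sufficient)
})

test_that("nodes in different components have an empty bridge", {
  g <- graph_from_pairs("a", "b", "c", "d")
  th <- assign_thresholds(g, "absolute", 1)
  br <- bridge_report(g, "a", "c", th)
  expect_equal(br$width, 0)
  expect_false(br$sufficient)
})

test_that("bridge report rejects identical endpoints", {
  g <- k5()
  th <- assign_thresholds(g, "absolute", 2)
  expect_error(bridge_report(g, "1", "1", th), "distinct")
})

test_that("bridge partners follow the incoming-width definition", {
  th <- function(g) assign_thresholds(g, "absolute", 2)
  g <- k5()
  expect_setequal(bridge_partners(g, "1", th(g)), as.character(2:5))
  p <- path_graph(c("a", "b", "c"))
  expect_setequal(bridge_partners(p, "a", th(p)), c("b", "c"))
  iso <- graph_from_pairs("x", "y")
  iso <- igraph::add_vertices(iso, 1, name = "z")
  expect_length(bridge_partners(iso, "z", th(iso)), 0)
})

test_that("local sufficiency averages the outgoing sufficiency indicators", {
  g <- k5()
  th <- assign_thresholds(g, "absolute", 2)
  expect_equal(local_sufficiency(g, "1", th), 1)
  # path a-b-c at T=2: W_ab = 2 (sufficient), W_ac = 1 (not)
  p <- path_graph(c("a", "b", "c"))
  thp <- assign_thresholds(p, "absolute", 2)
  expect_equal(local_sufficiency(p, "a", thp), 0.5)
})

test_that("graph LB covers the complete and empty extremes", {
  g <- k5()
  th <- assign_thresholds(g, "absolute", 2)
  expect_equal(graph_lb(g, th), 1)
  e <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(e)$name <- as.character(1:4)
  the <- assign_thresholds(e, "absolute", 2)
  expect_equal(graph_lb(e, the), 0)
})

test_that("width decomposes as |O| + |R| and is antitone in the threshold", {
  for (s in 1:10) {
    g <- random_graph(15, 0.2, s)
    nm <- igraph::V(g)$name
    pair <- withr::with_seed(s, sample(nm, 2))
    widths <- vapply(1:4, function(tv) {
      th <- assign_thresholds(g, "absolute", tv)
      br <- bridge_report(g, pair[1], pair[2], th)
      expect_equal(br$width, length(br$overlap) + length(br$reinforcement))
      expect_length(intersect(br$overlap, br$reinforcement), 0)
      br$sufficient
    }, logical(1))
    # sufficiency can only switch off as T grows
    expect_true(all(diff(as.integer(widths)) <= 0))
  }
})

test_that("adjacent pairs always bridge with width at least two", {
  for (s in 1:5) {
    g <- random_connected_graph(12, 0.25, s)
    th <- assign_thresholds(g, "absolute", 2)
    W <- bridge_width_matrix(g, th)
    el <- igraph::as_edgelist(g)
    for (e in seq_len(nrow(el))) {
      expect_gte(W[el[e, 1], el[e, 2]], 2)  # {i, j} subset of O_ij
    }
  }
})

test_that("matrix path and per-pair reports agree, including heterogeneous", {
  for (s in 1:6) {
    g <- random_graph(14, 0.25, s)
    nm <- igraph::V(g)$name
    th <- if (s %% 2 == 0) {
      assign_thresholds(g, "absolute", c(2, 4), rng_seed = s)
    } else {
      assign_thresholds(g, "absolute", 2)
    }
    W <- bridge_width_matrix(g, th)
    pairs <- withr::with_seed(s, replicate(8, sample(nm, 2)))
    for (k in seq_len(ncol(pairs))) {
      br <- bridge_report(g, pairs[1, k], pairs[2, k], th)
      expect_equal(br$width, unname(W[pairs[1, k], pairs[2, k]]))
    }
  }
})

test_that("prose and formal reinforcement variants differ where they should", {
  g <- path_graph(c("a", "b", "c", "d"))
  th <- assign_thresholds(g, "absolute", 2)
  formal <- bridge_report(g, "a", "b", th)
  prose <- bridge_report(g, "a", "b", th, prose_reinforcement = TRUE)
  # c is adjacent to b in N[a] but shares no induced edge with N[a]
  expect_length(formal$reinforcement, 0)
  expect_setequal(prose$reinforcement, "c")
  expect_equal(prose$width, formal$width + 1)
  Wp <- bridge_width_matrix(g, th, prose_reinforcement = TRUE)
  expect_equal(unname(Wp["a", "b"]), prose$width)
})

test_that("heterogeneous filter prunes reinforcement nodes the source cannot activate", {
  # b-c-d triangle reached from a's side: x = d has |O_ad| = 2
  g <- graph_from_pairs("a", "b", "a", "c", "b", "c", "b", "d", "c", "d")
  # give d a high threshold so the filter drops it from R_ab's role in any
  # bridge whose source neighbourhood overlaps it in fewer than teff nodes
  th_lo <- assign_thresholds(g, "absolute", c(2, 2), rng_seed = 1)  # het, all 2
  th_hi <- assign_thresholds(g, "absolute", c(4, 4), rng_seed = 1)  # het, all 4
  br_lo <- bridge_report(g, "a", "b", th_lo)
  br_hi <- bridge_report(g, "a", "b", th_hi)
  expect_true("d" %in% br_lo$reinforcement)   # |O_ad| = |{b,c}| = 2 >= 2
  expect_false("d" %in% br_hi$reinforcement)  # 2 < 4
})
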