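# Fixture graphs built in code. All are plain named igraphs.

graph_from_pairs <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = FALSE)
}

path_graph <- function(labels) {
  el <- cbind(labels[-length(labels)], labels[-1])
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = FALSE)
}

star_graph <- function(n_leaves, center = "c") {
  leaves <- paste0("l", seq_len(n_leaves))
  igraph::graph_from_data_frame(
    data.frame(from = center, to = leaves, stringsAsFactors = FALSE),
    directed = FALSE)
}

k5 <- function() {
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- as.character(1:5)
  g
}

# Two triangles {a,b,c} and {c,d,e} sharing c, plus the extra edge b-d:
# at T = 2 a contagion seeded at N[a] reaches e in 3 vertices.
two_triangles <- function() {
  graph_from_pairs("a","b", "a","c", "b","c", "c","d", "c","e", "d","e", "b","d")
}

# Chain of `n_cliques` K4s in which consecutive cliques share two nodes
# (bridge width >= 2 everywhere along the chain, so a T = 2 contagion
# traverses it), plus a hub with `n_leaves` mutually unconnected leaves.
# The hub has the highest degree but cannot spread at T = 2; the chain
# carries the contagion. Hub is tied to chain node "1" to keep one component.
hub_vs_clique_chain <- function(n_cliques = 6, n_leaves = 8) {
  el <- NULL
  for (t in seq_len(n_cliques)) {
    nodes <- as.character((2 * t - 1):(2 * t + 2))
    el <- rbind(el, t(combn(nodes, 2)))
  }
  el <- el[!duplicated(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))), ]
  leaves <- paste0("leaf", seq_len(n_leaves))
  el <- rbind(el, cbind("hub", leaves), c("hub", "1"))
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = FALSE)
}

random_graph <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p_edge)
    igraph::V(g)$name <- as.character(seq_len(n))
    g
  })
}

random_connected_graph <- function(n, p_edge, seed) {
  offset <- 0L
  repeat {
    g <- random_graph(n, p_edge, seed + offset * 7919L)
    if (igraph::is_connected(g)) return(g)
    offset <- offset + 1L
  }
}
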