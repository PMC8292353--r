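# Node centralities: complex centrality (the average complex path length of
# a node) and the classical baselines it is compared against. Baselines go
# through igraph where igraph implements them; the collective-influence
# style percolation score and radius-limited reach are computed directly
# from the distance matrix.

#' Complex centrality of every node
#'
#' `CC_i = PL_c_i`: the node with the highest average complex path length
#' has the longest, most robust chains of sufficient bridges and is the best
#' seed for a complex contagion. The top node is reported in the `"top"`
#' attribute; ties are broken by the smallest node label and reported via a
#' message.
#'
#' @param graph An undirected simple igraph.
#' @param thresholds A [assign_thresholds()] result.
#' @return Named numeric vector of scores with attribute `"top"`.
#' @examples
#' g <- generate_rewired_lattice(20, 4, 0)
#' th <- assign_thresholds(g, "absolute", 2)
#' cc <- complex_centrality(g, th)
#' attr(cc, "top")
#' @export
complex_centrality <- function(graph, thresholds) {
  prof <- complex_path_profile(graph, thresholds)
  scores <- setNames(prof$plc, prof$node)
  top <- top_node(scores)
  attr(scores, "top") <- top
  scores
}

# deterministic argmax: highest score, ties to the smallest label
top_node <- function(scores) {
  mx <- max(scores)
  tied <- names(scores)[scores == mx]
  if (length(tied) > 1) {
    message("centrality argmax tie among ", length(tied),
            " nodes; taking smallest label")
  }
  tied[order(tied)][1]
}

#' Classical baseline centralities
#'
#' @param graph An undirected simple igraph.
#' @param measures Subset of `"degree"`, `"betweenness"`, `"eigenvector"`,
#'   `"k_core"`, `"percolation"`, `"closeness"`, `"reach"`.
#' @param d Distance parameter of the percolation (collective-influence)
#'   score `(deg(i) - 1) * sum over nodes j at shortest-path distance
#'   exactly d of (deg(j) - 1)`; default 3.
#' @param reach_radius Radius of the reach count (nodes within the radius,
#'   excluding the node itself); default 2.
#' @return Data.frame with a `node` column plus one column per measure.
#'   Eigenvector centrality on a disconnected graph is computed per
#'   connected component (each component scaled to maximum 1), which is
#'   reported via a message.
#' @export
baseline_centralities <- function(graph,
                                  measures = c("degree", "betweenness",
                                               "eigenvector", "k_core",
                                               "percolation"),
                                  d = 3, reach_radius = 2) {
  graph <- as_cc_graph(graph)
  measures <- match.arg(measures,
                        c("degree", "betweenness", "eigenvector", "k_core",
                          "percolation", "closeness", "reach"),
                        several.ok = TRUE)
  if (d < 1) stop("`d` must be >= 1", call. = FALSE)
  n <- igraph::vcount(graph)
  deg <- igraph::degree(graph)
  out <- data.frame(node = node_names(graph), stringsAsFactors = FALSE)
  dist_mat <- NULL
  need_dist <- any(c("percolation", "closeness", "reach") %in% measures)
  if (need_dist) dist_mat <- igraph::distances(graph)

  for (m in measures) {
    out[[m]] <- switch(
      m,
      degree = as.numeric(deg),
      betweenness = as.numeric(igraph::betweenness(graph, directed = FALSE)),
      eigenvector = eigenvector_by_component(graph),
      k_core = as.numeric(igraph::coreness(graph)),
      percolation = {
        red <- pmax(deg - 1, 0)
        vapply(seq_len(n), function(i) {
          at_d <- which(dist_mat[i, ] == d)
          red[i] * sum(red[at_d])
        }, numeric(1))
      },
      closeness = vapply(seq_len(n), function(i) {
        dd <- dist_mat[i, -i]
        dd <- dd[is.finite(dd)]
        if (length(dd) == 0) 0 else 1 / mean(dd)
      }, numeric(1)),
      reach = vapply(seq_len(n), function(i) {
        sum(dist_mat[i, -i] <= reach_radius)
      }, numeric(1))
    )
  }
  out
}

eigenvector_by_component <- function(graph) {
  comps <- igraph::components(graph)
  scores <- numeric(igraph::vcount(graph))
  if (comps$no > 1) {
    message("eigenvector centrality computed per connected component (",
            comps$no, " components)")
  }
  for (cid in seq_len(comps$no)) {
    members <- which(comps$membership == cid)
    if (length(members) == 1 ||
        igraph::ecount(igraph::induced_subgraph(graph, members)) == 0) {
      scores[members] <- 0
      next
    }
    sub <- igraph::induced_subgraph(graph, members)
    scores[members] <- igraph::eigen_centrality(sub, directed = FALSE)$vector
  }
  scores
}

#' Ensemble complex centrality over a threshold range
#'
#' When the empirical adoption threshold is unknown, a node's expected
#' complex centrality is taken as the mean of its complex centrality over a
#' range of homogeneous absolute thresholds (default 2..6).
#'
#' @inheritParams complex_centrality
#' @param t_values Non-empty vector of absolute threshold values.
#' @return Named numeric vector of mean scores with attribute `"top"`.
#' @export
ensemble_complex_centrality <- function(graph, t_values = 2:6) {
  graph <- as_cc_graph(graph)
  if (length(t_values) == 0) stop("`t_values` must be non-empty", call. = FALSE)
  cols <- vapply(t_values, function(tv) {
    th <- assign_thresholds(graph, "absolute", tv)
    as.numeric(complex_path_profile(graph, th)$plc)
  }, numeric(igraph::vcount(graph)))
  scores <- setNames(rowMeans(as.matrix(cols)), node_names(graph))
  attr(scores, "top") <- top_node(scores)
  scores
}

#' Greedy seed ranking by simulated individual performance
#'
#' The canonical greedy baseline: simulate diffusion from every node
#' (seeding the node plus `effective_threshold - 1` of its neighbours via
#' [build_seed_set()]), estimate each node's expected final adoption over
#' `trials` runs, and rank nodes by that estimate.
#'
#' @param graph An undirected simple igraph.
#' @param thresholds A [assign_thresholds()] result (threshold model), or
#'   `NULL` for the alternative models.
#' @param model `"threshold"` (default), `"ic"` or `"lt"`.
#' @param theta Activation probability for the Independent Cascade model.
#' @param budget Number of top-ranked nodes to mark as selected.
#' @param trials Simulations per focal node.
#' @param rng_seed Optional master seed; each (node, trial) gets a derived
#'   sub-seed so rankings are reproducible.
#' @return Data.frame with `node`, `expected_adoption`, `rank`, `selected`,
#'   sorted by decreasing expected adoption (ties by label).
#' @export
greedy_seed_selection <- function(graph, thresholds = NULL,
                                  model = c("threshold", "ic", "lt"),
                                  theta = 0.1, budget = 1, trials = 10,
                                  rng_seed = NULL) {
  graph <- as_cc_graph(graph)
  model <- match.arg(model)
  if (budget < 1) stop("`budget` must be >= 1", call. = FALSE)
  if (model == "threshold" && is.null(thresholds)) {
    stop("`thresholds` is required for the threshold model", call. = FALSE)
  }
  n <- igraph::vcount(graph)
  nm <- node_names(graph)
  teff <- if (!is.null(thresholds)) {
    as.numeric(effective_threshold(graph, thresholds))
  } else {
    rep(2, n)  # seed budget convention for ic/lt: focal + 1 neighbour
  }
  master <- if (is.null(rng_seed)) sample.int(2^31 - 2, 1) else as.integer(rng_seed)

  expected <- vapply(seq_len(n), function(ii) {
    fracs <- vapply(seq_len(trials), function(tr) {
      sd <- derive_seed(master, ii * 1000L + tr)
      seeds <- build_seed_set(graph, nm[ii], teff[ii], rng_seed = sd)
      trace <- switch(model,
        threshold = run_threshold_model(graph, thresholds, seeds),
        ic = run_independent_cascade(graph, theta, seeds, rng_seed = sd),
        lt = run_linear_threshold(graph, seeds, rng_seed = sd))
      cascade_outcome(trace)$adoption_fraction
    }, numeric(1))
    mean(fracs)
  }, numeric(1))

  ord <- order(-expected, nm)
  out <- data.frame(node = nm[ord], expected_adoption = expected[ord],
                    rank = seq_len(n), stringsAsFactors = FALSE)
  out$selected <- out$rank <= budget
  if (budget < n && out$expected_adoption[budget] ==
        out$expected_adoption[budget + 1]) {
    message("greedy_seed_selection: tie at the selection boundary")
  }
  out
}
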