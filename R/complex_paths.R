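# Complex path length.
#
# The complex path from i to j is measured by seeding i's entire closed
# neighbourhood N[i], running the threshold cascade to fixation, and — if j
# was activated — taking a shortest i -> j path inside the subgraph induced
# by the activated nodes (CP_ij). Its length PL_c_ij is the number of
# vertices on that geodesic; if the contagion cannot reach j, PL_c_ij = 0.
# The node-level average PL_c_i sums PL_c_ij over targets outside N[i] and
# divides by n - |N[i]|; the graph-level PL_c averages PL_c_i over nodes.

# One neighbourhood-seeded spread: cascade from N[i] plus a BFS from i
# restricted to the activated set. Returns activation indicator and
# hop distances (NA = not reachable inside the activated subgraph).
spread_from_neighborhood_core <- function(A, teff, ncl_i, i) {
  n <- nrow(A)
  cas <- threshold_cascade_core(A, teff, ncl_i)
  active <- !is.na(cas$times)
  dist <- rep(NA_real_, n)
  if (active[i]) {
    dist[i] <- 0
    frontier <- rep(0, n)
    frontier[i] <- 1
    d <- 0
    while (TRUE) {
      reached <- as.numeric(A %*% frontier) > 0
      newly <- which(reached & active & is.na(dist))
      if (length(newly) == 0) break
      d <- d + 1
      dist[newly] <- d
      frontier <- rep(0, n)
      frontier[newly] <- 1
    }
  }
  list(active = active, dist = dist, steps = cas$steps, times = cas$times)
}

#' Complex path between two nodes
#'
#' Seeds the closed neighbourhood `N[i]`, runs the threshold cascade to
#' fixation, and extracts the activated subgraph `CP_ij` together with a
#' shortest `i -> j` path inside it. When `j` is not activated the result is
#' empty with length 0. Only the geodesic's length is consumed by the
#' summary measures, so ties between equally short geodesics are broken by
#' igraph's BFS order and are inconsequential.
#'
#' @param graph An undirected simple igraph.
#' @param i,j Distinct node labels or indices.
#' @param thresholds A [assign_thresholds()] result.
#' @return A `complex_path_result` with the activated node set, the geodesic
#'   vertex sequence (possibly empty) and `length` (vertex count, 0 if
#'   unreachable).
#' @examples
#' g <- generate_rewired_lattice(10, 4, 0)
#' th <- assign_thresholds(g, "absolute", 2)
#' complex_path(g, "1", "6", th)
#' @export
complex_path <- function(graph, i, j, thresholds) {
  graph <- as_cc_graph(graph)
  ii <- node_index(graph, i)
  jj <- node_index(graph, j)
  if (ii == jj) stop("`i` and `j` must be distinct nodes", call. = FALSE)
  teff <- as.numeric(effective_threshold(graph, thresholds))
  ncl <- closed_nb_list(graph)
  sp <- spread_from_neighborhood_core(adj_sparse(graph), teff, ncl[[ii]], ii)
  nm <- node_names(graph)

  if (!sp$active[jj] || is.na(sp$dist[jj])) {
    res <- list(source = nm[ii], target = nm[jj],
                activated = character(0), geodesic = character(0), length = 0)
  } else {
    cp <- igraph::induced_subgraph(graph, which(sp$active))
    path <- igraph::shortest_paths(cp, from = nm[ii], to = nm[jj],
                                   output = "vpath")$vpath[[1]]
    res <- list(source = nm[ii], target = nm[jj],
                activated = nm[sp$active],
                geodesic = names(path), length = length(path))
  }
  structure(res, class = "complex_path_result")
}

#' @export
print.complex_path_result <- function(x, ...) {
  if (x$length == 0) {
    cat(sprintf("<complex_path> %s -> %s: unreachable (PL_c = 0)\n",
                x$source, x$target))
  } else {
    cat(sprintf("<complex_path> %s -> %s: PL_c = %d via %s\n",
                x$source, x$target, x$length,
                paste(x$geodesic, collapse = " - ")))
  }
  invisible(x)
}

#' Complex path lengths from one node to all others
#'
#' Runs a single neighbourhood-seeded cascade from `N[i]` and returns
#' `PL_c_ij` for every other node `j`: the geodesic vertex count inside the
#' activated subgraph, or 0 where `j` was not activated. Values are reported
#' for all `j`, including members of `N[i]`; the node-level average
#' [node_complex_path_length()] uses only targets outside `N[i]`.
#'
#' @inheritParams complex_path
#' @param i Source node label or index.
#' @return Named numeric vector over all nodes `j != i`.
#' @export
complex_path_lengths <- function(graph, i, thresholds) {
  graph <- as_cc_graph(graph)
  ii <- node_index(graph, i)
  teff <- as.numeric(effective_threshold(graph, thresholds))
  ncl <- closed_nb_list(graph)
  sp <- spread_from_neighborhood_core(adj_sparse(graph), teff, ncl[[ii]], ii)
  pl <- ifelse(is.na(sp$dist), 0, sp$dist + 1)
  setNames(pl, node_names(graph))[-ii]
}

#' Average complex path length of a node (complex centrality)
#'
#' `PL_c_i`: the sum of `PL_c_ij` over all targets `j` outside the closed
#' neighbourhood `N[i]`, divided by `n - |N[i]|`. When `N[i]` covers the
#' whole graph there are no targets and the value is defined as 0.
#'
#' @inheritParams complex_path_lengths
#' @return A single non-negative number.
#' @export
node_complex_path_length <- function(graph, i, thresholds) {
  graph <- as_cc_graph(graph)
  ii <- node_index(graph, i)
  teff <- as.numeric(effective_threshold(graph, thresholds))
  ncl <- closed_nb_list(graph)
  node_plc_core(adj_sparse(graph), teff, ncl, ii)$plc
}

node_plc_core <- function(A, teff, ncl, ii) {
  n <- nrow(A)
  sp <- spread_from_neighborhood_core(A, teff, ncl[[ii]], ii)
  denom <- n - length(ncl[[ii]])
  targets <- setdiff(seq_len(n), ncl[[ii]])
  plc <- if (denom <= 0) {
    0
  } else {
    d <- sp$dist[targets]
    sum(ifelse(is.na(d), 0, d + 1)) / denom
  }
  list(plc = plc, adoption = mean(sp$active), steps = sp$steps)
}

#' Per-node complex path profile
#'
#' The workhorse behind [complex_centrality()] and the experiment harness:
#' for every node `i` it seeds `N[i]`, runs the cascade once, and records
#' both `PL_c_i` and the final adoption fraction of that run.
#'
#' @inheritParams complex_path
#' @return A data.frame with columns `node`, `plc` and `adoption_fraction`.
#' @export
complex_path_profile <- function(graph, thresholds) {
  graph <- as_cc_graph(graph)
  n <- igraph::vcount(graph)
  teff <- as.numeric(effective_threshold(graph, thresholds))
  ncl <- closed_nb_list(graph)
  A <- adj_sparse(graph)
  plc <- numeric(n)
  adoption <- numeric(n)
  for (ii in seq_len(n)) {
    res <- node_plc_core(A, teff, ncl, ii)
    plc[ii] <- res$plc
    adoption[ii] <- res$adoption
  }
  data.frame(node = node_names(graph), plc = plc,
             adoption_fraction = adoption, stringsAsFactors = FALSE)
}

#' Average complex path length of a graph
#'
#' `PL_c`: the mean of `PL_c_i` over all nodes — the graph-level
#' connectedness measure for complex contagions.
#'
#' @inheritParams complex_path
#' @return A single non-negative number.
#' @examples
#' g <- generate_rewired_lattice(20, 4, 0)
#' th <- assign_thresholds(g, "absolute", 2)
#' graph_complex_path_length(g, th)
#' @export
graph_complex_path_length <- function(graph, thresholds) {
  mean(complex_path_profile(graph, thresholds)$plc)
}
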