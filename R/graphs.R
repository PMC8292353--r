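# Graph generators and edge-list I/O.
#
# Two synthetic ensembles are provided: degree-preserving rewired ring
# lattices (the k-regular small-world continuum) and clustering-tunable
# scale-free graphs grown by preferential attachment with triad formation.
# Both are written out as plain igraph objects with character vertex names
# so that generated and file-read graphs are interchangeable everywhere else.

#' Generate a degree-preserving rewired ring lattice
#'
#' Starts from a ring of `n` vertices in which every vertex is connected to
#' its `k` nearest neighbours (`k/2` on each side) and randomises it with
#' degree-preserving double-edge swaps: each lattice edge is visited once in
#' random order and, with probability `p`, a swap with another uniformly
#' chosen edge is attempted. Swaps that would create a self-loop or a
#' multi-edge are rejected, so the result is always a simple k-regular
#' graph. `p = 0` returns the pristine lattice; `p = 1` attempts a swap for
#' every edge.
#'
#' Connectivity is not enforced: at high `p` a realization can (rarely)
#' disconnect, which callers that need connected graphs should check with
#' [igraph::is_connected()].
#'
#' @param n Number of nodes (`n > k`).
#' @param k Even degree, `2 <= k < n`.
#' @param p Rewiring probability in `[0, 1]`.
#' @param rng_seed Optional integer seed; fixed seeds give bit-identical
#'   graphs.
#' @return An undirected simple k-regular igraph with nodes `"1"`..`"n"`.
#' @examples
#' g <- generate_rewired_lattice(20, 4, 0.1, rng_seed = 1)
#' all(igraph::degree(g) == 4)
#' @export
generate_rewired_lattice <- function(n, k, p, rng_seed = NULL) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (length(n) != 1 || n < 3) stop("`n` must be a single integer >= 3", call. = FALSE)
  if (length(k) != 1 || k %% 2L != 0L || k < 2L || k >= n) {
    stop("`k` must be even with 2 <= k < n", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }

  # ring lattice edges: i -- i+d (mod n) for d = 1..k/2
  from <- rep(seq_len(n), k / 2L)
  d <- rep(seq_len(k / 2L), each = n)
  to <- (from + d - 1L) %% n + 1L
  edges <- cbind(from, to)
  # d = n/2 with even n would duplicate edges; excluded by k < n guard for
  # k/2 < n/2, but drop any duplicates defensively
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(key), , drop = FALSE]

  edges <- with_seed_opt(rng_seed, rewire_double_swaps(edges, n, p))

  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# Single pass of probabilistic degree-preserving double-edge swaps over the
# edge matrix. Maintains a dense logical adjacency for O(1) multi-edge checks.
rewire_double_swaps <- function(edges, n, p) {
  m <- nrow(edges)
  if (p == 0 || m < 2) return(edges)
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, c(2, 1), drop = FALSE]] <- TRUE

  for (e in sample.int(m)) {
    if (runif(1) >= p) next
    f <- sample.int(m - 1L, 1L)
    if (f >= e) f <- f + 1L  # uniform over the other edges
    a <- edges[e, 1]; b <- edges[e, 2]
    c_ <- edges[f, 1]; d_ <- edges[f, 2]
    if (runif(1) < 0.5) { tmp <- c_; c_ <- d_; d_ <- tmp }
    # proposed replacement: (a,b),(c,d) -> (a,d),(c,b)
    if (a == d_ || c_ == b) next                   # self-loop
    if (adj[a, d_] || adj[c_, b]) next             # multi-edge
    if ((a == c_ && d_ == b) || (a == b)) next     # identical new edges
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c_, d_] <- adj[d_, c_] <- FALSE
    adj[a, d_] <- adj[d_, a] <- TRUE
    adj[c_, b] <- adj[b, c_] <- TRUE
    edges[e, ] <- c(a, d_)
    edges[f, ] <- c(c_, b)
  }
  edges
}

#' Generate a clustering-tunable scale-free graph
#'
#' Grows a graph by preferential attachment with a triad-formation step:
#' starting from a clique on `m` nodes, each arriving node attaches with `m`
#' edges. The first edge of an arrival always goes to a target chosen with
#' probability proportional to degree; each subsequent edge is, with
#' probability `triad_p`, connected to a random neighbour of the previous
#' preferential-attachment target (closing a triangle), and otherwise drawn
#' by preferential attachment again. `triad_p = 0` gives the familiar
#' heavy-tailed degree distribution with exponent close to 3; increasing
#' `triad_p` raises clustering while leaving the degree exponent essentially
#' unchanged.
#'
#' The resulting graph has exactly `m * (n - m) + choose(m, 2)` edges, is
#' connected, and every non-core node has degree at least `m`.
#'
#' @param n Number of nodes.
#' @param m Edges added per arriving node, `1 <= m < n`.
#' @param triad_p Triad-formation probability in `[0, 1]`.
#' @param rng_seed Optional integer seed for reproducibility.
#' @return An undirected simple igraph with nodes `"1"`..`"n"`.
#' @examples
#' g <- generate_scale_free(100, 4, 0.5, rng_seed = 1)
#' igraph::ecount(g) == 4 * 96 + 6
#' @export
generate_scale_free <- function(n, m, triad_p = 0, rng_seed = NULL) {
  n <- as.integer(n)
  m <- as.integer(m)
  if (length(n) != 1 || n < 1) stop("`n` must be a positive integer", call. = FALSE)
  if (length(m) != 1 || m < 1 || m >= n) {
    stop("`m` must satisfy 1 <= m < n", call. = FALSE)
  }
  if (!is.numeric(triad_p) || length(triad_p) != 1 || triad_p < 0 || triad_p > 1) {
    stop("`triad_p` must be a probability in [0, 1]", call. = FALSE)
  }

  with_seed_opt(rng_seed, {
    nbrs <- vector("list", n)          # adjacency under construction
    repeated <- integer(0)             # node repeated once per incident edge
    if (m > 1) {
      core <- combn(m, 2)
      for (idx in seq_len(ncol(core))) {
        a <- core[1, idx]; b <- core[2, idx]
        nbrs[[a]] <- c(nbrs[[a]], b)
        nbrs[[b]] <- c(nbrs[[b]], a)
      }
      repeated <- rep(seq_len(m), each = m - 1L)
    }

    pa_target <- function(v, chosen) {
      # degree-proportional draw with rejection against v and earlier targets
      repeat {
        cand <- if (length(repeated) > 0) {
          repeated[sample.int(length(repeated), 1L)]
        } else {
          sample.int(v - 1L, 1L)
        }
        if (cand != v && !(cand %in% chosen)) return(cand)
      }
    }

    for (v in seq.int(m + 1L, n)) {
      chosen <- integer(0)
      last_pa <- NA_integer_
      while (length(chosen) < m) {
        use_triad <- length(chosen) > 0 && !is.na(last_pa) &&
          runif(1) < triad_p
        target <- NA_integer_
        if (use_triad) {
          cand <- setdiff(nbrs[[last_pa]], c(v, chosen))
          if (length(cand) > 0) {
            target <- cand[sample.int(length(cand), 1L)]
          }
        }
        if (is.na(target)) {
          target <- pa_target(v, chosen)
          last_pa <- target
        }
        chosen <- c(chosen, target)
      }
      for (t in chosen) {
        nbrs[[t]] <- c(nbrs[[t]], v)
        repeated <- c(repeated, t, v)
      }
      nbrs[[v]] <- chosen
    }

    el <- do.call(rbind, lapply(seq_len(n), function(i) {
      js <- nbrs[[i]][nbrs[[i]] > i]
      if (length(js) == 0) NULL else cbind(i, js)
    }))
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (!is.null(el)) g <- igraph::add_edges(g, t(el))
    igraph::V(g)$name <- as.character(seq_len(n))
    g
  })
}

#' Read a graph from a two-column edge list
#'
#' Each non-blank line that does not start with `#` must contain exactly two
#' node labels separated by whitespace and/or a comma. Duplicate edges are
#' collapsed and self-loops are dropped with a warning. Node labels are kept
#' as character strings (integer labels are stringified).
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple igraph.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no edges found in ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0) {
    stop("malformed edge list line ", keep[bad[1]], " in ", path,
         ": expected two node labels", call. = FALSE)
  }
  el <- do.call(rbind, toks)
  loops <- el[, 1] == el[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped while reading ", path,
            call. = FALSE)
    el <- el[!loops, , drop = FALSE]
  }
  if (nrow(el) == 0) stop("edge list contains only self-loops", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = FALSE
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a two-column edge list
#'
#' @param graph An undirected simple igraph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  graph <- as_cc_graph(graph)
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}
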