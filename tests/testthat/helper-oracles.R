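# Independent brute-force oracles. These deliberately avoid the package's
# computation paths: bridge sets are enumerated with igraph subgraph edge
# lists, the threshold fixed point is found by asynchronous scanning, and
# complex path lengths at T = 1 come from plain BFS distances.

# Per-graph context caching closed neighbourhoods and induced-subgraph edge
# keys so all-pairs oracle sweeps stay affordable.
oracle_context <- function(g) {
  nm <- igraph::V(g)$name
  ncl <- lapply(nm, function(v) {
    sort(unique(c(v, nm[igraph::neighbors(g, v)])))
  })
  names(ncl) <- nm
  edge_keys <- lapply(nm, function(v) {
    sub <- igraph::induced_subgraph(g, ncl[[v]])
    el <- igraph::as_edgelist(sub)
    if (nrow(el) == 0) character(0) else
      paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  })
  names(edge_keys) <- nm
  list(nm = nm, ncl = ncl, edge_keys = edge_keys)
}

# Bridge sets for the ordered pair (i, j) per the formal definitions.
# teff: named effective thresholds; het: apply the heterogeneous filter.
oracle_bridge <- function(ctx, i, j, teff, het) {
  Ni <- ctx$ncl[[i]]; Nj <- ctx$ncl[[j]]
  O <- intersect(Ni, Nj)
  D <- setdiff(Nj, Ni)
  Ei <- ctx$edge_keys[[i]]
  R <- D[vapply(D, function(x) {
    ok <- length(intersect(Ei, ctx$edge_keys[[x]])) >= 1
    if (ok && het) ok <- length(intersect(Ni, ctx$ncl[[x]])) >= teff[[x]]
    ok
  }, logical(1))]
  list(O = sort(O), D = sort(D), R = sort(R), W = length(O) + length(R))
}

# Graph LB by direct all-pairs enumeration of the definitions.
oracle_lb <- function(g, teff, het) {
  ctx <- oracle_context(g)
  nm <- ctx$nm
  n <- length(nm)
  W <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in nm) for (j in nm) {
    if (i != j) W[i, j] <- oracle_bridge(ctx, i, j, teff, het)$W
  }
  lb_i <- vapply(nm, function(i) {
    partners <- nm[nm != i & W[, i] >= 1]
    if (length(partners) == 0) return(0)
    mean(W[i, partners] >= teff[partners])
  }, numeric(1))
  list(lb = mean(lb_i), W = W)
}

# Asynchronous fixed point of the threshold dynamics: repeatedly scan all
# nodes in random order, activating any node whose active-neighbour count
# meets its threshold, until a full scan changes nothing.
oracle_async_fixed_point <- function(g, teff, seeds, scan_seed = 1) {
  nm <- igraph::V(g)$name
  active <- setNames(rep(FALSE, length(nm)), nm)
  active[seeds] <- TRUE
  withr::with_seed(scan_seed, {
    repeat {
      changed <- FALSE
      for (v in sample(nm)) {
        if (active[v]) next
        cnt <- sum(active[nm[igraph::neighbors(g, v)]])
        if (cnt >= teff[[v]]) {
          active[v] <- TRUE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  })
  sort(nm[active])
}

# All isomorphism classes of connected graphs on n nodes (n <= 6),
# enumerated by edge-subset masks and deduplicated by canonical form.
# Memoised across test files.
.graph_class_cache <- new.env(parent = emptyenv())

connected_graph_classes <- function(n) {
  key <- as.character(n)
  if (!is.null(.graph_class_cache[[key]])) return(.graph_class_cache[[key]])
  pairs <- combn(n, 2)
  m <- ncol(pairs)
  bits <- 2^(0:(m - 1))
  reps <- list()
  seen <- new.env(hash = TRUE)
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, bits) > 0)
    if (length(sel) < n - 1) next
    el <- pairs[, sel, drop = FALSE]
    parent <- seq_len(n)
    find <- function(a) {
      while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }
      a
    }
    for (e in seq_len(ncol(el))) {
      ra <- find(el[1, e]); rb <- find(el[2, e])
      if (ra != rb) parent[ra] <- rb
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) != 1) next
    g <- igraph::graph_from_edgelist(t(el), directed = FALSE)
    cp <- igraph::canonical_permutation(g)$labeling
    cel <- igraph::as_edgelist(igraph::permute(g, cp))
    cel <- cbind(pmin(cel[, 1], cel[, 2]), pmax(cel[, 1], cel[, 2]))
    cel <- cel[order(cel[, 1], cel[, 2]), , drop = FALSE]
    keyg <- paste(t(cel), collapse = ",")
    if (!exists(keyg, envir = seen)) {
      assign(keyg, TRUE, envir = seen)
      igraph::V(g)$name <- as.character(seq_len(n))
      reps[[length(reps) + 1L]] <- g
    }
  }
  .graph_class_cache[[key]] <- reps
  reps
}

# named effective thresholds for a homogeneous absolute T
teff_const <- function(g, t) {
  setNames(rep(t, igraph::vcount(g)), igraph::V(g)$name)
}
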