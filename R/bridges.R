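# Bridge width between neighbourhoods.
#
# For an ordered pair (i, j) the bridge from N[i] (closed neighbourhood of
# i) to N[j] is built from:
#   O_ij = N[i] intersect N[j]                      (overlap)
#   D_ij = N[j] \ N[i]                              (disjoint set)
#   R_ij = { x in D_ij : |E(N[i]) inter E(N[x])| >= 1 }   (reinforcement)
#   BW_ij = O_ij union R_ij,  W_ij = |BW_ij|        (bridge and its width)
# where E(N[i]) is the edge set of the subgraph induced by N[i]. An edge
# lies in both E(N[i]) and E(N[x]) exactly when both its endpoints lie in
# O_ix, so the reinforcement test is "the subgraph induced by N[i] inter
# N[x] contains at least one edge". Under heterogeneous thresholds R_ij
# additionally keeps only nodes x that N[i] could itself activate,
# |O_ix| >= effective_threshold(x). The bridge is sufficient when
# W_ij >= effective_threshold(j).
#
# Two computation paths are provided: a readable per-pair set enumeration
# (bridge_report) and a sparse-matrix all-pairs path (bridge_width_matrix)
# used by graph-level summaries; the test-suite checks them against each
# other and against an independent brute-force oracle.

# does the subgraph induced by node set S contain at least one edge?
has_internal_edge <- function(al, S) {
  if (length(S) < 2) return(FALSE)
  for (a in S) {
    if (any(al[[a]] %in% S)) return(TRUE)
  }
  FALSE
}

# Per-pair bridge sets on integer indices. `prose` switches the
# reinforcement test to the looser reading "x has at least one neighbour in
# N[i]" (exposed for sensitivity analysis only).
bridge_sets_core <- function(al, ncl, i, j, teff, heterogeneous, prose = FALSE) {
  O <- intersect(ncl[[i]], ncl[[j]])
  D <- setdiff(ncl[[j]], ncl[[i]])
  keep <- logical(length(D))
  for (idx in seq_along(D)) {
    x <- D[idx]
    linked <- if (prose) {
      any(al[[x]] %in% ncl[[i]])
    } else {
      has_internal_edge(al, intersect(ncl[[i]], ncl[[x]]))
    }
    if (linked && heterogeneous) {
      linked <- length(intersect(ncl[[i]], ncl[[x]])) >= teff[x]
    }
    keep[idx] <- linked
  }
  R <- D[keep]
  list(O = O, D = D, R = R, BW = c(O, R), W = length(O) + length(R))
}

#' Bridge width report for an ordered node pair
#'
#' Computes the overlap, disjoint, reinforcement and bridge sets between the
#' closed neighbourhoods of `i` and `j`, the bridge width `W_ij`, and
#' whether the bridge is sufficient to carry a contagion into `j`
#' (`W_ij >= effective_threshold(j)`).
#'
#' @param graph An undirected simple igraph.
#' @param i,j Distinct node labels or indices; the bridge is directed from
#'   `i`'s neighbourhood towards `j`.
#' @param thresholds A [assign_thresholds()] result. Under heterogeneous
#'   thresholds the reinforcement set keeps only nodes `x` with
#'   `|N[i] inter N[x]| >= effective_threshold(x)`.
#' @param prose_reinforcement If `TRUE`, use the looser reinforcement test
#'   "x has a neighbour in N[i]" instead of the shared-induced-edge test.
#'   Intended for sensitivity checks; the default is the formal definition.
#' @return A `bridge_report`: sets as character vectors plus `width` and
#'   `sufficient`.
#' @examples
#' g <- igraph::make_full_graph(4)
#' th <- assign_thresholds(g, "absolute", 2)
#' bridge_report(g, 1, 2, th)
#' @export
bridge_report <- function(graph, i, j, thresholds, prose_reinforcement = FALSE) {
  graph <- as_cc_graph(graph)
  ii <- node_index(graph, i)
  jj <- node_index(graph, j)
  if (ii == jj) stop("`i` and `j` must be distinct nodes", call. = FALSE)
  teff <- as.numeric(effective_threshold(graph, thresholds))
  al <- adj_list_int(graph)
  ncl <- closed_nb_list(graph)
  s <- bridge_sets_core(al, ncl, ii, jj, teff, thresholds$heterogeneous,
                        prose_reinforcement)
  nm <- node_names(graph)
  structure(
    list(i = nm[ii], j = nm[jj],
         overlap = nm[s$O], disjoint = nm[s$D], reinforcement = nm[s$R],
         bridge = nm[s$BW], width = s$W,
         sufficient = s$W >= teff[jj]),
    class = "bridge_report"
  )
}

#' @export
print.bridge_report <- function(x, ...) {
  cat(sprintf("<bridge_report> %s -> %s: |O| = %d, |R| = %d, W = %d, %s\n",
              x$i, x$j, length(x$overlap), length(x$reinforcement), x$width,
              if (x$sufficient) "sufficient" else "insufficient"))
  invisible(x)
}

#' All-pairs bridge width matrix
#'
#' Computes `W_ij` for every ordered pair in a handful of sparse matrix
#' operations: with `Ncl` the closed-neighbourhood incidence matrix,
#' `|O_ij|` is `Ncl %*% Ncl`, and `|E(N[i]) inter E(N[x])|` is assembled
#' edge-by-edge from the product of the endpoint columns of `Ncl`, giving
#' the reinforcement eligibility of every (source, candidate) pair at once.
#'
#' @inheritParams bridge_report
#' @return Dense numeric `n x n` matrix with dimnames; entry `[i, j]` is
#'   `W_ij` (bridge from `i`'s neighbourhood towards `j`); the diagonal is
#'   `NA` (a node has no bridge to itself).
#' @export
bridge_width_matrix <- function(graph, thresholds, prose_reinforcement = FALSE) {
  graph <- as_cc_graph(graph)
  n <- igraph::vcount(graph)
  teff <- as.numeric(effective_threshold(graph, thresholds))
  A <- adj_sparse(graph)
  Ncl <- A + Matrix::Diagonal(n)                      # closed neighbourhoods
  M <- Ncl %*% Ncl                                    # |O_ij|

  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) > 0) {
    # Z[, e] = 1 for nodes whose closed neighbourhood contains both
    # endpoints of edge e; S[v, x] = number of shared induced edges.
    Z <- Ncl[, el[, 1], drop = FALSE] * Ncl[, el[, 2], drop = FALSE]
    S <- Matrix::tcrossprod(Z)
    elig <- (S >= 1) & (Ncl == 0)
    if (isTRUE(thresholds$heterogeneous)) {
      # keep candidate x only if |O_ix| >= teff[x] (columnwise threshold)
      elig <- elig & ((M - Matrix::tcrossprod(rep(1, n), teff - 1)) > 0)
    }
    elig <- methods::as(elig, "dMatrix")
    RR <- elig %*% Ncl
  } else {
    RR <- Matrix::Matrix(0, n, n, sparse = TRUE)
  }
  if (prose_reinforcement) {
    eligp <- ((Ncl %*% A) >= 1) & (Ncl == 0)
    if (isTRUE(thresholds$heterogeneous)) {
      eligp <- eligp & ((M - Matrix::tcrossprod(rep(1, n), teff - 1)) > 0)
    }
    RR <- methods::as(eligp, "dMatrix") %*% Ncl
  }

  W <- as.matrix(M + RR)
  diag(W) <- NA_real_
  dimnames(W) <- list(node_names(graph), node_names(graph))
  W
}

#' Bridge partners of a node
#'
#' The set `B_i` of nodes `v != i` whose neighbourhood has a non-empty
#' bridge towards `i` (`W_vi >= 1`).
#'
#' @inheritParams bridge_report
#' @param i Node label or index.
#' @return Character vector of partner labels.
#' @export
bridge_partners <- function(graph, i, thresholds) {
  graph <- as_cc_graph(graph)
  ii <- node_index(graph, i)
  W <- bridge_width_matrix(graph, thresholds)
  partners <- which(!is.na(W[, ii]) & W[, ii] >= 1)
  setdiff(node_names(graph)[partners], node_names(graph)[ii])
}

#' Local sufficient-bridge fraction of a node
#'
#' `LB_i`: the proportion of a node's bridge partners `x` (members of `B_i`)
#' for which the outgoing bridge `i -> x` is sufficiently wide
#' (`W_ix >= effective_threshold(x)`). Partnerhood is judged on the incoming
#' width `W_vi` while sufficiency is judged on the outgoing width `W_ix`,
#' following the two formal definitions literally. A node with no bridge
#' partners gets `LB_i = 0` (degenerate, reported via message).
#'
#' @inheritParams bridge_partners
#' @return A single value in `[0, 1]`.
#' @export
local_sufficiency <- function(graph, i, thresholds) {
  graph <- as_cc_graph(graph)
  ii <- node_index(graph, i)
  W <- bridge_width_matrix(graph, thresholds)
  teff <- as.numeric(effective_threshold(graph, thresholds))
  lb_from_matrix(W, teff, ii)
}

lb_from_matrix <- function(W, teff, ii) {
  partners <- which(!is.na(W[, ii]) & W[, ii] >= 1)
  partners <- setdiff(partners, ii)
  if (length(partners) == 0) {
    message("local_sufficiency: node has no bridge partners, LB_i = 0")
    return(0)
  }
  mean(W[ii, partners] >= teff[partners])
}

#' Graph-level fraction of locally sufficient bridges
#'
#' `LB`: the mean of `LB_i` over all nodes — the fraction of neighbourhood
#' bridges in the graph wide enough to carry the contagion, a connectedness
#' measure for complex contagions.
#'
#' @inheritParams bridge_report
#' @return A single value in `[0, 1]`.
#' @examples
#' g <- generate_rewired_lattice(20, 4, 0)
#' th <- assign_thresholds(g, "absolute", 2)
#' graph_lb(g, th)
#' @export
graph_lb <- function(graph, thresholds) {
  graph <- as_cc_graph(graph)
  n <- igraph::vcount(graph)
  W <- bridge_width_matrix(graph, thresholds)
  teff <- as.numeric(effective_threshold(graph, thresholds))
  suff <- sweep(W, 2, teff, ">=")           # suff[i, x] = [W_ix]
  lb_i <- vapply(seq_len(n), function(ii) {
    partners <- which(!is.na(W[, ii]) & W[, ii] >= 1)
    partners <- setdiff(partners, ii)
    if (length(partners) == 0) return(0)
    mean(suff[ii, partners])
  }, numeric(1))
  mean(lb_i)
}
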