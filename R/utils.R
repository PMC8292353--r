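# Internal helpers shared across modules. All public functions operate on
# undirected simple igraph objects whose vertices carry character names;
# these helpers normalise inputs and build the index-based structures the
# numeric cores work with.

# Validate and normalise a graph argument: undirected, simple, named.
as_cc_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) {
    stop("`graph` must be an igraph object", call. = FALSE)
  }
  if (igraph::is_directed(graph)) {
    stop("`graph` must be undirected", call. = FALSE)
  }
  if (!igraph::is_simple(graph)) {
    stop("`graph` must be simple (no self-loops or multi-edges)", call. = FALSE)
  }
  if (igraph::vcount(graph) < 1) {
    stop("`graph` must have at least one node", call. = FALSE)
  }
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  graph
}

node_names <- function(graph) igraph::V(graph)$name

# Map node labels (or numeric indices) to integer vertex indices.
node_index <- function(graph, nodes) {
  if (is.numeric(nodes)) {
    idx <- as.integer(nodes)
    if (any(idx < 1L | idx > igraph::vcount(graph))) {
      stop("node index out of range", call. = FALSE)
    }
    return(idx)
  }
  idx <- match(as.character(nodes), node_names(graph))
  if (anyNA(idx)) {
    stop("unknown node label(s): ",
         paste(nodes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

# Sparse 0/1 adjacency (dgCMatrix) used by the diffusion and bridge cores.
adj_sparse <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  methods::as(A, "dMatrix")
}

# Open adjacency as a list of integer vectors.
adj_list_int <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
}

# Closed neighbourhoods N[i] as a list of sorted integer vectors.
closed_nb_list <- function(graph) {
  al <- adj_list_int(graph)
  lapply(seq_along(al), function(i) sort(c(i, al[[i]])))
}

# Evaluate `expr` under a local RNG seed when one is supplied, without
# disturbing the caller's RNG stream; with seed = NULL the current stream
# is consumed as usual.
with_seed_opt <- function(rng_seed, expr) {
  if (is.null(rng_seed)) {
    expr
  } else {
    withr::with_seed(as.integer(rng_seed), expr)
  }
}

# Deterministic per-task seed derivation from an experiment master seed.
# Keeps derived seeds in the 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 65011 * 32999 + as.numeric(index)) %%
               2147483629 + 1)
}

#' Min-max normalisation
#'
#' Rescales a numeric vector to `[0, 1]`. A constant vector (degenerate
#' normalisation) is mapped to all zeros with a message, so that downstream
#' averaging stays defined.
#'
#' @param x Numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_scale <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    message("minmax_scale: constant column, returning zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}
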