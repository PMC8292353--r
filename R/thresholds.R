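# Adoption thresholds. A threshold assignment stores, for every node, the
# number (absolute mode) or fraction (fractional mode) of neighbours that
# must be active before the node adopts. Assignments are either homogeneous
# (one value for all nodes) or heterogeneous (independent uniform draws from
# an interval: integers in absolute mode, reals in fractional mode).

new_threshold_assignment <- function(mode, values, heterogeneous, spec) {
  structure(
    list(mode = mode, values = values,
         heterogeneous = heterogeneous, spec = spec),
    class = "threshold_assignment"
  )
}

#' Assign adoption thresholds to every node
#'
#' @param graph An undirected simple igraph.
#' @param mode `"absolute"` (threshold = count of active neighbours) or
#'   `"fractional"` (threshold = fraction of neighbours, in `(0, 1]`).
#' @param spec A single value for a homogeneous assignment, or a length-2
#'   interval `c(lo, hi)` for a heterogeneous one. Heterogeneous absolute
#'   thresholds are uniform integers on `lo..hi`; heterogeneous fractional
#'   thresholds are uniform reals on `[lo, hi]`.
#' @param rng_seed Optional seed making heterogeneous draws reproducible.
#' @return A `threshold_assignment` with per-node `values` named by node.
#' @examples
#' g <- generate_rewired_lattice(10, 4, 0)
#' assign_thresholds(g, "absolute", 2)
#' assign_thresholds(g, "fractional", c(0.1, 0.5), rng_seed = 1)
#' @export
assign_thresholds <- function(graph, mode = c("absolute", "fractional"),
                              spec, rng_seed = NULL) {
  graph <- as_cc_graph(graph)
  mode <- match.arg(mode)
  n <- igraph::vcount(graph)
  if (!is.numeric(spec) || !length(spec) %in% 1:2) {
    stop("`spec` must be a single threshold or an interval c(lo, hi)",
         call. = FALSE)
  }
  check_one <- function(v) {
    if (mode == "absolute") {
      if (v < 1 || v != round(v)) {
        stop("absolute thresholds must be integers >= 1", call. = FALSE)
      }
    } else if (v <= 0 || v > 1) {
      stop("fractional thresholds must lie in (0, 1]", call. = FALSE)
    }
  }
  for (v in spec) check_one(v)

  if (length(spec) == 1) {
    values <- rep(as.numeric(spec), n)
    het <- FALSE
  } else {
    if (spec[1] > spec[2]) stop("`spec` interval must have lo <= hi", call. = FALSE)
    values <- with_seed_opt(rng_seed, {
      if (mode == "absolute") {
        pool <- seq.int(as.integer(spec[1]), as.integer(spec[2]))
        as.numeric(pool[sample.int(length(pool), n, replace = TRUE)])
      } else {
        runif(n, spec[1], spec[2])
      }
    })
    het <- TRUE
  }
  names(values) <- node_names(graph)
  new_threshold_assignment(mode, values, het, spec)
}

#' @export
print.threshold_assignment <- function(x, ...) {
  kind <- if (x$heterogeneous) {
    sprintf("heterogeneous uniform [%g, %g]", x$spec[1], x$spec[2])
  } else {
    sprintf("homogeneous %g", x$spec[1])
  }
  cat(sprintf("<threshold_assignment> %s, %s; %d nodes\n",
              x$mode, kind, length(x$values)))
  invisible(x)
}

#' Effective (integer) adoption threshold of nodes
#'
#' Converts a threshold assignment to the integer count of active neighbours
#' each node requires. Absolute thresholds pass through; a fractional
#' threshold `T_i` becomes `ceiling(T_i * degree(i))`, floored at 1 — the
#' smallest neighbour count satisfying the stated fraction. An isolated node
#' in fractional mode degenerates to 1 (it can then only adopt by being
#' seeded) and is reported via a message.
#'
#' @param graph The graph the assignment was made on.
#' @param thresholds A [assign_thresholds()] result.
#' @param nodes Optional node labels/indices; default all nodes.
#' @return Named integer vector of effective thresholds.
#' @export
effective_threshold <- function(graph, thresholds, nodes = NULL) {
  graph <- as_cc_graph(graph)
  stopifnot(inherits(thresholds, "threshold_assignment"))
  idx <- if (is.null(nodes)) seq_len(igraph::vcount(graph)) else node_index(graph, nodes)
  vals <- thresholds$values[node_names(graph)[idx]]
  if (anyNA(vals)) stop("threshold assignment does not cover all nodes", call. = FALSE)
  if (thresholds$mode == "absolute") {
    teff <- as.integer(round(vals))
  } else {
    deg <- igraph::degree(graph)[idx]
    if (any(deg == 0)) {
      message("effective_threshold: isolated node(s) in fractional mode, using 1")
    }
    teff <- pmax(1L, as.integer(ceiling(vals * deg)))
  }
  setNames(teff, node_names(graph)[idx])
}
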