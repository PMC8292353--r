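# Diffusion models. The primary model is the synchronous threshold cascade:
# at each discrete step every inactive node counts its active neighbours and
# adopts when the count reaches its effective threshold; active nodes stay
# active. Because the update is monotone, the synchronous fixed point equals
# the fixed point of any asynchronous scan order, and is the unique minimal
# fixed point containing the seed set. Independent Cascade and Linear
# Threshold are provided as robustness models.

new_activation_trace <- function(times, seeds, steps) {
  structure(
    list(activation_time = times, seeds = seeds, steps = steps,
         n = length(times)),
    class = "activation_trace"
  )
}

#' @export
print.activation_trace <- function(x, ...) {
  cat(sprintf("<activation_trace> %d/%d nodes active, %d seed(s), %d step(s)\n",
              sum(!is.na(x$activation_time)), x$n, length(x$seeds), x$steps))
  invisible(x)
}

#' Nodes active at fixation
#'
#' @param trace An `activation_trace`.
#' @return Character vector of active node labels.
#' @export
active_nodes <- function(trace) {
  stopifnot(inherits(trace, "activation_trace"))
  names(trace$activation_time)[!is.na(trace$activation_time)]
}

# Synchronous threshold cascade on a sparse adjacency matrix.
# Returns activation times (NA = never) as a plain numeric vector.
threshold_cascade_core <- function(A, teff, seed_idx) {
  n <- nrow(A)
  times <- rep(NA_real_, n)
  active <- rep(FALSE, n)
  if (length(seed_idx) > 0) {
    active[seed_idx] <- TRUE
    times[seed_idx] <- 0
  }
  t <- 0L
  while (any(active)) {
    counts <- as.numeric(A %*% active)
    newly <- which(!active & counts >= teff)
    if (length(newly) == 0) break
    t <- t + 1L
    active[newly] <- TRUE
    times[newly] <- t
  }
  list(times = times, steps = t)
}

#' Run the synchronous threshold contagion model
#'
#' Seeds are activated at time 0; at every subsequent step each inactive
#' node whose number of active neighbours reaches its effective threshold
#' (see [effective_threshold()]) adopts. The run is deterministic given
#' graph, thresholds and seeds, and stops at fixation (a full step with no
#' new activation).
#'
#' @param graph An undirected simple igraph.
#' @param thresholds A [assign_thresholds()] result.
#' @param seeds Node labels (or indices) active at time 0; may be empty.
#' @return An `activation_trace`: per-node activation time (`NA` = never),
#'   the seed set and the number of steps to fixation.
#' @examples
#' g <- generate_rewired_lattice(20, 4, 0)
#' th <- assign_thresholds(g, "absolute", 2)
#' run_threshold_model(g, th, seeds = c("1", "2"))
#' @export
run_threshold_model <- function(graph, thresholds, seeds) {
  graph <- as_cc_graph(graph)
  teff <- effective_threshold(graph, thresholds)
  seed_idx <- if (length(seeds) == 0) integer(0) else unique(node_index(graph, seeds))
  res <- threshold_cascade_core(adj_sparse(graph), as.numeric(teff), seed_idx)
  new_activation_trace(setNames(res$times, node_names(graph)),
                       node_names(graph)[seed_idx], res$steps)
}

#' Run the Independent Cascade model
#'
#' Each node, on the step after it becomes active, gets a single chance to
#' activate each currently inactive neighbour, independently with
#' probability `theta`.
#'
#' @param graph An undirected simple igraph.
#' @param theta Per-edge activation probability in `[0, 1]`.
#' @param seeds Node labels active at time 0.
#' @param rng_seed Optional seed for reproducibility.
#' @return An `activation_trace`.
#' @export
run_independent_cascade <- function(graph, theta, seeds, rng_seed = NULL) {
  graph <- as_cc_graph(graph)
  if (!is.numeric(theta) || theta < 0 || theta > 1) {
    stop("`theta` must be a probability in [0, 1]", call. = FALSE)
  }
  al <- adj_list_int(graph)
  n <- igraph::vcount(graph)
  seed_idx <- if (length(seeds) == 0) integer(0) else unique(node_index(graph, seeds))

  with_seed_opt(rng_seed, {
    times <- rep(NA_real_, n)
    active <- rep(FALSE, n)
    active[seed_idx] <- TRUE
    times[seed_idx] <- 0
    frontier <- seed_idx
    t <- 0L
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        targets <- al[[u]][!active[al[[u]]]]
        if (length(targets) == 0) next
        hit <- targets[runif(length(targets)) < theta]
        nxt <- c(nxt, hit)
      }
      nxt <- unique(nxt)
      if (length(nxt) == 0) break
      t <- t + 1L
      active[nxt] <- TRUE
      times[nxt] <- t
      frontier <- nxt
    }
    new_activation_trace(setNames(times, node_names(graph)),
                         node_names(graph)[seed_idx], t)
  })
}

#' Run the Linear Threshold model
#'
#' Each node draws a private threshold uniformly on `(0, 1)` once per run;
#' every neighbour of a node `j` carries influence weight `1/degree(j)`.
#' A node adopts when the summed weight of its active neighbours reaches its
#' private threshold; updates are synchronous and monotone.
#'
#' @param graph An undirected simple igraph.
#' @param seeds Node labels active at time 0.
#' @param rng_seed Optional seed (thresholds are redrawn per run).
#' @return An `activation_trace`.
#' @export
run_linear_threshold <- function(graph, seeds, rng_seed = NULL) {
  graph <- as_cc_graph(graph)
  n <- igraph::vcount(graph)
  A <- adj_sparse(graph)
  deg <- igraph::degree(graph)
  seed_idx <- if (length(seeds) == 0) integer(0) else unique(node_index(graph, seeds))

  with_seed_opt(rng_seed, {
    u <- runif(n)
    times <- rep(NA_real_, n)
    active <- rep(FALSE, n)
    active[seed_idx] <- TRUE
    times[seed_idx] <- 0
    t <- 0L
    while (any(active)) {
      counts <- as.numeric(A %*% active)
      frac <- ifelse(deg > 0, counts / deg, 0)
      newly <- which(!active & frac >= u)
      if (length(newly) == 0) break
      t <- t + 1L
      active[newly] <- TRUE
      times[newly] <- t
    }
    new_activation_trace(setNames(times, node_names(graph)),
                         node_names(graph)[seed_idx], t)
  })
}

#' Build a clustered seed set around a focal node
#'
#' Returns the focal node plus `budget - 1` further seeds: first a uniform
#' random subset of the focal node's neighbours; if the budget exceeds the
#' neighbourhood size, the set is extended by iteratively sampling nodes
#' adjacent to already-selected nodes (clustered seeding). If the candidate
#' pool runs dry the smaller set is returned with a warning.
#'
#' @param graph An undirected simple igraph.
#' @param focal Focal node label or index.
#' @param budget Total number of seeds (>= 1).
#' @param rng_seed Optional seed for the random neighbour choices.
#' @return Character vector of seed labels (focal first).
#' @export
build_seed_set <- function(graph, focal, budget, rng_seed = NULL) {
  graph <- as_cc_graph(graph)
  if (!is.numeric(budget) || budget < 1) stop("`budget` must be >= 1", call. = FALSE)
  budget <- as.integer(budget)
  f <- node_index(graph, focal)
  al <- adj_list_int(graph)

  with_seed_opt(rng_seed, {
    selected <- f
    nb <- al[[f]]
    take <- min(budget - 1L, length(nb))
    if (take > 0) {
      selected <- c(selected, nb[sample.int(length(nb), take)])
    }
    while (length(selected) < budget) {
      cand <- setdiff(unique(unlist(al[selected])), selected)
      if (length(cand) == 0) {
        warning("seed budget ", budget, " not reachable from focal node; ",
                "returning ", length(selected), " seed(s)", call. = FALSE)
        break
      }
      selected <- c(selected, cand[sample.int(length(cand), 1L)])
    }
    node_names(graph)[selected]
  })
}

#' Summarise a diffusion run
#'
#' @param trace An `activation_trace`.
#' @param n Population size; defaults to the trace's node count.
#' @param cascade_fraction Adoption fraction at or above which a run counts
#'   as a global cascade (default 0.5, inclusive).
#' @return List with `adoption_fraction` and `is_global_cascade`.
#' @export
cascade_outcome <- function(trace, n = trace$n, cascade_fraction = 0.5) {
  stopifnot(inherits(trace, "activation_trace"))
  frac <- sum(!is.na(trace$activation_time)) / n
  list(adoption_fraction = frac,
       is_global_cascade = frac >= cascade_fraction)
}
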