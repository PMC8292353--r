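# Experiment harness. Three designs:
#   * run_cascade_vs_lb: locally sufficient bridge fraction vs global
#     cascade frequency on degree-preserving rewired lattices, across the
#     rewiring probability grid and threshold regimes;
#   * run_plc_vs_adoption: graph-level complex path length vs mean adoption
#     over all neighbourhood seedings on clustering-tunable scale-free
#     graphs, under fractional threshold regimes;
#   * run_seeding_tournament: head-to-head comparison of seeding strategies
#     (complex centrality vs classical baselines) on a set of networks.
# Every run is reproducible from (config, rng_seed): per-task seeds are
# derived from the master seed with a fixed counter scheme, so serial and
# re-ordered execution agree.

#' Build an experiment configuration
#'
#' A flat list of parameters with defaults at desk scale. Unknown names are
#' rejected so typos do not silently fall back to defaults.
#'
#' @param ... Named parameters overriding the defaults: `n`, `k`, `m`,
#'   `triad_p`, `p_grid`, `tmode`, `t_specs` (list of threshold specs:
#'   scalars for homogeneous regimes, length-2 vectors for heterogeneous
#'   ones), `realizations`, `trials`, `cascade_fraction`, `t_values`
#'   (tournament threshold range), `strategies`, `d`, `rng_seed`, `n_boot`.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    n = 200, k = 8, m = 4, triad_p = 0.5,
    p_grid = c(0, 0.1, 0.5, 1),
    tmode = "absolute",
    t_specs = list(2, 3, 4),
    realizations = 10,
    trials = 1,
    cascade_fraction = 0.5,
    t_values = 2:6,
    strategies = c("complex", "degree", "betweenness", "eigenvector",
                   "k_core", "percolation"),
    d = 3,
    rng_seed = 1L,
    n_boot = 1000
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop("unknown config parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "experiment_config")
}

t_spec_label <- function(spec) {
  if (length(spec) == 1) sprintf("T=%g", spec)
  else sprintf("T~U[%g,%g]", spec[1], spec[2])
}

#' Sufficient-bridge fraction vs cascade frequency on rewired lattices
#'
#' For every rewiring probability in `p_grid`, threshold regime in `t_specs`
#' and realization: generate a k-regular rewired lattice, compute the
#' graph-level locally sufficient bridge fraction `LB`, and estimate the
#' global cascade frequency by seeding every focal node with
#' `effective_threshold(focal)` seeds (the focal node plus threshold-minus-1
#' neighbours) and averaging the global-cascade indicator over all focal
#' nodes (and `trials` repeats of the random neighbour choice).
#'
#' @param config An [experiment_config()]; uses `n`, `k`, `p_grid`, `tmode`,
#'   `t_specs`, `realizations`, `trials`, `cascade_fraction`, `rng_seed`.
#' @return Data.frame with one row per `(p, threshold regime)` cell:
#'   mean `lb`, mean `cascade_frequency`, `mean_adoption`, `connected`
#'   fraction, and `realizations`. Per-realization rows are in the
#'   `"detail"` attribute.
#' @export
run_cascade_vs_lb <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  task <- 0L
  for (p in config$p_grid) {
    for (spec in config$t_specs) {
      for (r in seq_len(config$realizations)) {
        task <- task + 1L
        gseed <- derive_seed(config$rng_seed, task * 3L)
        g <- generate_rewired_lattice(config$n, config$k, p, rng_seed = gseed)
        th <- assign_thresholds(g, config$tmode, spec,
                                rng_seed = derive_seed(config$rng_seed, task * 3L + 1L))
        lb <- graph_lb(g, th)
        cf <- cascade_frequency(g, th, config$trials, config$cascade_fraction,
                                derive_seed(config$rng_seed, task * 3L + 2L))
        rows[[task]] <- data.frame(
          p = p, threshold = t_spec_label(spec), realization = r,
          lb = lb, cascade_frequency = cf$cascade_frequency,
          mean_adoption = cf$mean_adoption,
          connected = igraph::is_connected(g),
          stringsAsFactors = FALSE)
      }
    }
  }
  detail <- do.call(rbind, rows)
  agg <- stats::aggregate(
    cbind(lb, cascade_frequency, mean_adoption, connected) ~ p + threshold,
    data = detail, FUN = mean)
  agg$realizations <- config$realizations
  attr(agg, "detail") <- detail
  agg
}

# Cascade frequency over all focal nodes for one (graph, thresholds).
cascade_frequency <- function(graph, thresholds, trials, cascade_fraction,
                              rng_seed) {
  n <- igraph::vcount(graph)
  nm <- node_names(graph)
  teff <- as.numeric(effective_threshold(graph, thresholds))
  A <- adj_sparse(graph)
  globals <- numeric(0)
  adopts <- numeric(0)
  al <- adj_list_int(graph)
  counter <- 0L
  for (ii in seq_len(n)) {
    for (tr in seq_len(trials)) {
      counter <- counter + 1L
      seeds <- seed_idx_clustered(al, ii, teff[ii],
                                  derive_seed(rng_seed, counter))
      res <- threshold_cascade_core(A, teff, seeds)
      frac <- sum(!is.na(res$times)) / n
      adopts <- c(adopts, frac)
      globals <- c(globals, frac >= cascade_fraction)
    }
  }
  list(cascade_frequency = mean(globals), mean_adoption = mean(adopts))
}

# index-level clustered seeding (same rule as build_seed_set, no igraph
# round-trips; silent truncation when the pool runs dry)
seed_idx_clustered <- function(al, focal, budget, rng_seed) {
  with_seed_opt(rng_seed, {
    selected <- focal
    nb <- al[[focal]]
    take <- min(budget - 1L, length(nb))
    if (take > 0) selected <- c(selected, nb[sample.int(length(nb), take)])
    while (length(selected) < budget) {
      cand <- setdiff(unique(unlist(al[selected])), selected)
      if (length(cand) == 0) break
      selected <- c(selected, cand[sample.int(length(cand), 1L)])
    }
    selected
  })
}

#' Complex path length vs adoption on scale-free graphs
#'
#' For every threshold regime in `t_specs` and realization: generate a
#' clustering-tunable scale-free graph, assign fractional thresholds,
#' compute the graph-level complex path length `PL_c` and the mean final
#' adoption fraction over all neighbourhood seedings (both from the same
#' per-node spreads), then correlate `PL_c` with adoption across all rows
#' (Spearman, two-tailed, bootstrap CI).
#'
#' @param config An [experiment_config()]; uses `n`, `m`, `triad_p`,
#'   `t_specs` (fractional), `realizations`, `rng_seed`, `n_boot`.
#' @return Data.frame with one row per `(threshold regime, realization)`:
#'   `plc` and `mean_adoption`; the Spearman summary is in the `"summary"`
#'   attribute.
#' @export
run_plc_vs_adoption <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  task <- 0L
  for (spec in config$t_specs) {
    for (r in seq_len(config$realizations)) {
      task <- task + 1L
      g <- generate_scale_free(config$n, config$m, config$triad_p,
                               rng_seed = derive_seed(config$rng_seed, task * 2L))
      th <- assign_thresholds(g, "fractional", spec,
                              rng_seed = derive_seed(config$rng_seed, task * 2L + 1L))
      prof <- complex_path_profile(g, th)
      rows[[task]] <- data.frame(
        graph_id = task, threshold = t_spec_label(spec), realization = r,
        plc = mean(prof$plc), mean_adoption = mean(prof$adoption_fraction),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- summarize_experiment(
    out$plc, out$mean_adoption, stat = "spearman",
    n_boot = config$n_boot, rng_seed = derive_seed(config$rng_seed, 999983L))
  out
}

#' Seeding-strategy tournament
#'
#' For each network and each homogeneous absolute threshold in `t_values`:
#' identify the most central node under every strategy, seed it together
#' with threshold-minus-1 of its neighbours ([build_seed_set()]), simulate
#' `trials` threshold cascades and record the mean adoption. Adoption and
#' the chosen focal's complex centrality are min-max normalised within each
#' (network, threshold) cell across strategies, then averaged over
#' thresholds. Paired Wilcoxon signed-rank tests compare the complex
#' strategy against every baseline across networks, and the association
#' between a chosen focal's complex centrality and its adoption is
#' summarised by Spearman and Pearson correlations over all records.
#'
#' @param config An [experiment_config()]; uses `t_values`, `strategies`,
#'   `trials`, `d`, `rng_seed`.
#' @param networks A list of undirected simple igraphs.
#' @return List with `records` (one row per network x threshold x strategy),
#'   `by_strategy` (normalised adoption averaged over thresholds, one row
#'   per network x strategy), `comparisons` (Wilcoxon complex vs baseline)
#'   and `association` (correlation between focal complex centrality and
#'   adoption, both normalised).
#' @export
run_seeding_tournament <- function(config, networks) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(networks) < 1) stop("need at least one network", call. = FALSE)
  strategies <- config$strategies
  baselines <- setdiff(strategies, "complex")
  records <- list()
  rec <- 0L

  for (net_id in seq_along(networks)) {
    g <- as_cc_graph(networks[[net_id]])
    base_tab <- baseline_centralities(g, measures = baselines, d = config$d)
    for (tv in config$t_values) {
      th <- assign_thresholds(g, "absolute", tv)
      cc <- complex_centrality(g, th)
      cell <- list()
      for (s in strategies) {
        scores <- if (s == "complex") cc else setNames(base_tab[[s]], base_tab$node)
        focal <- top_node(scores)
        rec <- rec + 1L
        adopts <- vapply(seq_len(config$trials), function(tr) {
          sd <- derive_seed(config$rng_seed,
                            net_id * 100000L + tv * 1000L + tr * 10L + match(s, strategies))
          seeds <- build_seed_set(g, focal, tv, rng_seed = sd)
          cascade_outcome(run_threshold_model(g, th, seeds))$adoption_fraction
        }, numeric(1))
        cell[[s]] <- data.frame(
          network = net_id, threshold = tv, strategy = s, focal = focal,
          adoption = mean(adopts), focal_cc = unname(cc[focal]),
          stringsAsFactors = FALSE)
      }
      cell <- do.call(rbind, cell)
      cell$adoption_norm <- minmax_scale(cell$adoption)
      cell$focal_cc_norm <- minmax_scale(cell$focal_cc)
      records[[length(records) + 1L]] <- cell
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  by_strategy <- stats::aggregate(
    cbind(adoption_norm, adoption, focal_cc_norm) ~ network + strategy,
    data = records, FUN = mean)

  comparisons <- lapply(baselines, function(b) {
    x <- by_strategy$adoption_norm[by_strategy$strategy == "complex"]
    y <- by_strategy$adoption_norm[by_strategy$strategy == b]
    s <- summarize_experiment(x, y, stat = "wilcoxon",
                              n_boot = config$n_boot,
                              rng_seed = derive_seed(config$rng_seed, 777L))
    data.frame(baseline = b, mean_difference = mean(x - y),
               statistic = s$statistic, p_value = s$p_value,
               degenerate = s$degenerate, stringsAsFactors = FALSE)
  })
  comparisons <- do.call(rbind, comparisons)

  association <- if (nrow(records) >= 3 &&
                     stats::sd(records$focal_cc_norm) > 0 &&
                     stats::sd(records$adoption_norm) > 0) {
    list(
      spearman = summarize_experiment(records$focal_cc_norm,
                                      records$adoption_norm,
                                      stat = "spearman",
                                      n_boot = config$n_boot,
                                      rng_seed = derive_seed(config$rng_seed, 778L)),
      pearson = suppressWarnings(
        stats::cor.test(records$focal_cc_norm, records$adoption_norm))
    )
  } else {
    NULL
  }

  list(records = records, by_strategy = by_strategy,
       comparisons = comparisons, association = association)
}

#' Summary statistics for experiment tables
#'
#' @param x,y Numeric vectors: the two correlated columns (`spearman`), the
#'   two paired columns (`wilcoxon`), or for `minmax_mean` the values in `x`
#'   and their grouping factor in `y`.
#' @param stat One of `"spearman"`, `"wilcoxon"`, `"minmax_mean"`.
#' @param n_boot Bootstrap resamples for the 95 percent CI (spearman).
#' @param rng_seed Optional seed for the bootstrap.
#' @return A list with `statistic`, `p_value` (where defined), `n`, `ci`
#'   and, for wilcoxon, a `degenerate` flag set when all paired differences
#'   are zero.
#' @export
summarize_experiment <- function(x, y, stat = c("spearman", "wilcoxon",
                                                "minmax_mean"),
                                 n_boot = 10000, rng_seed = NULL) {
  stat <- match.arg(stat)
  if (stat == "spearman") {
    if (length(x) < 3) stop("need at least 3 observations for a correlation",
                            call. = FALSE)
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", alternative = "two.sided"))
    boot <- with_seed_opt(rng_seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(x), replace = TRUE)
        suppressWarnings(stats::cor(x[idx], y[idx], method = "spearman"))
      }, numeric(1))
    })
    list(statistic = unname(ct$estimate), p_value = ct$p.value,
         n = length(x),
         ci = unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE)))
  } else if (stat == "wilcoxon") {
    if (length(x) != length(y)) stop("paired columns differ in length", call. = FALSE)
    diffs <- x - y
    if (all(diffs == 0)) {
      return(list(statistic = NA_real_, p_value = NA_real_, n = length(x),
                  ci = c(0, 0), degenerate = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              alternative = "two.sided"))
    boot <- with_seed_opt(rng_seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(diffs), replace = TRUE)
        mean(diffs[idx])
      }, numeric(1))
    })
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n = length(x),
         ci = unname(quantile(boot, c(0.025, 0.975))), degenerate = FALSE)
  } else {
    groups <- as.factor(y)
    normed <- unsplit(lapply(split(x, groups), minmax_scale), groups)
    list(statistic = mean(normed), p_value = NA_real_, n = length(x),
         ci = c(NA_real_, NA_real_))
  }
}
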