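# Topology diagnostics of the drug similarity network: degree distribution
# against a discrete power law (maximum likelihood + Kolmogorov-Smirnov
# bootstrap), nominal assortativity by toxicity class, greedy modularity,
# and degree-preserving rewired reference networks at the extremes of the
# assortativity and modularity ranges. All computations treat the network
# as unweighted (links present or absent).

# coerce a network_bundle or igraph graph to an undirected simple graph
as_graph <- function(network) {
  g <- if (inherits(network, "network_bundle")) as_igraph(network) else network
  if (!igraph::is_igraph(g)) {
    stop_dilinet("network must be a network_bundle or an igraph graph",
                 class = "dilinet_validation_error")
  }
  igraph::as_undirected(g, mode = "collapse")
}

#' Empirical degree distribution
#'
#' @param network A `network_bundle` or igraph graph with at least one node.
#' @return Named numeric vector: degree k -> probability P_k, summing to 1;
#'   isolated nodes contribute to P_0.
#' @export
degree_distribution_table <- function(network) {
  g <- as_graph(network)
  if (igraph::vcount(g) == 0L) {
    stop_dilinet("network has no nodes", class = "dilinet_validation_error")
  }
  tab <- table(igraph::degree(g))
  p <- as.numeric(tab) / igraph::vcount(g)
  names(p) <- names(tab)
  p
}

#' Sample a discrete power law
#'
#' Exact inverse-CDF sampling from the (truncated) zeta distribution
#' `P(k) proportional to k^-alpha`, `k >= xmin`; support truncated at
#' `xmin + 1e6` where the omitted tail mass is negligible for the exponents
#' used here.
#'
#' @param n Sample size.
#' @param alpha Exponent (> 1).
#' @param xmin Lower bound of the support.
#' @return Integer vector of length `n`.
#' @export
rpl_discrete <- function(n, alpha, xmin, cap = xmin + 1e6) {
  stopifnot(alpha > 1, xmin >= 1)
  ks <- xmin:cap
  cdf <- cumsum(ks^(-alpha))
  cdf <- cdf / cdf[length(cdf)]
  ks[findInterval(runif(n), cdf) + 1L]
}

# discrete MLE with xmin chosen to minimise the KS distance among
# candidates whose tail retains at least a min_tail_frac share of the data
# (the fit then describes the bulk of the distribution, not just an
# arbitrarily small extreme tail)
fit_pl <- function(x, min_tail_frac = 0.5) {
  min_tail <- max(2L, ceiling(min_tail_frac * length(x)))
  cands <- sort(unique(x))
  keep <- vapply(cands, function(v) sum(x >= v), 1L) >= min(min_tail, length(x))
  # need at least two distinct values at or above xmin for a non-degenerate fit
  keep <- keep & vapply(cands, function(v) sum(x > v) >= 1L, TRUE)
  cands <- cands[keep]
  if (!length(cands)) cands <- min(x)
  fits <- lapply(cands, function(v) {
    igraph::fit_power_law(x, xmin = v, implementation = "plfit")
  })
  ks <- vapply(fits, function(f) f$KS.stat, numeric(1))
  f <- fits[[which.min(ks)]]
  list(alpha = f$alpha, xmin = f$xmin, ks = f$KS.stat)
}

#' Discrete power-law fit with bootstrap goodness of fit
#'
#' Fits a discrete power law to a degree sequence by maximum likelihood,
#' choosing `xmin` to minimise the Kolmogorov-Smirnov distance (among
#' cutoffs retaining at least half the positive degrees, so the fit speaks
#' for the distribution rather than a vanishing tail), then assesses
#' goodness of fit with a semi-parametric bootstrap: each synthetic sample
#' redraws the tail from the fitted law ([rpl_discrete()]) and the body
#' from the empirical data below `xmin`, is refitted, and contributes its
#' KS distance. The p-value is the fraction of synthetic samples fitting
#' worse than the data; a small p-value rejects the power law.
#'
#' @param degrees Integer vector of node degrees; zeros are dropped and at
#'   least 10 positive degrees are required.
#' @param n_bootstrap Number of bootstrap samples (default 100).
#' @param seed RNG seed for the bootstrap.
#' @return List: `exponent`, `xmin`, `ks_statistic`, `ks_p_value`,
#'   `n_tail` (observations at or above `xmin`).
#' @export
powerlaw_goodness_of_fit <- function(degrees, n_bootstrap = 100, seed = 1L) {
  x <- degrees[degrees > 0]
  if (length(x) < 10L) {
    stop_dilinet("need at least 10 positive degrees, got ", length(x),
                 class = "dilinet_validation_error")
  }
  if (length(unique(x)) == 1L) {
    stop_dilinet("all degrees are equal; power-law fit is degenerate",
                 class = "dilinet_degenerate_error")
  }
  obs <- fit_pl(x)
  n <- length(x)
  body <- x[x < obs$xmin]
  p_tail <- (n - length(body)) / n
  set.seed(seed)
  ks_boot <- vapply(seq_len(n_bootstrap), function(i) {
    n_tail <- rbinom(1L, n, p_tail)
    y <- c(rpl_discrete(n_tail, obs$alpha, obs$xmin),
           if (n - n_tail > 0L) sample(body, n - n_tail, replace = TRUE))
    fit_pl(y)$ks
  }, numeric(1))
  list(exponent = obs$alpha, xmin = obs$xmin, ks_statistic = obs$ks,
       ks_p_value = mean(ks_boot >= obs$ks), n_tail = sum(x >= obs$xmin))
}

#' Scale-free reference network
#'
#' Preferential-attachment graph matched to a target node and edge count, as
#' a size-matched scale-free comparison for an observed degree
#' distribution. Edges added per step are distributed as evenly as integral
#' attachment allows.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param n_edges Number of edges; must be achievable
#'   (`<= choose(n_nodes, 2)`).
#' @param seed RNG seed; the same seed reproduces the same edge list.
#' @return An undirected igraph graph with exactly `n_nodes` nodes and
#'   `n_edges` edges.
#' @export
scale_free_reference <- function(n_nodes, n_edges, seed = 1L) {
  if (!is_count(n_nodes, 2) || !is_count(n_edges, 1) ||
      n_edges > choose(n_nodes, 2)) {
    stop_dilinet("infeasible size: ", n_edges, " edges on ", n_nodes, " nodes",
                 class = "dilinet_validation_error")
  }
  # distribute n_edges over attachment steps 2..n, capped at i-1 new links
  out_seq <- integer(n_nodes)
  remaining <- n_edges
  for (i in 2:n_nodes) {
    take <- min(i - 1L, ceiling(remaining / (n_nodes - i + 1L)))
    take <- min(take, remaining)
    out_seq[i] <- take
    remaining <- remaining - take
  }
  # push any leftover into steps with spare capacity
  i <- n_nodes
  while (remaining > 0L && i >= 2L) {
    spare <- (i - 1L) - out_seq[i]
    add <- min(spare, remaining)
    out_seq[i] <- out_seq[i] + add
    remaining <- remaining - add
    i <- i - 1L
  }
  if (remaining > 0L) {
    stop_dilinet("could not place all edges by preferential attachment",
                 class = "dilinet_validation_error")
  }
  set.seed(seed)
  igraph::sample_pa(n_nodes, out.seq = out_seq, directed = FALSE)
}

#' Nominal assortativity by node class
#'
#' Newman's nominal assortativity over discrete node labels: +1 when links
#' run only within classes, negative (down to -1 for a two-class network)
#' when they run only between classes.
#'
#' @param network A `network_bundle` or igraph graph.
#' @param labels Vector of class labels, either named by node id or in
#'   graph vertex order; for a `network_bundle`, defaults to the binary
#'   DILI split of `toxicity_class` (toxic/very_toxic vs the rest).
#' @return The assortativity coefficient in \[-1, 1\], or `NA` with a
#'   warning when only one class is present.
#' @export
assortativity_by_class <- function(network, labels = NULL) {
  g <- as_graph(network)
  if (is.null(labels)) {
    if (!inherits(network, "network_bundle")) {
      stop_dilinet("labels must be supplied for an igraph input",
                   class = "dilinet_validation_error")
    }
    labels <- setNames(
      ifelse(network$nodes$toxicity_class %in% DILI_CLASSES, "dili", "other"),
      network$nodes$drug_id)
  }
  if (!is.null(names(labels))) {
    labels <- labels[igraph::V(g)$name]
  }
  if (anyNA(labels) || length(labels) != igraph::vcount(g)) {
    stop_dilinet("every node needs a class label",
                 class = "dilinet_validation_error")
  }
  if (length(unique(labels)) < 2L) {
    warning("only one class present; assortativity is undefined")
    return(NA_real_)
  }
  igraph::assortativity_nominal(g, types = as.integer(factor(labels)),
                                directed = FALSE)
}

#' Greedy modularity of the best node partition
#'
#' Newman-Girvan modularity of the partition found by greedy agglomerative
#' optimisation (unweighted).
#'
#' @param network A `network_bundle` or igraph graph with at least one edge.
#' @return List: `M` (modularity) and `partition` (named membership
#'   vector).
#' @export
modularity_score <- function(network) {
  g <- as_graph(network)
  if (igraph::ecount(g) == 0L) {
    stop_dilinet("modularity is undefined for an edgeless network",
                 class = "dilinet_validation_error")
  }
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  memb <- igraph::membership(cl)
  M <- igraph::modularity(g, memb)
  # the trivial one-community partition always has Q = 0; never do worse
  # (greedy cuts can otherwise return a negative-Q split, e.g. on cliques)
  if (M < 0) {
    memb[] <- 1L
    M <- 0
  }
  list(M = M, partition = memb)
}

#' Rewire a network toward an assortativity or modularity extreme
#'
#' Degree-preserving double-edge-swap annealing that drives the network
#' toward the named extreme while keeping the exact degree sequence, so the
#' result is a fair size- and degree-matched reference. For assortativity
#' targets the objective is the count of within-class edges (equivalent to
#' the assortativity coefficient at fixed degrees); for modularity targets,
#' the count of edges inside the blocks of the input network's greedy
#' partition (equivalent to that partition's modularity at fixed degrees).
#'
#' @param network A `network_bundle` or igraph graph.
#' @param labels Node class labels (required for assortativity targets);
#'   same conventions as [assortativity_by_class()].
#' @param target One of `"assortative"`, `"unassortative"`, `"modular"`,
#'   `"unmodular"`.
#' @param seed RNG seed; the same seed reproduces the same result.
#' @param n_iter Number of proposed swaps (default `30 * n_edges`).
#' @return An igraph graph with identical node set and degree sequence.
#' @export
reference_extreme_networks <- function(network, labels = NULL,
                                       target = c("assortative", "unassortative",
                                                  "modular", "unmodular"),
                                       seed = 1L, n_iter = NULL) {
  target <- match.arg(target)
  g <- as_graph(network)
  m <- igraph::ecount(g)
  nv <- igraph::vcount(g)
  if (nv == 0L || m == 0L) {
    stop_dilinet("network must have nodes and edges",
                 class = "dilinet_validation_error")
  }
  if (m == choose(nv, 2)) {
    warning("complete graph cannot be rewired; returning input")
    return(g)
  }
  group <- if (target %in% c("assortative", "unassortative")) {
    if (is.null(labels)) {
      if (!inherits(network, "network_bundle")) {
        stop_dilinet("labels required for assortativity targets",
                     class = "dilinet_validation_error")
      }
      setNames(ifelse(network$nodes$toxicity_class %in% DILI_CLASSES,
                      "dili", "other"), network$nodes$drug_id)
    } else labels
  } else {
    as.vector(modularity_score(g)$partition)
  }
  if (!is.null(names(group))) group <- group[igraph::V(g)$name]
  group <- as.integer(factor(group))
  maximise <- target %in% c("assortative", "modular")

  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(m)) assign(pair_key(el[r, 1], el[r, 2]), TRUE, present)
  within <- function(a, b) as.integer(group[a] == group[b])
  obj <- sum(within(el[, 1], el[, 2]))
  best_el <- el
  best_obj <- obj

  n_iter <- n_iter %||% (30L * m)
  set.seed(seed)
  # geometric cooling; temperature in units of single-edge objective changes
  temps <- 0.5 * 0.995^seq_len(n_iter)
  pick <- sample.int(m, 2L * n_iter, replace = TRUE)
  cross <- runif(n_iter) < 0.5
  acc_u <- runif(n_iter)
  for (it in seq_len(n_iter)) {
    e1 <- pick[2L * it - 1L]
    e2 <- pick[2L * it]
    if (e1 == e2) next
    a <- el[e1, 1]; b <- el[e1, 2]; c <- el[e2, 1]; d <- el[e2, 2]
    # two swap orientations: (a,d)+(c,b) or (a,c)+(b,d)
    if (cross[it]) { n1 <- c(a, d); n2 <- c(c, b) } else { n1 <- c(a, c); n2 <- c(b, d) }
    if (n1[1] == n1[2] || n2[1] == n2[2]) next
    k1 <- pair_key(n1[1], n1[2]); k2 <- pair_key(n2[1], n2[2])
    if (k1 == k2 || !is.null(present[[k1]]) || !is.null(present[[k2]])) next
    delta <- (within(n1[1], n1[2]) + within(n2[1], n2[2])) -
      (within(a, b) + within(c, d))
    gain <- if (maximise) delta else -delta
    if (gain > 0 || acc_u[it] < exp(gain / temps[it])) {
      rm(list = c(pair_key(a, b), pair_key(c, d)), envir = present)
      assign(k1, TRUE, present)
      assign(k2, TRUE, present)
      el[e1, ] <- n1
      el[e2, ] <- n2
      obj <- obj + delta
      better <- if (maximise) obj > best_obj else obj < best_obj
      if (better) { best_obj <- obj; best_el <- el }
    }
  }
  out <- igraph::make_empty_graph(nv, directed = FALSE)
  out <- igraph::add_edges(out, t(best_el))
  igraph::V(out)$name <- igraph::V(g)$name
  out
}

#' Topology summary of a drug network
#'
#' Convenience wrapper collecting node/edge counts, the degree
#' distribution, the power-law goodness of fit, assortativity over the
#' binary DILI split, and modularity.
#'
#' @param network A `network_bundle`.
#' @param n_bootstrap Bootstrap samples for the power-law fit; skipped (with
#'   `NA` results) when fewer than 10 nodes have positive degree.
#' @param seed RNG seed.
#' @return List of class `topology_summary`.
#' @export
topology_summary <- function(network, n_bootstrap = 100, seed = 1L) {
  g <- as_graph(network)
  deg <- igraph::degree(g)
  pl <- if (sum(deg > 0) >= 10L && length(unique(deg[deg > 0])) > 1L) {
    powerlaw_goodness_of_fit(deg, n_bootstrap = n_bootstrap, seed = seed)
  } else {
    list(exponent = NA_real_, xmin = NA_real_, ks_statistic = NA_real_,
         ks_p_value = NA_real_, n_tail = NA_integer_)
  }
  A <- tryCatch(assortativity_by_class(network),
                warning = function(w) NA_real_)
  M <- if (igraph::ecount(g) > 0) modularity_score(g)$M else NA_real_
  structure(list(
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    degree_distribution = degree_distribution_table(network),
    powerlaw_exponent = pl$exponent, powerlaw_xmin = pl$xmin,
    ks_statistic = pl$ks_statistic, ks_p_value = pl$ks_p_value,
    assortativity_A = A, modularity_M = M
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("nodes: ", x$n_nodes, "  edges: ", x$n_edges, "\n",
      "power-law exponent: ", signif(x$powerlaw_exponent, 4),
      " (xmin ", x$powerlaw_xmin, ", KS p = ", signif(x$ks_p_value, 3), ")\n",
      "assortativity A: ", signif(x$assortativity_A, 4), "\n",
      "modularity M: ", signif(x$modularity_M, 4), "\n", sep = "")
  invisible(x)
}
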