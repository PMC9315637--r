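# Overlapping community detection by clustering links: communities are sets
# of similar edges rather than sets of nodes, so a drug inherits one
# membership per community its incident links fall into. Edge-edge
# similarity is computed for edge pairs sharing a node, edges are grouped by
# single-linkage agglomeration, and the dendrogram is cut at the height
# maximising the partition density.

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# inclusive neighborhood (node plus its neighbors), by node name
inclusive_neighborhood <- function(g, v) {
  c(v, igraph::neighbors(g, v)$name)
}

#' Similarity between two adjacent edges
#'
#' For edges sharing exactly one endpoint, similarity compares the two
#' non-shared endpoints: unweighted, the Jaccard index of their inclusive
#' neighborhoods (node plus neighbors); weighted, the Tanimoto coefficient
#' of their edge-weight vectors, with each node's self-affinity set to the
#' mean weight of its incident edges. Edge pairs sharing no endpoint have
#' similarity 0 by definition.
#'
#' @param edge_a,edge_b Length-2 character vectors of endpoint node ids.
#' @param network A `network_bundle` or igraph graph (weights taken from
#'   the `weight` edge attribute / `alpha`).
#' @param weighted Use the weighted Tanimoto variant (default FALSE here;
#'   the clustering wrapper defaults to weighted).
#' @return Similarity in \[0, 1\].
#' @export
edge_similarity <- function(edge_a, edge_b, network, weighted = FALSE) {
  g <- as_graph(network)
  stopifnot(length(edge_a) == 2L, length(edge_b) == 2L)
  edge_a <- as.character(edge_a)
  edge_b <- as.character(edge_b)
  if (edge_key(edge_a[1], edge_a[2]) == edge_key(edge_b[1], edge_b[2])) {
    stop_dilinet("edge similarity is undefined for identical edges",
                 class = "dilinet_validation_error")
  }
  shared <- intersect(edge_a, edge_b)
  if (length(shared) != 1L) return(0)
  i <- setdiff(edge_a, shared)
  j <- setdiff(edge_b, shared)
  if (!weighted) {
    ni <- inclusive_neighborhood(g, i)
    nj <- inclusive_neighborhood(g, j)
    return(length(intersect(ni, nj)) / length(union(ni, nj)))
  }
  ai <- affinity_vector(g, i)
  aj <- affinity_vector(g, j)
  nodes <- union(names(ai), names(aj))
  vi <- setNames(numeric(length(nodes)), nodes)
  vj <- vi
  vi[names(ai)] <- ai
  vj[names(aj)] <- aj
  dot <- sum(vi * vj)
  dot / (sum(vi^2) + sum(vj^2) - dot)
}

# weight vector of node v over its inclusive neighborhood;
# self-affinity = mean incident weight
affinity_vector <- function(g, v) {
  inc <- igraph::incident(g, v)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) inc$weight
       else rep(1, length(inc))
  nb <- igraph::neighbors(g, v)$name
  setNames(c(mean(w), w), c(v, nb))
}

#' Single-linkage clustering of network edges
#'
#' Computes similarities for all adjacent edge pairs (non-adjacent pairs
#' have similarity 0) and agglomerates edges by single linkage on
#' dissimilarity `1 - similarity`. Edges are ordered lexicographically by
#' endpoint ids so merges are deterministic.
#'
#' @param network A `network_bundle` or igraph graph with at least 2 edges.
#' @param weighted Use weighted Tanimoto edge similarity (default TRUE; the
#'   drug network carries the integration weight alpha).
#' @return An object of class `edge_dendrogram`: the `hclust` tree, the
#'   edge list (in tree leaf order) and the graph.
#' @export
cluster_edges <- function(network, weighted = TRUE) {
  g <- as_graph(network)
  m <- igraph::ecount(g)
  if (m < 2L) {
    stop_dilinet("need at least 2 edges to cluster, got ", m,
                 class = "dilinet_validation_error")
  }
  el <- igraph::as_edgelist(g)
  keys <- edge_key(el[, 1], el[, 2])
  ord <- order(keys)
  el <- el[ord, , drop = FALSE]
  keys <- keys[ord]
  eid <- setNames(seq_len(m), keys)

  sim <- matrix(0, m, m)
  # weighted similarity needs node affinity vectors; cache them
  aff <- if (weighted) {
    setNames(lapply(igraph::V(g)$name, function(v) affinity_vector(g, v)),
             igraph::V(g)$name)
  }
  for (v in igraph::V(g)$name) {
    inc <- igraph::incident(g, v)
    ends <- igraph::ends(g, inc)
    ids <- eid[edge_key(ends[, 1], ends[, 2])]
    if (length(ids) < 2L) next
    others <- ifelse(ends[, 1] == v, ends[, 2], ends[, 1])
    pairs <- combn(seq_along(ids), 2L)
    for (pc in seq_len(ncol(pairs))) {
      a <- pairs[1, pc]; b <- pairs[2, pc]
      i <- others[a]; j <- others[b]
      s <- if (i == j) {
        1  # parallel paths to the same node (multi-edge collapse guard)
      } else if (!weighted) {
        ni <- inclusive_neighborhood(g, i)
        nj <- inclusive_neighborhood(g, j)
        length(intersect(ni, nj)) / length(union(ni, nj))
      } else {
        vi0 <- aff[[i]]; vj0 <- aff[[j]]
        nodes <- union(names(vi0), names(vj0))
        vi <- setNames(numeric(length(nodes)), nodes)
        vj <- vi
        vi[names(vi0)] <- vi0
        vj[names(vj0)] <- vj0
        dot <- sum(vi * vj)
        dot / (sum(vi^2) + sum(vj^2) - dot)
      }
      sim[ids[a], ids[b]] <- max(sim[ids[a], ids[b]], s)
      sim[ids[b], ids[a]] <- sim[ids[a], ids[b]]
    }
  }
  d <- stats::as.dist(1 - sim)
  tree <- stats::hclust(d, method = "single")
  tree$labels <- keys
  structure(list(tree = tree, edges = el, keys = keys, graph = g),
            class = "edge_dendrogram")
}

# partition density of one community: m_c edges over n_c nodes, normalised
# between a tree (0) and a clique (1); defined as 0 for n_c = 2
community_density <- function(m_c, n_c) {
  if (n_c <= 2L) return(0)
  (m_c - (n_c - 1)) / (n_c * (n_c - 1) / 2 - (n_c - 1))
}

# weighted mean of community densities: D = (1/M) sum m_c D_c
partition_density_value <- function(m_cs, n_cs) {
  M <- sum(m_cs)
  sum(m_cs * mapply(community_density, m_cs, n_cs)) / M
}

#' Cut the edge dendrogram at maximum partition density
#'
#' Evaluates the partition density `D = (1/M) sum_c m_c D_c`, with
#' `D_c = (m_c - (n_c - 1)) / (n_c(n_c-1)/2 - (n_c - 1))` (0 for two-node
#' communities), at every merge height of the dendrogram plus the trivial
#' all-singletons cut, and returns the edge partition maximising `D`. Ties
#' are broken toward fewer communities.
#'
#' @param dendrogram An `edge_dendrogram` from [cluster_edges()].
#' @return A `link_community_partition`: list of communities (each with
#'   `community_id`, `edges` two-column matrix, `nodes`, `m_c`, `n_c`,
#'   `density`), the cut `height` and the overall `partition_density`.
#' @export
cut_at_max_partition_density <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "edge_dendrogram"))
  tree <- dendrogram$tree
  el <- dendrogram$edges
  M <- nrow(el)
  heights <- sort(unique(c(-1, tree$height)))
  best <- NULL
  for (h in heights) {
    memb <- if (h < 0) seq_len(M) else stats::cutree(tree, h = h)
    split_idx <- split(seq_len(M), memb)
    m_cs <- lengths(split_idx)
    n_cs <- vapply(split_idx, function(ix) {
      length(unique(c(el[ix, 1], el[ix, 2])))
    }, 1L)
    D <- partition_density_value(m_cs, n_cs)
    # strict improvement, or equal D with fewer communities (larger h wins
    # since heights ascend)
    if (is.null(best) || D > best$D + 1e-12 ||
        (abs(D - best$D) <= 1e-12 && length(split_idx) <= length(best$split))) {
      best <- list(D = D, h = h, split = split_idx)
    }
  }
  communities <- mapply(function(ix, id) {
    nodes <- sort(unique(c(el[ix, 1], el[ix, 2])))
    list(community_id = id, edges = el[ix, , drop = FALSE], nodes = nodes,
         m_c = length(ix), n_c = length(nodes),
         density = community_density(length(ix), length(nodes)))
  }, best$split, seq_along(best$split), SIMPLIFY = FALSE)
  structure(list(communities = unname(communities), height = best$h,
                 partition_density = best$D),
            class = "link_community_partition")
}

#' @export
print.link_community_partition <- function(x, ...) {
  cat("link communities: ", length(x$communities),
      " (partition density D = ", signif(x$partition_density, 4),
      ", cut height ", signif(x$height, 4), ")\n", sep = "")
  invisible(x)
}

#' Overlapping drug memberships of a link-community partition
#'
#' A drug belongs to every community containing at least one of its
#' incident links, so memberships overlap.
#'
#' @param partition A `link_community_partition`.
#' @return Named list: drug_id -> integer vector of community ids.
#' @export
drug_memberships <- function(partition) {
  stopifnot(inherits(partition, "link_community_partition"))
  if (!length(partition$communities)) return(structure(list(), names = character()))
  pairs <- do.call(rbind, lapply(partition$communities, function(cm) {
    data.frame(drug_id = cm$nodes, community_id = cm$community_id,
               stringsAsFactors = FALSE)
  }))
  lapply(split(pairs$community_id, pairs$drug_id), function(x) sort(unique(x)))
}

#' Detect link communities in a drug network
#'
#' Convenience wrapper: [cluster_edges()] then
#' [cut_at_max_partition_density()].
#'
#' @param network A `network_bundle` or igraph graph with at least 2 edges.
#' @param weighted Use weighted Tanimoto edge similarity (default TRUE).
#' @return A `link_community_partition`.
#' @export
link_communities <- function(network, weighted = TRUE) {
  cut_at_max_partition_density(cluster_edges(network, weighted = weighted))
}

#' Tabulate a link-community partition
#'
#' @param partition A `link_community_partition`.
#' @return data.frame: `community_id`, `m_c`, `n_c`, `density`, `drugs`
#'   (comma-separated member list).
#' @export
partition_table <- function(partition) {
  stopifnot(inherits(partition, "link_community_partition"))
  do.call(rbind, lapply(partition$communities, function(cm) {
    data.frame(community_id = cm$community_id, m_c = cm$m_c, n_c = cm$n_c,
               density = cm$density,
               drugs = paste(cm$nodes, collapse = ","),
               stringsAsFactors = FALSE)
  })) %||% data.frame(community_id = integer(), m_c = integer(),
                      n_c = integer(), density = numeric(),
                      drugs = character(), stringsAsFactors = FALSE)
}
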