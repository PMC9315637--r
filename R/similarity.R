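# Drug-drug similarity: per-channel hypergeometric overlap indices (protein
# targets and enriched Pfam domains), integrated per drug pair as a
# two-component vector whose module (alpha) weighs the link and whose angle
# (gamma) tells which channel carries the association.

# cap on -log10(p) once the tail probability underflows double precision
INDEX_CAP <- 300

#' Hypergeometric overlap index of two profiles
#'
#' The index is `-log10 P(X >= k)` where `k` is the observed overlap and `X`
#' follows the hypergeometric distribution of drawing `|B|` elements from a
#' universe containing `|A|` marked ones — the probability of an overlap at
#' least as large as observed between two random profiles of the same sizes.
#' An index of 3 therefore corresponds exactly to a tail probability of
#' `1e-3`, and any larger index to a probability below 0.001. Computed as an
#' exact tail sum in log space; zero overlap gives index 0; capped at 300
#' when the probability underflows.
#'
#' @param set_a,set_b Character (or atomic) vectors; duplicated elements are
#'   ignored.
#' @param universe_size Size of the common universe both profiles are drawn
#'   from; must be at least `max(|A|, |B|)`.
#' @return A nonnegative scalar index.
#' @export
hypergeometric_index <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!is_count(universe_size, min = 1)) {
    stop_dilinet("universe_size must be a positive integer",
                 class = "dilinet_validation_error")
  }
  if (length(set_a) > universe_size || length(set_b) > universe_size) {
    stop_dilinet("profile larger than the universe (|A| = ", length(set_a),
                 ", |B| = ", length(set_b), ", universe = ", universe_size, ")",
                 class = "dilinet_validation_error")
  }
  hyper_index_k(length(intersect(set_a, set_b)),
                length(set_a), length(set_b), universe_size)
}

# vectorised index from overlap counts; exact log-space tail via phyper.
# The tail is symmetric in the two profile sizes; passing the smaller size
# as the marked count makes the computation bitwise symmetric too.
hyper_index_k <- function(k, n_a, n_b, universe_size) {
  lo <- pmin(n_a, n_b)
  hi <- pmax(n_a, n_b)
  log_p <- phyper(k - 1L, m = lo, n = universe_size - lo, k = hi,
                  lower.tail = FALSE, log.p = TRUE)
  idx <- -log_p / log(10)
  idx[k == 0L] <- 0
  pmin(pmax(idx, 0), INDEX_CAP)
}

#' Tail probability at a given index
#'
#' Inverts the minus-log10 definition of the hypergeometric index back to
#' the overlap tail probability it encodes.
#'
#' @param index Nonnegative index value(s).
#' @return `10^-index`.
#' @export
index_tail_probability <- function(index) {
  stopifnot(is.numeric(index), all(index >= 0))
  10^(-index)
}

#' Integrate the two channel indices as a similarity vector
#'
#' The protein-channel and domain-channel indices of a drug pair form a
#' two-component vector: the module `alpha` (Euclidean norm) measures the
#' intensity of the association and the angle `gamma` (degrees from the
#' protein axis toward the domain axis) its channel balance — 0 degrees is
#' protein-only evidence, 90 domain-only, 45 equal contribution.
#'
#' @param h_protein,h_domain Nonnegative channel indices (vectorised).
#' @return data.frame with columns `alpha` and `gamma`; a pair with both
#'   indices zero has no vector and yields `NA` in both columns.
#' @export
pair_vector <- function(h_protein, h_domain) {
  stopifnot(is.numeric(h_protein), is.numeric(h_domain),
            length(h_protein) == length(h_domain),
            all(h_protein >= 0), all(h_domain >= 0))
  alpha <- sqrt(h_protein^2 + h_domain^2)
  gamma <- atan2(h_domain, h_protein) * 180 / pi
  zero <- h_protein == 0 & h_domain == 0
  alpha[zero] <- NA_real_
  gamma[zero] <- NA_real_
  data.frame(alpha = alpha, gamma = gamma)
}

#' Pairwise similarities over a cohort
#'
#' Computes, for every unordered drug pair, the protein-channel and
#' domain-channel hypergeometric indices and the integrated vector. Each
#' channel uses its own universe: by default the cohort-wide set of kept
#' target proteins and of enriched domains. Drugs lacking a domain profile
#' participate with `h_domain = 0`.
#'
#' @param protein_profiles Named list drug -> protein accessions.
#' @param domain_profiles Named list drug -> Pfam ids (may be missing drugs
#'   or empty vectors).
#' @param protein_universe,domain_universe Optional explicit universes;
#'   default is the union over the cohort's profiles.
#' @return data.frame: `drug_i`, `drug_j`, `h_protein`, `h_domain`,
#'   `alpha`, `gamma` — one row per unordered pair with at least one
#'   non-zero channel (pairs with no overlap on either channel are
#'   suppressed).
#' @export
pair_similarities <- function(protein_profiles, domain_profiles = list(),
                              protein_universe = NULL, domain_universe = NULL) {
  drugs <- sort(unique(c(names(protein_profiles), names(domain_profiles))))
  if (length(drugs) < 2L) {
    stop_dilinet("need at least 2 drugs to compute pair similarities",
                 class = "dilinet_validation_error")
  }
  protein_universe <- unique(protein_universe %||%
                               unlist(protein_profiles, use.names = FALSE))
  domain_universe <- unique(domain_universe %||%
                              unlist(domain_profiles, use.names = FALSE))

  overlap_counts <- function(profiles, universe) {
    # binary drug x element membership matrix; overlaps via crossproduct
    mat <- matrix(0L, nrow = length(drugs), ncol = length(universe),
                  dimnames = list(drugs, universe))
    for (d in intersect(drugs, names(profiles))) {
      el <- intersect(unique(profiles[[d]]), universe)
      mat[d, el] <- 1L
    }
    list(k = tcrossprod(mat), size = rowSums(mat))
  }

  ij <- which(upper.tri(diag(length(drugs))), arr.ind = TRUE)
  h_p <- h_d <- numeric(nrow(ij))
  if (length(protein_universe)) {
    oc <- overlap_counts(protein_profiles, protein_universe)
    h_p <- hyper_index_k(oc$k[ij], oc$size[ij[, 1]], oc$size[ij[, 2]],
                         length(protein_universe))
  }
  if (length(domain_universe)) {
    oc <- overlap_counts(domain_profiles, domain_universe)
    h_d <- hyper_index_k(oc$k[ij], oc$size[ij[, 1]], oc$size[ij[, 2]],
                         length(domain_universe))
  }
  vec <- pair_vector(h_p, h_d)
  out <- data.frame(drug_i = drugs[ij[, 1]], drug_j = drugs[ij[, 2]],
                    h_protein = h_p, h_domain = h_d,
                    alpha = vec$alpha, gamma = vec$gamma,
                    stringsAsFactors = FALSE)
  suppressed <- is.na(out$alpha)
  if (any(suppressed)) {
    message(sum(suppressed), " drug pair(s) with zero similarity on both ",
            "channels suppressed")
  }
  out <- out[!suppressed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct an edge rule
#'
#' Decides which drug pairs become links. `either_channel` (default) keeps a
#' pair when `max(h_protein, h_domain)` reaches the cutoff, `both_channels`
#' when both do, `module` when the vector module `alpha` does. The default
#' cutoff 3 keeps pairs whose overlap tail probability is at most `1e-3` on
#' the qualifying channel.
#'
#' @param cutoff Index threshold (default 3).
#' @param mode One of `"either_channel"`, `"both_channels"`, `"module"`.
#' @return An `edge_rule` object.
#' @export
edge_rule <- function(cutoff = 3,
                      mode = c("either_channel", "both_channels", "module")) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
  structure(list(cutoff = cutoff, mode = match.arg(mode)), class = "edge_rule")
}

rule_passes <- function(pairs, rule) {
  switch(rule$mode,
         either_channel = pmax(pairs$h_protein, pairs$h_domain) >= rule$cutoff,
         both_channels = pmin(pairs$h_protein, pairs$h_domain) >= rule$cutoff,
         module = pairs$alpha >= rule$cutoff)
}

#' Build the drug similarity network
#'
#' Computes all pairwise similarities and emits the weighted network: an
#' edge for every pair passing the [edge_rule()], weighted by the vector
#' module `alpha`. Drugs with no surviving link are retained as isolated
#' nodes.
#'
#' @inheritParams pair_similarities
#' @param rule An [edge_rule()].
#' @param drugs Optional drug annotation table (from [read_drug_table()])
#'   supplying node toxicity classes and categories.
#' @param pairs Optionally, a precomputed table from [pair_similarities()]
#'   (skips recomputation).
#' @return A `network_bundle`.
#' @export
build_network <- function(protein_profiles, domain_profiles = list(),
                          rule = edge_rule(), drugs = NULL,
                          protein_universe = NULL, domain_universe = NULL,
                          pairs = NULL) {
  stopifnot(inherits(rule, "edge_rule"))
  all_drugs <- sort(unique(c(names(protein_profiles), names(domain_profiles))))
  if (length(all_drugs) < 2L) {
    stop_dilinet("need at least 2 drugs to build a network",
                 class = "dilinet_validation_error")
  }
  pairs <- pairs %||% pair_similarities(protein_profiles, domain_profiles,
                                        protein_universe, domain_universe)
  edges <- pairs[rule_passes(pairs, rule), , drop = FALSE]
  nodes <- data.frame(drug_id = all_drugs,
                      toxicity_class = NA_character_,
                      category = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(drugs)) {
    m <- match(nodes$drug_id, drugs$drug_id)
    nodes$toxicity_class <- drugs$toxicity_class[m]
    if ("therapeutic_category" %in% names(drugs)) {
      nodes$category <- drugs$therapeutic_category[m]
    }
  }
  network_bundle(nodes, edges)
}

#' Angle distribution across cutoffs
#'
#' Summarises how the channel balance of surviving links shifts with the
#' stringency of the edge rule: at relaxed cutoffs domain-channel evidence
#' tends to dominate (gamma toward 90 degrees), at strict cutoffs protein
#' evidence (gamma toward 0).
#'
#' @param pairs Unthresholded table from [pair_similarities()].
#' @param cutoffs Numeric vector of index thresholds to sweep.
#' @param mode Edge-rule mode used at each cutoff.
#' @return data.frame: `cutoff`, `n` passing pairs, `median_gamma`,
#'   `q1_gamma`, `q3_gamma` (NA where no pair passes).
#' @export
angle_distribution <- function(pairs, cutoffs,
                               mode = c("either_channel", "both_channels",
                                        "module")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(pairs), is.numeric(cutoffs))
  rows <- lapply(cutoffs, function(co) {
    g <- pairs$gamma[rule_passes(pairs, edge_rule(co, mode))]
    g <- g[!is.na(g)]
    if (!length(g)) {
      data.frame(cutoff = co, n = 0L, median_gamma = NA_real_,
                 q1_gamma = NA_real_, q3_gamma = NA_real_)
    } else {
      q <- unname(quantile(g, c(0.25, 0.5, 0.75), type = 7))
      data.frame(cutoff = co, n = length(g), median_gamma = q[2],
                 q1_gamma = q[1], q3_gamma = q[3])
    }
  })
  do.call(rbind, rows)
}
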