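# Community annotation: rank drug communities by liver-toxicity enrichment
# (DILI score), name them by the Pfam family their member drugs share most,
# tabulate therapeutic categories, and run over-representation of community
# targets against user-supplied annotation sets.

#' DILI score of a drug community
#'
#' Percentage weighting the hepatotoxic content of a community:
#' `score = round(100 * (td + w * vtd) / d)` (half-up rounding) with `d`
#' drugs, `td` toxic drugs (classes toxic and very_toxic) and `vtd` very
#' toxic (withdrawn) drugs. With the default weight `w = 1` a withdrawn
#' drug counts twice — once as toxic, once as withdrawn — so communities
#' harbouring withdrawn drugs can exceed 100.
#'
#' @param td Number of toxic drugs (including the very toxic ones).
#' @param vtd Number of very toxic (withdrawn) drugs.
#' @param d Community size in drugs.
#' @param vtd_weight Extra weight per withdrawn drug (default 1).
#' @return Integer percentage.
#' @export
dili_score <- function(td, vtd, d, vtd_weight = 1) {
  if (!is_count(d, 1) || !is_count(td) || !is_count(vtd) ||
      vtd > td || td > d) {
    stop_dilinet("need 0 <= vtd <= td <= d with d >= 1 (got td = ", td,
                 ", vtd = ", vtd, ", d = ", d, ")",
                 class = "dilinet_validation_error")
  }
  as.integer(round_half_up(100 * (td + vtd_weight * vtd) / d))
}

#' Rank community reports by DILI score
#'
#' Descending DILI score, ties broken by community size (descending) then
#' community id.
#'
#' @param reports data.frame with columns `dili_score`, `d`,
#'   `community_id` (e.g. from [community_reports()]).
#' @return The same data.frame, reordered.
#' @export
rank_communities <- function(reports) {
  stopifnot(is.data.frame(reports))
  if (!nrow(reports)) return(reports)
  ord <- order(-reports$dili_score, -reports$d, reports$community_id)
  out <- reports[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dominant Pfam families of a community
#'
#' For each Pfam id, counts the member drugs whose domain profile contains
#' it; returns every id attaining the maximum count, so a community
#' described equally by two domains reports both.
#'
#' @param community_drugs Character vector of member drug ids.
#' @param domain_profiles Named list drug -> Pfam ids.
#' @return Character vector of Pfam ids (sorted; empty, with a warning,
#'   when no member has any domain).
#' @export
dominant_family <- function(community_drugs, domain_profiles) {
  doms <- unlist(lapply(community_drugs, function(d) {
    unique(domain_profiles[[d]])
  }), use.names = FALSE)
  if (!length(doms)) {
    warning("no member drug has a domain profile; community unnamed")
    return(character())
  }
  tab <- table(doms)
  sort(names(tab)[tab == max(tab)])
}

#' Therapeutic-category tabulation of a community
#'
#' @param community_drugs Character vector of member drug ids.
#' @param drug_records Drug table from [read_drug_table()].
#' @return Named integer vector of per-category counts, descending; drugs
#'   with no category are counted under `"unclassified"`.
#' @export
category_tabulation <- function(community_drugs, drug_records) {
  cat <- drug_records$therapeutic_category[
    match(community_drugs, drug_records$drug_id)]
  cat[is.na(cat)] <- "unclassified"
  tab <- table(cat)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

#' Over-representation of community targets in annotation sets
#'
#' Hypergeometric upper-tail over-representation of a protein set against
#' each term of a GMT-style annotation collection (KEGG/GO style), with
#' Benjamini-Hochberg correction across terms.
#'
#' @param community_targets Character vector of proteins (must lie in the
#'   universe).
#' @param annotation_sets Named list term -> member proteins (see
#'   [read_gmt()]).
#' @param universe Character vector of background proteins; every member
#'   set must be contained in it.
#' @return data.frame: `term`, `n_term`, `k_overlap`, `p_value`, `q_value`,
#'   sorted by p-value.
#' @export
target_ora <- function(community_targets, annotation_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) {
    stop_dilinet("empty universe", class = "dilinet_validation_error")
  }
  if (!length(annotation_sets)) {
    stop_dilinet("empty annotation set collection",
                 class = "dilinet_validation_error")
  }
  targets <- unique(community_targets)
  if (length(setdiff(targets, universe))) {
    stop_dilinet("community targets outside the universe",
                 class = "dilinet_validation_error")
  }
  sets <- lapply(annotation_sets, unique)
  oversize <- names(sets)[vapply(sets, function(s)
    length(setdiff(s, universe)) > 0, TRUE)]
  if (length(oversize)) {
    stop_dilinet("annotation set(s) not contained in the universe: ",
                 paste(oversize, collapse = ", "),
                 class = "dilinet_validation_error")
  }
  n_term <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, targets)), 1L)
  p <- phyper(k - 1L, m = n_term, n = length(universe) - n_term,
              k = length(targets), lower.tail = FALSE)
  p[k == 0L] <- 1
  out <- data.frame(term = names(sets), n_term = n_term, k_overlap = k,
                    p_value = pmin(p, 1), stringsAsFactors = FALSE)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proteins defining a community's links
#'
#' The targets "behind" a community: by default the union, over the
#' community's links, of the proteins shared by the two endpoint drugs;
#' optionally the union of all member-drug profiles.
#'
#' @param community One element of a `link_community_partition`'s
#'   `communities` list.
#' @param protein_profiles Named list drug -> proteins.
#' @param mode `"shared"` (default) or `"union"`.
#' @return Character vector of protein accessions.
#' @export
community_targets <- function(community, protein_profiles,
                              mode = c("shared", "union")) {
  mode <- match.arg(mode)
  if (mode == "union") {
    return(sort(unique(unlist(protein_profiles[community$nodes],
                              use.names = FALSE))))
  }
  el <- community$edges
  sort(unique(unlist(lapply(seq_len(nrow(el)), function(r) {
    intersect(protein_profiles[[el[r, 1]]], protein_profiles[[el[r, 2]]])
  }), use.names = FALSE)))
}

#' Build community reports
#'
#' One row per community: size, toxic and very-toxic counts, DILI score,
#' dominant Pfam families and therapeutic-category tabulation. Single-link
#' communities (2 drugs) are reported but flagged unranked; ranked rows are
#' ordered by [rank_communities()].
#'
#' @param partition A `link_community_partition`.
#' @param drug_records Drug table from [read_drug_table()].
#' @param domain_profiles Named list drug -> Pfam ids.
#' @param vtd_weight Withdrawn-drug weight for [dili_score()].
#' @param min_ranked_size Smallest community size eligible for ranking
#'   (default 3).
#' @return data.frame: `community_id`, `d`, `td`, `vtd`, `dili_score`,
#'   `dominant_families` (comma-separated), `categories`
#'   ("name (n); ..."), `ranked`.
#' @export
community_reports <- function(partition, drug_records, domain_profiles,
                              vtd_weight = 1, min_ranked_size = 3L) {
  stopifnot(inherits(partition, "link_community_partition"))
  rows <- lapply(partition$communities, function(cm) {
    cls <- drug_records$toxicity_class[match(cm$nodes, drug_records$drug_id)]
    td <- sum(cls %in% DILI_CLASSES, na.rm = TRUE)
    vtd <- sum(cls %in% "very_toxic", na.rm = TRUE)
    fams <- suppressWarnings(dominant_family(cm$nodes, domain_profiles))
    cats <- category_tabulation(cm$nodes, drug_records)
    data.frame(
      community_id = cm$community_id, d = cm$n_c, td = td, vtd = vtd,
      dili_score = dili_score(td, vtd, cm$n_c, vtd_weight = vtd_weight),
      dominant_families = paste(fams, collapse = ","),
      categories = paste(sprintf("%s (%d)", names(cats), cats),
                         collapse = "; "),
      ranked = cm$n_c >= min_ranked_size,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(community_id = integer(), d = integer(),
                      td = integer(), vtd = integer(), dili_score = integer(),
                      dominant_families = character(), categories = character(),
                      ranked = logical(), stringsAsFactors = FALSE))
  }
  ranked <- rank_communities(out[out$ranked, , drop = FALSE])
  unranked <- out[!out$ranked, , drop = FALSE]
  out <- rbind(ranked, unranked)
  rownames(out) <- NULL
  out
}
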