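# Drug-domain association: a drug is linked to a Pfam family when its
# protein targets are over-represented among the family's members, assessed
# with an exact binomial tail test and Benjamini-Hochberg correction.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values. Output
#' order matches input order; values are clipped to at most 1.
#'
#' @param p_values Numeric vector of probabilities in \[0, 1\].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop_dilinet("p-values must be numeric in [0, 1] with no missing values",
                 class = "dilinet_validation_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Binomial domain enrichment for one drug
#'
#' For each Pfam family carried by at least one protein in the universe,
#' tests whether the drug's targets fall in the family more often than
#' expected by chance: with `n` targets of which `k` carry the domain and a
#' family occupying fraction `f` of the universe, the p-value is the exact
#' upper tail `P(X >= k)` for `X ~ Binomial(n, f)` (no normal
#' approximation). Family membership is binary: a multi-domain protein
#' contributes one hit to each of its families.
#'
#' @param profile Character vector of the drug's target protein accessions.
#' @param domain_map Named list protein -> Pfam ids (see
#'   [read_domain_map()]).
#' @param universe Character vector of all proteins forming the background
#'   (typically every kept target across the cohort).
#' @return data.frame with one row per candidate domain: `pfam_id`,
#'   `n_targets`, `k_hits`, `family_fraction`, `p_value`.
#' @export
binomial_enrichment <- function(profile, domain_map, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) {
    stop_dilinet("empty protein universe", class = "dilinet_validation_error")
  }
  profile <- unique(profile)
  outside <- setdiff(profile, universe)
  if (length(outside)) {
    stop_dilinet("target profile contains protein(s) outside the universe: ",
                 paste(outside, collapse = ", "),
                 class = "dilinet_validation_error")
  }
  # proteins absent from the map simply carry no domains
  fam_all <- unlist(domain_map[intersect(universe, names(domain_map))],
                    use.names = FALSE)
  prot_of <- rep(intersect(universe, names(domain_map)),
                 lengths(domain_map[intersect(universe, names(domain_map))]))
  if (!length(fam_all)) {
    return(data.frame(pfam_id = character(), n_targets = integer(),
                      k_hits = integer(), family_fraction = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  fam_size <- tapply(prot_of, fam_all, function(p) length(unique(p)))
  in_prof <- prot_of %in% profile
  hit_tab <- table(fam_all[in_prof])
  pfam_ids <- sort(names(fam_size))
  n <- length(profile)
  k <- as.integer(ifelse(pfam_ids %in% names(hit_tab), hit_tab[pfam_ids], 0L))
  f <- as.numeric(fam_size[pfam_ids]) / length(universe)
  p <- pbinom(k - 1L, size = n, prob = f, lower.tail = FALSE)
  data.frame(pfam_id = pfam_ids, n_targets = n, k_hits = k,
             family_fraction = f, p_value = pmin(p, 1),
             stringsAsFactors = FALSE)
}

#' Cohort-wide domain enrichment
#'
#' Runs [binomial_enrichment()] for every drug and applies
#' Benjamini-Hochberg correction, by default globally across all drug-domain
#' pairs (optionally per drug).
#'
#' @param profiles Named list of target profiles from
#'   [build_target_profiles()].
#' @param domain_map Named list protein -> Pfam ids.
#' @param universe Protein background; defaults to the union of all
#'   profiles (the cohort's observable target space).
#' @param scope `"global"` (default) corrects across all drug-domain pairs
#'   jointly; `"per_drug"` corrects within each drug.
#' @return data.frame with columns `drug_id`, `pfam_id`, `n_targets`,
#'   `k_hits`, `family_fraction`, `p_value`, `q_value`.
#' @export
domain_enrichment <- function(profiles, domain_map, universe = NULL,
                              scope = c("global", "per_drug")) {
  scope <- match.arg(scope)
  stopifnot(is.list(profiles))
  universe <- universe %||% sort(unique(unlist(profiles, use.names = FALSE)))
  res <- lapply(names(profiles), function(d) {
    out <- binomial_enrichment(profiles[[d]], domain_map, universe)
    if (nrow(out)) cbind(drug_id = d, out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(drug_id = character(), pfam_id = character(),
                      n_targets = integer(), k_hits = integer(),
                      family_fraction = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  res$q_value <- if (scope == "global") {
    bh_adjust(res$p_value)
  } else {
    stats::ave(res$p_value, res$drug_id, FUN = bh_adjust)
  }
  rownames(res) <- NULL
  res
}

#' Build per-drug domain profiles from enrichment results
#'
#' A domain enters a drug's profile when its q-value is at or below the
#' threshold. Drugs with no passing domain are retained with an empty
#' profile, so protein-only evidence still reaches the network stage.
#'
#' @param results data.frame from [domain_enrichment()].
#' @param q_threshold Significance cutoff on the BH-adjusted q-value
#'   (default 0.05).
#' @return Named list: drug_id -> sorted character vector of Pfam ids
#'   (possibly empty).
#' @export
build_domain_profiles <- function(results, q_threshold = 0.05) {
  stopifnot(is.data.frame(results), is_prob(q_threshold))
  if (!"q_value" %in% names(results)) {
    stop_dilinet("results must carry q_values (run domain_enrichment first)",
                 class = "dilinet_validation_error")
  }
  drugs <- sort(unique(results$drug_id))
  hit <- results[results$q_value <= q_threshold, , drop = FALSE]
  profs <- lapply(drugs, function(d) {
    sort(unique(hit$pfam_id[hit$drug_id == d]))
  })
  names(profs) <- drugs
  profs
}
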