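# Independent brute-force oracles used to check the package's computations.
# These deliberately avoid the code paths under test: tail sums are built
# from explicit binomial coefficients and full pmf enumeration.

# hypergeometric upper tail P(overlap >= k) by enumerating every possible
# overlap count for |A| marked elements, drawing |B| from a universe of u
oracle_hyper_tail <- function(k, n_a, n_b, u) {
  ks <- max(0, n_a + n_b - u):min(n_a, n_b)
  pmf <- choose(n_a, ks) * choose(u - n_a, n_b - ks) / choose(u, n_b)
  sum(pmf[ks >= k])
}

# binomial upper tail P(X >= k), X ~ Binomial(n, f), by full pmf enumeration
oracle_binom_tail <- function(k, n, f) {
  ks <- 0:n
  pmf <- choose(n, ks) * f^ks * (1 - f)^(n - ks)
  sum(pmf[ks >= k])
}

# Benjamini-Hochberg by its step-up definition: q_(i) = min_{j >= i} m p_(j)/j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[ord][i:m] / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# small fixture: a valid ChEMBL-style activity record as a one-row data.frame
make_activity <- function(drug_id = "D1", protein = "P1", assay = "B",
                          rel = "D", target = "SINGLE PROTEIN",
                          std_type = "Ki", std_rel = "=",
                          std_value = 100, units = "nM",
                          pchembl = 7, comment = NA_character_) {
  data.frame(
    drug_id = drug_id, protein_accession = protein, assay_type = assay,
    relationship_type = rel, target_type = target, standard_type = std_type,
    standard_relation = std_rel, standard_value = std_value,
    standard_units = units, pchembl_value = pchembl,
    activity_comment = comment, stringsAsFactors = FALSE
  )
}

# run the analysis stages of the pipeline in memory on a generated cohort
run_cohort_pipeline <- function(cohort, cutoff = 3, weighted = TRUE) {
  filt <- filter_activities(cohort$activities)
  prof <- build_target_profiles(filt$kept)
  dmap <- lapply(split(cohort$domain_map$pfam_id,
                       cohort$domain_map$protein_accession),
                 function(x) sort(unique(x)))
  enr <- domain_enrichment(prof, dmap)
  dp <- build_domain_profiles(enr)
  net <- build_network(prof, dp, rule = edge_rule(cutoff),
                       drugs = cohort$drugs)
  part <- link_communities(net, weighted = weighted)
  list(filtered = filt, profiles = prof, domain_profiles = dp,
       network = net, partition = part,
       memberships = drug_memberships(part))
}

# hard (non-overlapping) module assignment: each drug goes to the community
# holding most of its incident links (ties to the smallest community id)
hard_assignment <- function(memberships, partition) {
  sizes <- vapply(partition$communities, function(cm) cm$m_c, 1L)
  vapply(memberships, function(ids) ids[which.max(sizes[ids])], 1L)
}
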