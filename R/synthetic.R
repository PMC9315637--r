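# Synthetic cohort generator: planted target-sharing modules with
# controllable noise, toxicity enrichment and deliberately invalid activity
# records, so every pipeline stage can be exercised and validated without
# external databases.

# filter rules that invalid records cycle through, matching the audit
# vocabulary of filter_activities()
INVALID_RULES <- FILTER_RULES

#' Synthetic cohort configuration
#'
#' Describes a cohort of drug modules: each module owns a Pfam family — a
#' disjoint set of proteins all carrying the family's domains — and each of
#' its drugs draws targets from the family, with probability `noise_rate`
#' of drawing an off-module target instead. Toxicity is planted per module
#' (`toxic_fraction_per_module`), a fraction of toxic drugs is flagged
#' withdrawn (`very_toxic`), and a fraction of extra activity rows each
#' violates exactly one filter rule.
#'
#' @param n_modules Number of planted modules (default 3).
#' @param drugs_per_module Drugs per module (default 10).
#' @param proteins_per_family Proteins per Pfam family (default 15).
#' @param domains_per_family Pfam domains shared by all proteins of a family
#'   (default 5; multi-domain architectures give the domain channel enough
#'   combinatorial depth to clear the index cutoff).
#' @param targets_per_drug Distinct targets drawn per drug (default 8).
#' @param noise_rate Probability a target is drawn outside the drug's own
#'   family (default 0.05).
#' @param toxic_fraction_per_module Per-module probability that a drug is
#'   hepatotoxic; default evenly spaced from 0.9 down to 0.1 so toxicity
#'   concentrates in the first module(s).
#' @param withdrawn_fraction Probability a toxic drug is flagged
#'   `very_toxic` (default 0.25).
#' @param invalid_record_rate Expected fraction of extra, filter-violating
#'   activity rows (default 0.1).
#' @param seed Integer seed; the same configuration and seed reproduce
#'   byte-identical tables.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_modules = 3L, drugs_per_module = 10L,
                         proteins_per_family = 15L, domains_per_family = 5L,
                         targets_per_drug = 8L, noise_rate = 0.05,
                         toxic_fraction_per_module = NULL,
                         withdrawn_fraction = 0.25,
                         invalid_record_rate = 0.1, seed = 1L) {
  toxic_fraction_per_module <- toxic_fraction_per_module %||%
    (if (n_modules == 1L) 0.5 else seq(0.9, 0.1, length.out = n_modules))
  stopifnot(is_count(n_modules, 1), is_count(drugs_per_module, 1),
            is_count(proteins_per_family, 1), is_count(domains_per_family, 1),
            is_count(targets_per_drug, 1), is_prob(noise_rate),
            is_prob(withdrawn_fraction), is_prob(invalid_record_rate),
            is_count(seed))
  if (length(toxic_fraction_per_module) != n_modules ||
      !all(vapply(toxic_fraction_per_module, is_prob, TRUE))) {
    stop_dilinet("toxic_fraction_per_module must give one probability per module",
                 class = "dilinet_validation_error")
  }
  if (targets_per_drug > proteins_per_family) {
    stop_dilinet("targets_per_drug (", targets_per_drug,
                 ") exceeds proteins_per_family (", proteins_per_family, ")",
                 class = "dilinet_validation_error")
  }
  structure(list(
    n_modules = as.integer(n_modules),
    drugs_per_module = as.integer(drugs_per_module),
    proteins_per_family = as.integer(proteins_per_family),
    domains_per_family = as.integer(domains_per_family),
    targets_per_drug = as.integer(targets_per_drug),
    noise_rate = noise_rate,
    toxic_fraction_per_module = as.numeric(toxic_fraction_per_module),
    withdrawn_fraction = withdrawn_fraction,
    invalid_record_rate = invalid_record_rate,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# one valid activity row: direct single-protein binding with a consistent
# pChEMBL / nM pair in the potent range
valid_activity_row <- function(drug, protein, pchembl, std_type) {
  data.frame(
    drug_id = drug, protein_accession = protein, assay_type = "B",
    relationship_type = "D", target_type = "SINGLE PROTEIN",
    standard_type = std_type, standard_relation = "=",
    standard_value = 10^(9 - pchembl), standard_units = "nM",
    pchembl_value = pchembl, activity_comment = NA_character_,
    stringsAsFactors = FALSE
  )
}

# corrupt one field of a valid row so that exactly the named rule fails
violate_rule <- function(row, rule) {
  switch(rule,
    target_type = { row$target_type <- "PROTEIN COMPLEX"; row },
    relationship_type = { row$relationship_type <- "H"; row },
    assay_type = { row$assay_type <- "A"; row },
    activity_comment = { row$activity_comment <- "Inactive"; row },
    activity = {
      # weak on both gates: pChEMBL below 5 and concentration above 10 uM
      row$pchembl_value <- 4
      row$standard_value <- 1e5
      row
    }
  )
}

#' Generate a synthetic cohort
#'
#' Emits the three pipeline input tables (drug annotations, raw activity
#' records, protein-to-Pfam map) plus the ground truth used to validate
#' recovery: the planted module of every drug, its toxicity class, and the
#' violated rule of every invalid activity row. Every valid activity row
#' passes the default [filter_policy()]; every invalid row violates exactly
#' one named rule, cycling deterministically through the rule list so all
#' rules are exercised.
#'
#' @param config A [synth_config()].
#' @return List with `drugs`, `activities`, `domain_map` (two-column
#'   data.frame), `ground_truth` (list: `modules`, `record_validity`),
#'   `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_drugs <- config$n_modules * config$drugs_per_module
  n_prot <- config$n_modules * config$proteins_per_family

  drug_ids <- sprintf("D%03d", seq_len(n_drugs))
  module_of <- rep(seq_len(config$n_modules), each = config$drugs_per_module)
  proteins <- sprintf("P%05d", seq_len(n_prot))
  prot_module <- rep(seq_len(config$n_modules), each = config$proteins_per_family)

  # domain map: every protein of family m carries all of family m's domains
  pfam_of_module <- function(m) {
    sprintf("PF%05d", (m - 1L) * config$domains_per_family +
              seq_len(config$domains_per_family))
  }
  domain_map <- do.call(rbind, lapply(seq_len(n_prot), function(i) {
    data.frame(protein_accession = proteins[i],
               pfam_id = pfam_of_module(prot_module[i]),
               stringsAsFactors = FALSE)
  }))

  # toxicity labels: per-module toxic fraction, withdrawn subset
  toxic <- runif(n_drugs) < config$toxic_fraction_per_module[module_of]
  withdrawn <- toxic & runif(n_drugs) < config$withdrawn_fraction
  toxicity <- ifelse(withdrawn, "very_toxic", ifelse(toxic, "toxic", "safe"))
  drugs <- data.frame(
    drug_id = drug_ids,
    name = sprintf("drug_%03d", seq_len(n_drugs)),
    toxicity_class = toxicity,
    therapeutic_category = sprintf("category_%02d", module_of),
    stringsAsFactors = FALSE
  )

  # targets: own-family draws with off-module noise, without replacement
  target_rows <- lapply(seq_len(n_drugs), function(i) {
    m <- module_of[i]
    own <- proteins[prot_module == m]
    other <- proteins[prot_module != m]
    n_noise <- if (length(other)) rbinom(1L, config$targets_per_drug,
                                         config$noise_rate) else 0L
    c(sample(own, config$targets_per_drug - n_noise),
      if (n_noise > 0L) sample(other, n_noise))
  })
  valid <- do.call(rbind, lapply(seq_len(n_drugs), function(i) {
    tg <- target_rows[[i]]
    do.call(rbind, lapply(seq_along(tg), function(j) {
      valid_activity_row(drug_ids[i], tg[j], round(runif(1, 5, 9), 2),
                         sample(c("Ki", "IC50"), 1L))
    }))
  }))

  # extra invalid rows, cycling through the rule list
  n_invalid <- rbinom(1L, nrow(valid), config$invalid_record_rate)
  invalid <- NULL
  rules <- character()
  if (n_invalid > 0L) {
    rules <- INVALID_RULES[(seq_len(n_invalid) - 1L) %% length(INVALID_RULES) + 1L]
    src <- sample(nrow(valid), n_invalid, replace = TRUE)
    invalid <- do.call(rbind, lapply(seq_len(n_invalid), function(i) {
      violate_rule(valid[src[i], , drop = FALSE], rules[i])
    }))
  }
  activities <- rbind(valid, invalid)
  rownames(activities) <- NULL
  record_validity <- data.frame(
    row = seq_len(nrow(activities)),
    violated_rule = c(rep(NA_character_, nrow(valid)), rules),
    stringsAsFactors = FALSE
  )

  list(
    drugs = drugs,
    activities = normalise_activity_units(activities),
    domain_map = domain_map,
    ground_truth = list(
      modules = setNames(module_of, drug_ids),
      toxicity = setNames(toxicity, drug_ids),
      record_validity = record_validity
    ),
    config = config
  )
}

#' Generate GMT annotation sets for a synthetic cohort
#'
#' One true term per planted family (containing exactly its proteins) plus
#' decoy terms of matched size drawn from the full protein pool, for
#' exercising over-representation analysis with known answers.
#'
#' @param cohort Output of [generate_cohort()].
#' @param n_decoys Decoy terms per true term (default 2).
#' @param seed RNG seed for decoy draws (default: the cohort seed + 1).
#' @return Named list term -> proteins (GMT-ready; see [write_gmt()]).
#' @export
generate_annotation_sets <- function(cohort, n_decoys = 2L, seed = NULL) {
  config <- cohort$config
  set.seed(seed %||% (config$seed + 1L))
  dm <- cohort$domain_map
  all_prot <- unique(dm$protein_accession)
  fam_size <- config$proteins_per_family
  sets <- list()
  desc <- character()
  for (m in seq_len(config$n_modules)) {
    fam_prot <- sort(unique(dm$protein_accession[
      dm$pfam_id == sprintf("PF%05d", (m - 1L) * config$domains_per_family + 1L)]))
    term <- sprintf("family_%02d", m)
    sets[[term]] <- fam_prot
    desc[term] <- sprintf("planted family of module %d", m)
    for (k in seq_len(n_decoys)) {
      dterm <- sprintf("decoy_%02d_%02d", m, k)
      sets[[dterm]] <- sort(sample(all_prot, fam_size))
      desc[dterm] <- "size-matched decoy"
    }
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a synthetic cohort to disk
#'
#' Writes `drugs.tsv`, `activities.tsv`, `domain_map.tsv` and the
#' ground-truth tables `truth_modules.tsv` and `truth_records.tsv` into a
#' directory.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acts <- cohort$activities[, ACTIVITY_COLUMNS, drop = FALSE]
  paths <- c(
    drugs = file.path(dir, "drugs.tsv"),
    activities = file.path(dir, "activities.tsv"),
    domain_map = file.path(dir, "domain_map.tsv"),
    truth_modules = file.path(dir, "truth_modules.tsv"),
    truth_records = file.path(dir, "truth_records.tsv")
  )
  write_tsv(cohort$drugs, paths[["drugs"]])
  write_tsv(acts, paths[["activities"]])
  write_tsv(cohort$domain_map, paths[["domain_map"]])
  write_tsv(data.frame(drug_id = names(cohort$ground_truth$modules),
                       module = as.integer(cohort$ground_truth$modules),
                       stringsAsFactors = FALSE),
            paths[["truth_modules"]])
  write_tsv(cohort$ground_truth$record_validity, paths[["truth_records"]])
  invisible(paths)
}
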