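# High-confidence interaction filtering: reduce raw ChEMBL-style bioactivity
# records to direct, single-protein, potent binding interactions, and collect
# the surviving proteins into per-drug target profiles.

#' Construct an activity filtering policy
#'
#' Encodes the rules separating specific, high-affinity drug-protein binding
#' from noise. A record passes the structural gates (single-protein target,
#' direct relationship, binding/functional assay, no inactivity comment) and
#' then at least one of two potency gates: pChEMBL >= `min_pchembl`, or an
#' exact (`=`) Ki/IC50 measurement at or below `max_activity_nM` (10 uM by
#' default; pChEMBL 5 and 10 uM express the same potency bound on the two
#' scales).
#'
#' @param min_pchembl Minimum pChEMBL value (default 5).
#' @param max_activity_nM Maximum standard activity in nM (default 10000,
#'   i.e. 10 uM).
#' @param allowed_assay_types Assay type codes accepted (default B, F).
#' @param required_relationship_type Target relationship code (default "D",
#'   direct).
#' @param required_target_type Target type (default "SINGLE PROTEIN").
#' @param allowed_standard_types Measurement types accepted for the
#'   concentration gate (default Ki, IC50; case-insensitive).
#' @param required_standard_relation Relation required for the concentration
#'   gate (default "=").
#' @param excluded_comments Activity comments that disqualify a record
#'   (case-insensitive).
#' @param potency_gates `"either"` (default) keeps a record passing the
#'   pChEMBL gate or the concentration gate; `"both"` requires both.
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(min_pchembl = 5,
                          max_activity_nM = 10000,
                          allowed_assay_types = c("B", "F"),
                          required_relationship_type = "D",
                          required_target_type = "SINGLE PROTEIN",
                          allowed_standard_types = c("Ki", "IC50"),
                          required_standard_relation = "=",
                          excluded_comments = c("Inactive", "Not Active",
                                                "Inconclusive"),
                          potency_gates = c("either", "both")) {
  stopifnot(is.numeric(min_pchembl), min_pchembl >= 0,
            is.numeric(max_activity_nM), max_activity_nM > 0)
  potency_gates <- match.arg(potency_gates)
  if (9 - log10(max_activity_nM) > min_pchembl) {
    warning("policy is internally inconsistent: the concentration gate (",
            max_activity_nM, " nM ~ pChEMBL ", round(9 - log10(max_activity_nM), 2),
            ") is stricter than min_pchembl = ", min_pchembl)
  }
  structure(list(
    min_pchembl = min_pchembl,
    max_activity_nM = max_activity_nM,
    allowed_assay_types = allowed_assay_types,
    required_relationship_type = required_relationship_type,
    required_target_type = required_target_type,
    allowed_standard_types = toupper(allowed_standard_types),
    required_standard_relation = required_standard_relation,
    excluded_comments = tolower(excluded_comments),
    potency_gates = potency_gates
  ), class = "filter_policy")
}

# rejection reasons, checked in this order; the audit reports the first hit
FILTER_RULES <- c("target_type", "relationship_type", "assay_type",
                  "activity_comment", "activity")

#' Filter activity records to high-confidence interactions
#'
#' Applies a [filter_policy()] to parsed activity records. Filtering is
#' total: every record is either kept or rejected with the first failing
#' rule recorded in the audit.
#'
#' @param records data.frame from [read_activity_table()] (unit-normalised,
#'   with a `value_nM` column).
#' @param policy A [filter_policy()].
#' @return A list with `kept` (the surviving records) and `audit` (one row
#'   per input record: `row`, `drug_id`, `protein_accession`, `status`
#'   kept/rejected, and `reason` — `NA` for kept records, otherwise one of
#'   `r paste(FILTER_RULES, collapse = ", ")`).
#' @export
filter_activities <- function(records, policy = filter_policy()) {
  stopifnot(is.data.frame(records), inherits(policy, "filter_policy"))
  if (!"value_nM" %in% names(records)) {
    records <- normalise_activity_units(records)
  }
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  fail_target <- is.na(records$target_type) |
    records$target_type != policy$required_target_type
  fail_rel <- is.na(records$relationship_type) |
    records$relationship_type != policy$required_relationship_type
  fail_assay <- is.na(records$assay_type) |
    !records$assay_type %in% policy$allowed_assay_types
  fail_comment <- !is.na(records$activity_comment) &
    tolower(records$activity_comment) %in% policy$excluded_comments

  pass_pchembl <- !is.na(records$pchembl_value) &
    records$pchembl_value >= policy$min_pchembl
  pass_conc <- !is.na(records$standard_type) &
    toupper(records$standard_type) %in% policy$allowed_standard_types &
    !is.na(records$standard_relation) &
    records$standard_relation == policy$required_standard_relation &
    !is.na(records$value_nM) &
    records$value_nM <= policy$max_activity_nM
  fail_potency <- if (policy$potency_gates == "either") {
    !(pass_pchembl | pass_conc)
  } else {
    !(pass_pchembl & pass_conc)
  }

  # first failing rule wins, in fixed order
  reason[fail_potency] <- "activity"
  reason[fail_comment] <- "activity_comment"
  reason[fail_assay] <- "assay_type"
  reason[fail_rel] <- "relationship_type"
  reason[fail_target] <- "target_type"

  kept <- is.na(reason)
  audit <- data.frame(
    row = seq_len(n),
    drug_id = records$drug_id,
    protein_accession = records$protein_accession,
    status = ifelse(kept, "kept", "rejected"),
    reason = reason,
    stringsAsFactors = FALSE
  )
  list(kept = records[kept, , drop = FALSE], audit = audit)
}

#' Build per-drug protein target profiles
#'
#' Collapses kept activity records to the set of proteins each drug binds
#' (the drug's protein profile). One passing record suffices to place a
#' protein in a drug's profile; affinities are not averaged.
#'
#' @param kept data.frame of records that passed [filter_activities()].
#' @return Named list: drug_id -> sorted character vector of protein
#'   accessions. Drugs with no kept record are absent.
#' @export
build_target_profiles <- function(kept) {
  stopifnot(is.data.frame(kept))
  if (nrow(kept) == 0L) return(structure(list(), names = character()))
  profs <- lapply(split(kept$protein_accession, kept$drug_id),
                  function(x) sort(unique(x)))
  profs[order(names(profs))]
}
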