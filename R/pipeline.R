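# End-to-end pipeline: read (or simulate) the three input tables, filter
# activities, infer domain profiles, build the similarity network, summarise
# its topology, detect link communities and write the annotated community
# reports. Every stage writes its table before the next begins; stage tables
# carry a header comment naming the producing stage and the config hash.

#' Default run configuration
#'
#' @param drugs,activities,domain_map Paths to the three input TSVs.
#' @param out_dir Output directory.
#' @param annotation_gmt Optional GMT file for target over-representation.
#' @param min_pchembl,max_activity_nM Potency gates for [filter_policy()].
#' @param q_threshold Domain-profile q-value cutoff.
#' @param bh_scope BH correction scope (`"global"` or `"per_drug"`).
#' @param cutoff,edge_mode Edge rule parameters.
#' @param angle_sweep Cutoffs for the angle-distribution table.
#' @param weighted Weighted edge similarity for link communities.
#' @param vtd_weight Withdrawn-drug weight in the DILI score.
#' @param n_bootstrap Bootstrap samples for the power-law fit.
#' @param seed Integer seed for all stochastic stages.
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(drugs, activities, domain_map, out_dir,
                       annotation_gmt = NULL,
                       min_pchembl = 5, max_activity_nM = 10000,
                       q_threshold = 0.05, bh_scope = "global",
                       cutoff = 3, edge_mode = "either_channel",
                       angle_sweep = c(1, 2, 3, 4), weighted = TRUE,
                       vtd_weight = 1, n_bootstrap = 100, seed = 1L) {
  structure(list(
    paths = list(drugs = drugs, activities = activities,
                 domain_map = domain_map, annotation_gmt = annotation_gmt,
                 out_dir = out_dir),
    filter = list(min_pchembl = min_pchembl, max_activity_nM = max_activity_nM),
    domains = list(q_threshold = q_threshold, bh_scope = bh_scope),
    network = list(cutoff = cutoff, edge_mode = edge_mode,
                   angle_sweep = angle_sweep),
    communities = list(weighted = weighted),
    annotate = list(vtd_weight = vtd_weight),
    topology = list(n_bootstrap = n_bootstrap),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; nested sections
#' (`paths`, `filter`, `domains`, `network`, `communities`, `annotate`,
#' `topology`) are flattened onto the defaults.
#'
#' @param path YAML file.
#' @param overrides Named list of `section.key` overrides (e.g. from CLI
#'   flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    drugs = raw$paths$drugs %||% stop_dilinet("config lacks paths.drugs",
                                              class = "dilinet_validation_error"),
    activities = raw$paths$activities %||%
      stop_dilinet("config lacks paths.activities", class = "dilinet_validation_error"),
    domain_map = raw$paths$domain_map %||%
      stop_dilinet("config lacks paths.domain_map", class = "dilinet_validation_error"),
    out_dir = raw$paths$out_dir %||% "dilinet_out",
    annotation_gmt = raw$paths$annotation_gmt
  )
  for (section in c("filter", "domains", "network", "communities",
                    "annotate", "topology")) {
    for (key in names(raw[[section]])) cfg[[section]][[key]] <- raw[[section]][[key]]
  }
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  for (ov in names(overrides)) {
    parts <- strsplit(ov, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L) cfg[[parts[1]]][[parts[2]]] <- overrides[[ov]]
    else cfg[[ov]] <- overrides[[ov]]
  }
  cfg
}

# hash of the analytical settings; file locations are excluded so the same
# analysis written elsewhere carries the same hash
config_hash <- function(config) {
  settings <- unclass(config)
  settings$paths <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(settings), tmp)
  unname(tools::md5sum(tmp))
}

stage_header <- function(stage, hash) {
  c(paste0("stage: ", stage), paste0("config: ", hash))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: activity filtering, target profiles, domain
#' enrichment and profiles, similarity network (with angle sweep), topology
#' summary, link communities, community reports and (optionally) target
#' over-representation. Each stage writes its table under
#' `config$paths$out_dir` before the next stage runs; `run_metadata.json`
#' records the seed, thresholds, edge-rule mode and config hash.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$paths$drugs, config$paths$activities,
              config$paths$domain_map)) {
    if (!file.exists(p)) {
      stop_dilinet("input path does not exist: ", p, class = "dilinet_io_error")
    }
  }
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hdr <- function(stage) stage_header(stage, hash)

  drugs <- read_drug_table(config$paths$drugs)
  acts <- read_activity_table(config$paths$activities)
  dmap_df <- read_tsv_raw(config$paths$domain_map)
  require_columns(dmap_df, c("protein_accession", "pfam_id"),
                  config$paths$domain_map)
  validate_pfam_ids(dmap_df$pfam_id)
  dmap <- lapply(split(dmap_df$pfam_id, dmap_df$protein_accession),
                 function(x) sort(unique(x)))

  policy <- filter_policy(min_pchembl = config$filter$min_pchembl,
                          max_activity_nM = config$filter$max_activity_nM)
  filt <- filter_activities(acts, policy)
  write_tsv(filt$kept[, ACTIVITY_COLUMNS, drop = FALSE],
            file.path(out, "kept_activities.tsv"), hdr("filter"))
  write_tsv(filt$audit, file.path(out, "filter_audit.tsv"), hdr("filter"))

  profiles <- build_target_profiles(filt$kept)
  write_tsv(data.frame(
    drug_id = rep(names(profiles), lengths(profiles)),
    protein_accession = unlist(profiles, use.names = FALSE),
    stringsAsFactors = FALSE
  ), file.path(out, "target_profiles.tsv"), hdr("profiles"))

  enrich <- domain_enrichment(profiles, dmap, scope = config$domains$bh_scope)
  write_tsv(enrich, file.path(out, "domain_enrichment.tsv"), hdr("domains"))
  dom_profiles <- build_domain_profiles(enrich, config$domains$q_threshold)
  write_tsv(data.frame(
    drug_id = rep(names(dom_profiles), lengths(dom_profiles)),
    pfam_id = unlist(dom_profiles, use.names = FALSE),
    stringsAsFactors = FALSE
  ), file.path(out, "domain_profiles.tsv"), hdr("domains"))

  pairs <- pair_similarities(profiles, dom_profiles)
  rule <- edge_rule(config$network$cutoff, config$network$edge_mode)
  net <- build_network(profiles, dom_profiles, rule = rule, drugs = drugs,
                       pairs = pairs)
  write_network(net, file.path(out, "network"), hdr("network"))
  write_tsv(angle_distribution(pairs, config$network$angle_sweep,
                               config$network$edge_mode),
            file.path(out, "angle_distribution.tsv"), hdr("network"))

  topo <- topology_summary(net, n_bootstrap = config$topology$n_bootstrap,
                           seed = config$seed)
  topo_df <- data.frame(
    key = c("n_nodes", "n_edges", "powerlaw_exponent", "powerlaw_xmin",
            "ks_statistic", "ks_p_value", "assortativity_A", "modularity_M"),
    value = c(topo$n_nodes, topo$n_edges, topo$powerlaw_exponent,
              topo$powerlaw_xmin, topo$ks_statistic, topo$ks_p_value,
              topo$assortativity_A, topo$modularity_M),
    stringsAsFactors = FALSE
  )
  write_tsv(topo_df, file.path(out, "topology_summary.tsv"), hdr("topology"))
  write_tsv(data.frame(degree = names(topo$degree_distribution),
                       probability = as.numeric(topo$degree_distribution),
                       stringsAsFactors = FALSE),
            file.path(out, "degree_distribution.tsv"), hdr("topology"))

  partition <- NULL
  reports <- NULL
  memberships <- NULL
  if (nrow(net$edges) >= 2L) {
    partition <- link_communities(net, weighted = config$communities$weighted)
    write_tsv(partition_table(partition),
              file.path(out, "communities.tsv"), hdr("communities"))
    memberships <- drug_memberships(partition)
    write_tsv(data.frame(
      drug_id = rep(names(memberships), lengths(memberships)),
      community_id = unlist(memberships, use.names = FALSE),
      stringsAsFactors = FALSE
    ), file.path(out, "memberships.tsv"), hdr("communities"))
    reports <- community_reports(partition, drugs, dom_profiles,
                                 vtd_weight = config$annotate$vtd_weight)
    write_tsv(reports, file.path(out, "community_reports.tsv"), hdr("annotate"))
    if (!is.null(config$paths$annotation_gmt)) {
      sets <- read_gmt(config$paths$annotation_gmt)
      universe <- sort(unique(unlist(profiles, use.names = FALSE)))
      ora <- do.call(rbind, lapply(partition$communities, function(cm) {
        tg <- community_targets(cm, profiles)
        if (!length(tg)) return(NULL)
        cbind(community_id = cm$community_id,
              target_ora(tg, sets, universe))
      }))
      if (!is.null(ora)) {
        write_tsv(ora, file.path(out, "community_ora.tsv"), hdr("annotate"))
      }
    }
  } else {
    warning("fewer than 2 network edges; community stages skipped")
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("dilinet")),
    seed = config$seed,
    config_hash = hash,
    edge_rule = list(cutoff = config$network$cutoff,
                     mode = config$network$edge_mode),
    filter = config$filter,
    q_threshold = config$domains$q_threshold,
    vtd_weight = config$annotate$vtd_weight,
    n_drugs = nrow(drugs), n_activity_records = nrow(acts),
    n_kept_records = nrow(filt$kept),
    n_nodes = topo$n_nodes, n_edges = topo$n_edges,
    n_communities = if (!is.null(partition)) length(partition$communities) else 0L
  )
  jsonlite::write_json(meta, file.path(out, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(drugs = drugs, activities = acts, filtered = filt,
                 profiles = profiles, enrichment = enrich,
                 domain_profiles = dom_profiles, pairs = pairs, network = net,
                 topology = topo, partition = partition,
                 memberships = memberships, reports = reports,
                 metadata = meta))
}
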