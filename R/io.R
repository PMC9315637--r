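# Readers and writers for the tab-separated tables and GraphML export used
# throughout the pipeline. All tables are UTF-8 TSV with a header row; "NA"
# and the empty string both denote missing values.

ACTIVITY_COLUMNS <- c(
  "drug_id", "protein_accession", "assay_type", "relationship_type",
  "target_type", "standard_type", "standard_relation", "standard_value",
  "standard_units", "pchembl_value", "activity_comment"
)

read_tsv_raw <- function(path, comment.char = "#") {
  if (!file.exists(path)) {
    stop_dilinet("cannot read '", path, "': no such file", class = "dilinet_io_error")
  }
  read.delim(path, sep = "\t", header = TRUE, na.strings = c("NA", ""),
             comment.char = comment.char, stringsAsFactors = FALSE,
             colClasses = "character", check.names = FALSE,
             fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_dilinet("'", path, "' is missing required column(s): ",
                 paste(missing, collapse = ", "),
                 class = "dilinet_format_error")
  }
}

#' Read a drug annotation table
#'
#' Parses a tab-separated table of drugs with their liver-toxicity class and
#' (optionally) a name and therapeutic category. Toxicity classes follow the
#' registry-style grading: `very_toxic` (withdrawn from the market for liver
#' toxicity), `toxic` (acute liver failure or high hepatotoxicity rates),
#' `non_toxic` (low-risk registry drugs) and `safe` (background drugs with no
#' known hepatotoxicity).
#'
#' @param path Path to a TSV file with header naming at least `drug_id` and
#'   `toxicity_class`; `name` and `therapeutic_category` are optional.
#' @return A data.frame with columns `drug_id`, `name`, `toxicity_class`,
#'   `therapeutic_category` (one row per drug).
#' @export
read_drug_table <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("drug_id", "toxicity_class"), path)
  if (nrow(df) == 0L) {
    warning("drug table '", path, "' has a header but no rows")
    return(data.frame(drug_id = character(), name = character(),
                      toxicity_class = character(),
                      therapeutic_category = character(),
                      stringsAsFactors = FALSE))
  }
  bad <- !df$toxicity_class %in% TOXICITY_CLASSES
  if (any(bad)) {
    stop_dilinet("unknown toxicity class(es): ",
                 paste(unique(df$toxicity_class[bad]), collapse = ", "),
                 " (allowed: ", paste(TOXICITY_CLASSES, collapse = ", "), ")",
                 class = "dilinet_validation_error")
  }
  dup <- unique(df$drug_id[duplicated(df$drug_id)])
  if (length(dup)) {
    stop_dilinet("duplicate drug_id(s): ", paste(dup, collapse = ", "),
                 class = "dilinet_validation_error")
  }
  data.frame(
    drug_id = df$drug_id,
    name = if ("name" %in% names(df)) df$name else df$drug_id,
    toxicity_class = df$toxicity_class,
    therapeutic_category =
      if ("therapeutic_category" %in% names(df)) df$therapeutic_category
      else NA_character_,
    stringsAsFactors = FALSE
  )
}

# multiplier converting one unit of the given kind to nM
UNIT_TO_NM <- c("pM" = 1e-3, "nM" = 1, "uM" = 1e3, "µM" = 1e3,
                "mM" = 1e6, "M" = 1e9)

#' Read a ChEMBL-style activity table
#'
#' Parses raw drug-protein bioactivity records. Missing optional fields are
#' preserved as `NA`, never coerced to zero. `standard_value` entries are
#' normalised to nM (`value_nM`) when the unit is molar; pChEMBL consistency
#' (`|pchembl - (9 - log10(value_nM))| <= 0.05`) is checked and flagged in
#' `pchembl_consistent`, but inconsistent rows are kept.
#'
#' @param path Path to a TSV file with the eleven standard activity columns
#'   (`drug_id`, `protein_accession`, `assay_type`, `relationship_type`,
#'   `target_type`, `standard_type`, `standard_relation`, `standard_value`,
#'   `standard_units`, `pchembl_value`, `activity_comment`).
#' @return A data.frame of parsed records with numeric `standard_value`,
#'   `pchembl_value`, derived `value_nM` and logical `pchembl_consistent`.
#' @export
read_activity_table <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, ACTIVITY_COLUMNS, path)
  df <- df[, ACTIVITY_COLUMNS, drop = FALSE]
  for (col in c("standard_value", "pchembl_value")) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad)) {
      stop_dilinet("non-numeric ", col, " at data row(s) ",
                   paste(bad, collapse = ", "), " of '", path, "': ",
                   paste(unique(raw[bad]), collapse = ", "),
                   class = "dilinet_format_error")
    }
    if (any(num < 0, na.rm = TRUE)) {
      stop_dilinet("negative ", col, " at data row(s) ",
                   paste(which(num < 0), collapse = ", "),
                   class = "dilinet_validation_error")
    }
    df[[col]] <- num
  }
  normalise_activity_units(df)
}

# adds value_nM and pchembl_consistent columns
normalise_activity_units <- function(df) {
  mult <- UNIT_TO_NM[df$standard_units]
  df$value_nM <- ifelse(is.na(mult), NA_real_, df$standard_value * unname(mult))
  expected <- 9 - log10(df$value_nM)
  df$pchembl_consistent <- ifelse(
    is.na(df$pchembl_value) | is.na(df$value_nM) | df$value_nM <= 0,
    NA, abs(df$pchembl_value - expected) <= 0.05
  )
  n_bad <- sum(!df$pchembl_consistent, na.rm = TRUE)
  if (n_bad > 0) {
    warning(n_bad, " record(s) have pchembl_value inconsistent with their ",
            "standard_value (kept, flagged in pchembl_consistent)")
  }
  df
}

#' Read a protein-to-Pfam domain map
#'
#' @param path Two-column TSV (`protein_accession`, `pfam_id`), one pair per
#'   row; duplicate pairs are aggregated idempotently.
#' @return A named list mapping each protein accession to its (non-empty)
#'   character vector of Pfam identifiers.
#' @export
read_domain_map <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("protein_accession", "pfam_id"), path)
  validate_pfam_ids(df$pfam_id)
  lapply(split(df$pfam_id, df$protein_accession), function(x) sort(unique(x)))
}

validate_pfam_ids <- function(ids) {
  bad <- ids[is.na(ids) | !grepl("^PF[0-9]{5}$", ids)]
  if (length(bad)) {
    stop_dilinet("malformed Pfam identifier(s): ",
                 paste(unique(bad), collapse = ", "),
                 " (expected 'PF' followed by five digits)",
                 class = "dilinet_validation_error")
  }
  invisible(ids)
}

#' Construct a drug network bundle
#'
#' A network bundle is the on-disk and in-memory form of the drug similarity
#' network: a node table (drugs with toxicity class and category) and an edge
#' table (per unordered drug pair, the two channel hypergeometric indices
#' `h_protein` and `h_domain`, the vector module `alpha` used as edge weight
#' and the vector angle `gamma` in degrees).
#'
#' @param nodes data.frame with columns `drug_id`, `toxicity_class`,
#'   `category`.
#' @param edges data.frame with columns `drug_i`, `drug_j`, `h_protein`,
#'   `h_domain`, `alpha`, `gamma`.
#' @return A validated object of class `network_bundle`.
#' @export
network_bundle <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need_n <- c("drug_id", "toxicity_class", "category")
  need_e <- c("drug_i", "drug_j", "h_protein", "h_domain", "alpha", "gamma")
  if (!all(need_n %in% names(nodes))) {
    stop_dilinet("node table must have columns ", paste(need_n, collapse = ", "),
                 class = "dilinet_validation_error")
  }
  if (!all(need_e %in% names(edges))) {
    stop_dilinet("edge table must have columns ", paste(need_e, collapse = ", "),
                 class = "dilinet_validation_error")
  }
  nodes <- nodes[, need_n, drop = FALSE]
  edges <- edges[, need_e, drop = FALSE]
  if (anyDuplicated(nodes$drug_id)) {
    stop_dilinet("duplicate drug_id in node table", class = "dilinet_validation_error")
  }
  stray <- setdiff(c(edges$drug_i, edges$drug_j), nodes$drug_id)
  if (length(stray)) {
    stop_dilinet("edge endpoint(s) absent from node table: ",
                 paste(stray, collapse = ", "), class = "dilinet_validation_error")
  }
  if (any(edges$drug_i == edges$drug_j)) {
    stop_dilinet("self-loop edges are not allowed", class = "dilinet_validation_error")
  }
  if (anyDuplicated(pair_key(edges$drug_i, edges$drug_j))) {
    stop_dilinet("duplicate unordered drug pair in edge table",
                 class = "dilinet_validation_error")
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "network_bundle")
}

#' @export
print.network_bundle <- function(x, ...) {
  cat("drug similarity network: ", nrow(x$nodes), " drugs, ",
      nrow(x$edges), " links\n", sep = "")
  invisible(x)
}

#' Convert a network bundle to an igraph graph
#'
#' Nodes carry `toxicity_class` and `category` attributes; edges carry the
#' two channel indices, `gamma`, and `weight = alpha`.
#'
#' @param bundle A `network_bundle`.
#' @return An undirected igraph graph.
#' @export
as_igraph <- function(bundle) {
  stopifnot(inherits(bundle, "network_bundle"))
  v <- bundle$nodes
  names(v)[names(v) == "drug_id"] <- "name"
  e <- bundle$edges
  if (nrow(e)) {
    e$weight <- e$alpha
  } else {
    e <- data.frame(drug_i = character(), drug_j = character(),
                    weight = numeric(), stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

# format numeric columns so that write -> read round-trips doubles exactly
format_numeric_cols <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      out <- sprintf("%.17g", df[[col]])
      out[is.na(df[[col]])] <- NA_character_
      df[[col]] <- out
    }
  }
  df
}

write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  write.table(format_numeric_cols(df), con, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
}

#' Write a network bundle to disk
#'
#' Writes `<prefix>_nodes.tsv`, `<prefix>_edges.tsv` and `<prefix>.graphml`
#' (GraphML carries all node and edge attributes). [read_network()] on the
#' same prefix reproduces the bundle exactly.
#'
#' @param bundle A `network_bundle`.
#' @param path_prefix Output path prefix.
#' @param header_lines Optional comment lines ("# "-prefixed) for the TSVs.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(bundle, path_prefix, header_lines = character()) {
  stopifnot(inherits(bundle, "network_bundle"))
  paths <- c(nodes = paste0(path_prefix, "_nodes.tsv"),
             edges = paste0(path_prefix, "_edges.tsv"),
             graphml = paste0(path_prefix, ".graphml"))
  write_tsv(bundle$nodes, paths[["nodes"]], header_lines)
  write_tsv(bundle$edges, paths[["edges"]], header_lines)
  igraph::write_graph(as_igraph(bundle), paths[["graphml"]], format = "graphml")
  invisible(paths)
}

#' Read a network bundle written by [write_network()]
#'
#' @param path_prefix The prefix passed to [write_network()].
#' @return A `network_bundle`.
#' @export
read_network <- function(path_prefix) {
  nodes <- read_tsv_raw(paste0(path_prefix, "_nodes.tsv"))
  edges <- read_tsv_raw(paste0(path_prefix, "_edges.tsv"))
  for (col in c("h_protein", "h_domain", "alpha", "gamma")) {
    edges[[col]] <- as.numeric(edges[[col]])
  }
  network_bundle(nodes, edges)
}

#' Read a GMT-style annotation set file
#'
#' Each line holds a term id, a description and tab-separated member
#' identifiers, as used for KEGG/GO-style over-representation analysis.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (term -> members); the
#'   descriptions are kept in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop_dilinet("cannot read '", path, "': no such file", class = "dilinet_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop_dilinet("annotation file '", path, "' is empty", class = "dilinet_validation_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short)) {
    stop_dilinet("GMT line(s) with fewer than 3 fields: ",
                 paste(which(short), collapse = ", "),
                 class = "dilinet_format_error")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write annotation sets in GMT format
#'
#' @param sets Named list of character vectors (term -> members).
#' @param path Output path.
#' @param descriptions Optional named character vector of term descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% attr(sets, "description") %||%
    setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(term) {
    paste(c(term, desc[[term]] %||% "", sets[[term]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
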