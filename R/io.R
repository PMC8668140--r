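#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

stop_schema    <- function(msg) abort(msg, class = "fosnet_schema_error")
stop_integrity <- function(msg) abort(msg, class = "fosnet_integrity_error")
stop_value     <- function(msg) abort(msg, class = "fosnet_value_error")
stop_usage     <- function(msg) abort(msg, class = "fosnet_usage_error")

# read a CSV forcing the identifier-like columns present in the header to
# character ("F" would otherwise parse as logical FALSE)
read_csv_typed <- function(path, chr_cols) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  spec <- do.call(readr::cols,
                  stats::setNames(rep(list(readr::col_character()),
                                      sum(hdr %in% chr_cols)),
                                  intersect(hdr, chr_cols)))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = spec)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_schema(sprintf("%s is missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Load and validate a long-format Fos count table
#'
#' Reads a comma-separated file with one row per subject x region and columns
#' `subject_id, sex, condition, region, fos_count`. Counts are per-animal
#' mean Fos+ cell counts (averages over imaged slices), so they are real
#' numbers, not integers. Region codes are normalized through
#' [normalize_region()] and validated against [region_registry()]; conditions
#' against [condition_registry()].
#'
#' @param path Path to a CSV file.
#' @param regions Character vector of admissible region codes.
#' @param conditions Character vector of admissible condition codes.
#' @return A validated tibble of class `fos_table` with a `report` attribute
#'   (subjects per condition, rows read). Retrieve the report with
#'   [fos_report()].
#' @export
load_fos_table <- function(path,
                           regions = region_registry(),
                           conditions = condition_codes()) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  raw <- read_csv_typed(path, c("subject_id", "sex", "condition", "region"))
  validate_fos_table(raw, regions = regions, conditions = conditions)
}

#' Validate an in-memory Fos count table
#'
#' @param df Data frame with columns `subject_id, sex, condition, region,
#'   fos_count`.
#' @inheritParams load_fos_table
#' @return The validated `fos_table` tibble (see [load_fos_table()]).
#' @export
validate_fos_table <- function(df,
                               regions = region_registry(),
                               conditions = condition_codes()) {
  require_columns(df, c("subject_id", "sex", "condition", "region", "fos_count"),
                  "Fos count table")
  df <- tibble::as_tibble(df)
  df$region <- normalize_region(as.character(df$region))
  df$subject_id <- as.character(df$subject_id)
  df$sex <- as.character(df$sex)
  df$condition <- as.character(df$condition)

  bad_region <- which(!df$region %in% regions)
  if (length(bad_region) > 0L) {
    stop_integrity(sprintf(
      "unknown region code(s) %s at row(s) %s",
      paste(unique(df$region[bad_region]), collapse = ", "),
      paste(utils::head(bad_region, 5L), collapse = ", ")))
  }
  bad_cond <- which(!df$condition %in% conditions)
  if (length(bad_cond) > 0L) {
    stop_integrity(sprintf(
      "unknown condition code(s) %s at row(s) %s",
      paste(unique(df$condition[bad_cond]), collapse = ", "),
      paste(utils::head(bad_cond, 5L), collapse = ", ")))
  }
  bad_sex <- which(!df$sex %in% c("F", "M"))
  if (length(bad_sex) > 0L) {
    stop_integrity(sprintf("sex must be 'F' or 'M' (row(s) %s)",
                           paste(utils::head(bad_sex, 5L), collapse = ", ")))
  }
  if (any(!is.finite(df$fos_count)) || any(df$fos_count < 0)) {
    stop_value("fos_count must be finite and non-negative")
  }
  dup <- duplicated(df[, c("subject_id", "region")])
  if (any(dup)) {
    first <- df[which(dup)[1L], ]
    stop_integrity(sprintf("duplicate (subject_id, region) pair: (%s, %s)",
                           first$subject_id, first$region))
  }
  per_subj <- df %>%
    dplyr::distinct(.data$subject_id, .data$sex, .data$condition)
  multi <- per_subj$subject_id[duplicated(per_subj$subject_id)]
  if (length(multi) > 0L) {
    stop_integrity(sprintf(
      "subject(s) with more than one (sex, condition) assignment: %s",
      paste(unique(multi), collapse = ", ")))
  }

  report <- list(
    n_rows = nrow(df),
    n_subjects = nrow(per_subj),
    subjects_per_condition = as.list(table(per_subj$condition))
  )
  df <- df[order(match(df$condition, conditions), df$subject_id,
                 match(df$region, regions)), ]
  structure(df, report = report, class = c("fos_table", class(tibble::tibble())))
}

#' @rdname validate_fos_table
#' @param x A `fos_table`.
#' @export
fos_report <- function(x) attr(x, "report")

#' Load behavioral drinking records
#'
#' Expects columns `subject_id, sex, condition, body_weight, intake_d1,
#' intake_d2, licl_dose` and optionally `estrous_state`. Weights are in
#' grams, intakes in mL, doses in mg/kg.
#'
#' @param path CSV path.
#' @param doses Admissible LiCl doses (mg/kg); 0 denotes the NaCl control.
#' @return A validated tibble.
#' @export
load_behavior_table <- function(path, doses = licl_doses()) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  df <- read_csv_typed(path, c("subject_id", "sex", "condition", "estrous_state"))
  require_columns(df, c("subject_id", "sex", "condition", "body_weight",
                        "intake_d1", "intake_d2", "licl_dose"),
                  "behavior table")
  if (!"estrous_state" %in% names(df)) df$estrous_state <- NA_character_
  if (any(df$body_weight <= 0)) stop_value("body_weight must be positive")
  if (any(df$intake_d1 < 0 | df$intake_d2 < 0)) stop_value("intakes must be >= 0")
  if (any(!df$licl_dose %in% doses)) {
    stop_value(sprintf("licl_dose must be one of: %s",
                       paste(doses, collapse = ", ")))
  }
  if (any(duplicated(df$subject_id))) stop_integrity("duplicate subject_id")
  tibble::as_tibble(df)
}

#' Load per-minute USV call counts
#'
#' Wide format: one row per subject with columns `min55_1 .. min55_10` and
#' `min22_1 .. min22_10` holding non-negative integer call counts per 1-minute
#' block of the 10-minute recording, plus `subject_id, sex, condition`.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
load_usv_table <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  df <- read_csv_typed(path, c("subject_id", "sex", "condition"))
  cols <- c("subject_id", "sex", "condition",
            paste0("min55_", 1:10), paste0("min22_", 1:10))
  require_columns(df, cols, "USV table")
  counts <- as.matrix(df[, c(paste0("min55_", 1:10), paste0("min22_", 1:10))])
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_value("USV counts must be non-negative integers")
  }
  if (any(duplicated(df$subject_id))) stop_integrity("duplicate subject_id")
  tibble::as_tibble(df)
}

#' Load time-sampled nausea behavior observations
#'
#' Long format: `subject_id, behavior, epoch_index, block_index, score` with
#' `behavior` in pica/LOB/ptosis, `epoch_index` 0..11 (one epoch every 5 min
#' over 1 h), `block_index` 0..1 (two consecutive 15-s blocks per epoch) and
#' `score` 0..3.
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
load_nausea_table <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  df <- read_csv_typed(path, c("subject_id", "behavior"))
  require_columns(df, c("subject_id", "behavior", "epoch_index",
                        "block_index", "score"), "nausea table")
  if (!all(df$behavior %in% c("pica", "LOB", "ptosis"))) {
    stop_value("behavior must be one of pica, LOB, ptosis")
  }
  if (!all(df$epoch_index %in% 0:11)) stop_value("epoch_index must be 0..11")
  if (!all(df$block_index %in% 0:1)) stop_value("block_index must be 0 or 1")
  if (!all(df$score %in% 0:3)) stop_value("score must be an integer in 0..3")
  dup <- duplicated(df[, c("subject_id", "behavior", "epoch_index", "block_index")])
  if (any(dup)) stop_integrity("duplicate (subject, behavior, epoch, block) observation")
  tibble::as_tibble(df)
}

edge_table <- function(net) {
  if (inherits(net, "fos_diffnet")) net <- net$network
  net$edges
}

network_regions <- function(net) {
  if (inherits(net, "fos_diffnet")) net <- net$network
  net$regions
}

#' Write a thresholded or differential network to disk
#'
#' Serializes a network in one of three formats. `edge_list` is a TSV with
#' columns `node_a, node_b, r, p, n, sign`; `adjacency` is a symmetric CSV
#' matrix in registry order with 0 for absent edges; `graphml` is written via
#' igraph with node attributes (degree, component, isolate) and edge
#' attributes (r, p, n, sign) and can be read back with [read_network()].
#'
#' @param net A `fos_network` or `fos_diffnet`.
#' @param path Output file path.
#' @param format One of `"edge_list"`, `"adjacency"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_list", "adjacency", "graphml")) {
  if (!inherits(net, c("fos_network", "fos_diffnet"))) {
    stop_usage("net must be a fos_network or fos_diffnet")
  }
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_usage(
                       "unknown format; use edge_list, adjacency or graphml"))
  edges <- edge_table(net)
  if (format == "edge_list") {
    out <- edges[, c("node_a", "node_b", "r", "p", "n", "sign")]
    readr::write_tsv(out, path, progress = FALSE)
  } else if (format == "adjacency") {
    adj <- network_adjacency(net)
    df <- tibble::as_tibble(adj, rownames = "region")
    readr::write_csv(df, path, progress = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @details `read_network()` reads back a graphml file written by
#'   `write_network()` and returns the igraph object.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Convert a network to an igraph object
#'
#' Nodes are all registry regions (isolates included); edge attributes carry
#' the retained correlation (`r`), p-value, per-pair n and sign; node
#' attributes carry degree, component membership and an isolate flag.
#'
#' @param net A `fos_network` or `fos_diffnet`.
#' @return An igraph undirected graph.
#' @export
as_igraph <- function(net) {
  if (inherits(net, "fos_diffnet")) net <- net$network
  edges <- net$edges
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b", "r", "p", "n", "sign")],
    directed = FALSE,
    vertices = data.frame(name = net$regions, stringsAsFactors = FALSE))
  comp <- rep(0L, length(net$regions))  # 0 marks isolates
  names(comp) <- net$regions
  comp[names(net$components)] <- net$components
  igraph::V(g)$degree <- as.integer(igraph::degree(g))
  igraph::V(g)$component <- as.integer(comp[igraph::V(g)$name])
  igraph::V(g)$isolate <- igraph::V(g)$name %in% net$isolates
  g
}
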