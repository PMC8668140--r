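#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Defaults
#' mirror the study design: alpha 0.05, sexes pooled, the task conditions
#' COT/BOT/BLT networked, and BOT and BLT each compared against the
#' context-only control COT. Either provide input CSV paths (`fos`,
#' `drinking`, `usv`, `nausea`) or set `simulate = TRUE` to generate
#' synthetic inputs.
#'
#' @param out_dir Output directory for artifacts.
#' @param simulate Generate synthetic inputs instead of reading files.
#' @param fos,drinking,usv,nausea Input CSV paths (ignored when simulating).
#' @param conditions Conditions to build per-condition networks for.
#' @param comparisons List of `c(task, control)` pairs for differential
#'   networks.
#' @param alpha Significance level in (0, 1).
#' @param n_rule Which per-pair n feeds the differential t-test (see
#'   [differential_network()]).
#' @param pool_sexes Pool males and females when correlating.
#' @param seed Seed for simulation.
#' @param fos_config,behavior_config Optional synthetic configs; defaults are
#'   built with the given seed.
#' @return A validated `fosnet_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            simulate = FALSE,
                            fos = NULL, drinking = NULL, usv = NULL,
                            nausea = NULL,
                            conditions = c("COT", "BOT", "BLT"),
                            comparisons = list(c("BOT", "COT"), c("BLT", "COT")),
                            alpha = 0.05,
                            n_rule = "task_n",
                            pool_sexes = TRUE,
                            seed = 1L,
                            fos_config = NULL,
                            behavior_config = NULL) {
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1)) {
    stop_value("alpha must be in (0, 1)")
  }
  if (!n_rule %in% c("task_n", "control_n", "min_n")) {
    stop_value("n_rule must be one of task_n, control_n, min_n")
  }
  if (!simulate) {
    for (p in c(fos, drinking, usv, nausea)) {
      if (!is.null(p) && !file.exists(p)) {
        stop_usage(sprintf("input file not found: %s", p))
      }
    }
    if (is.null(fos)) stop_usage("either set simulate = TRUE or provide a fos path")
  }
  structure(list(out_dir = out_dir, simulate = simulate,
                 fos = fos, drinking = drinking, usv = usv, nausea = nausea,
                 conditions = conditions, comparisons = comparisons,
                 alpha = alpha, n_rule = n_rule, pool_sexes = pool_sexes,
                 seed = as.integer(seed),
                 fos_config = fos_config, behavior_config = behavior_config),
            class = "fosnet_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the same fields as [pipeline_config()]; `comparisons` is a list of
#' two-element `[task, control]` entries.
#'
#' @param path YAML file path.
#' @return A validated `fosnet_pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(args$comparisons)) {
    args$comparisons <- lapply(args$comparisons, unlist)
  }
  do.call(pipeline_config, args)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> behavioral scoring -> per-condition
#' thresholded networks -> differential networks -> summaries, writing all
#' artifacts under `config$out_dir`:
#' \itemize{
#'   \item `data/` simulated input CSVs and `truth.json` (when simulating)
#'   \item `scores/` CTA, USV and nausea score tables and the emitter tally
#'   \item `networks/<cond>_{edges.tsv,adjacency.csv,graph.graphml}`
#'   \item `networks/<task>-<control>_*` for each differential comparison,
#'     plus the full per-pair statistics table
#'   \item `report.json` / `report.md` with degree rankings, component counts
#'     and isolate lists per network
#'   \item `manifest.json` (package version, seed, alpha, n_rule, config
#'     hash) sufficient to reproduce every artifact
#' }
#' Reruns with an identical config and seed produce identical artifacts.
#'
#' @param config A `fosnet_pipeline_config` or path to a YAML file.
#' @return Invisibly, a list with the networks, differential networks, score
#'   tables and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (!inherits(config, "fosnet_pipeline_config")) {
    stop_usage("config must be a fosnet_pipeline_config or a YAML path")
  }
  out <- config$out_dir
  for (d in c("", "data", "scores", "networks")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
            class = "fosnet_pipeline_error", parent = e)
    })
  }

  # --- inputs ---------------------------------------------------------------
  if (config$simulate) {
    fos_cfg <- config$fos_config %||%
      synthetic_fos_config(seed = config$seed)
    beh_cfg <- config$behavior_config %||%
      synthetic_behavior_config(seed = config$seed + 1L)
    fos <- stage("simulate", simulate_fos(fos_cfg, seed = config$seed))
    sim <- stage("simulate", simulate_behavior(beh_cfg, seed = config$seed + 1L))
    readr::write_csv(as.data.frame(fos), file.path(out, "data", "fos.csv"),
                     progress = FALSE)
    readr::write_csv(sim$behavior, file.path(out, "data", "drinking.csv"),
                     progress = FALSE)
    readr::write_csv(sim$usv, file.path(out, "data", "usv.csv"), progress = FALSE)
    readr::write_csv(sim$nausea, file.path(out, "data", "nausea.csv"),
                     progress = FALSE)
    truth <- attr(fos, "truth")
    write_json_file(list(
      seed = config$seed,
      planted_edges = truth$planted_edges,
      n_per_group = truth$n_per_group
    ), file.path(out, "data", "truth.json"))
    drinking <- sim$behavior; usv <- sim$usv; nausea <- sim$nausea
  } else {
    fos <- stage("load", load_fos_table(config$fos))
    drinking <- if (!is.null(config$drinking)) {
      stage("load", load_behavior_table(config$drinking))
    }
    usv <- if (!is.null(config$usv)) stage("load", load_usv_table(config$usv))
    nausea <- if (!is.null(config$nausea)) {
      stage("load", load_nausea_table(config$nausea))
    }
  }

  # --- behavioral scoring ---------------------------------------------------
  scores <- list()
  if (!is.null(drinking)) {
    scores$cta <- stage("score-behavior", score_cta(drinking))
    readr::write_csv(scores$cta, file.path(out, "scores", "cta.csv"),
                     progress = FALSE)
  }
  if (!is.null(usv)) {
    scores$usv <- stage("score-behavior", score_usv(usv))
    scores$tally <- stage("score-behavior", tally_emitters(scores$usv))
    readr::write_csv(scores$usv, file.path(out, "scores", "usv.csv"),
                     progress = FALSE)
    readr::write_csv(scores$tally, file.path(out, "scores", "emitter_tally.csv"),
                     progress = FALSE)
  }
  if (!is.null(nausea)) {
    scores$nausea <- stage("score-behavior", score_nausea(nausea))
    readr::write_csv(scores$nausea, file.path(out, "scores", "nausea.csv"),
                     progress = FALSE)
  }

  # --- networks -------------------------------------------------------------
  corrs <- list(); nets <- list(); summaries <- list()
  safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
  for (cond in config$conditions) {
    cr <- stage("build-networks",
                condition_correlation_matrix(fos, cond,
                                             pool_sexes = config$pool_sexes))
    net <- stage("build-networks", threshold_network(cr, alpha = config$alpha))
    corrs[[cond]] <- cr; nets[[cond]] <- net
    summaries[[cond]] <- network_summary(net)
    base <- file.path(out, "networks", safe_name(cond))
    write_network(net, paste0(base, "_edges.tsv"), "edge_list")
    write_network(net, paste0(base, "_adjacency.csv"), "adjacency")
    write_network(net, paste0(base, "_graph.graphml"), "graphml")
  }
  diffs <- list()
  for (cmp in config$comparisons) {
    key <- paste0(cmp[1], "-", cmp[2])
    dn <- stage("diff-networks",
                differential_network(corrs[[cmp[1]]], corrs[[cmp[2]]],
                                     alpha = config$alpha,
                                     n_rule = config$n_rule))
    diffs[[key]] <- dn
    summaries[[key]] <- network_summary(dn)
    base <- file.path(out, "networks", safe_name(key))
    write_network(dn, paste0(base, "_edges.tsv"), "edge_list")
    write_network(dn, paste0(base, "_adjacency.csv"), "adjacency")
    write_network(dn, paste0(base, "_graph.graphml"), "graphml")
    readr::write_csv(dn$pairs, paste0(base, "_pairs.csv"), progress = FALSE)
  }

  # --- report and manifest --------------------------------------------------
  report <- lapply(summaries, function(s) {
    list(condition = s$condition,
         n_edges = s$n_edges,
         n_components = s$n_components,
         isolates = s$isolates,
         all_regions_involved = s$all_regions_involved,
         degree_ranking = as.list(stats::setNames(s$ranking$degree,
                                                  s$ranking$region)))
  })
  write_json_file(report, file.path(out, "report.json"))
  writeLines(report_markdown(summaries), file.path(out, "report.md"))

  manifest <- list(
    package = "fosnet",
    version = as.character(utils::packageVersion("fosnet")),
    seed = config$seed,
    alpha = config$alpha,
    n_rule = config$n_rule,
    pool_sexes = config$pool_sexes,
    conditions = config$conditions,
    comparisons = lapply(config$comparisons, as.list),
    simulate = config$simulate,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")])
  )
  write_json_file(manifest, file.path(out, "manifest.json"))

  invisible(list(fos = fos, scores = scores, correlations = corrs,
                 networks = nets, differential = diffs,
                 summaries = summaries, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

report_markdown <- function(summaries) {
  lines <- c("# Network report", "")
  for (s in summaries) {
    lines <- c(lines,
               sprintf("## %s", s$condition),
               "",
               sprintf("- edges: %d", s$n_edges),
               sprintf("- components: %d", s$n_components),
               sprintf("- isolates: %s",
                       if (length(s$isolates)) paste(s$isolates, collapse = ", ")
                       else "(none)"),
               "- degree ranking:",
               sprintf("    - %s: %d", s$ranking$region, s$ranking$degree),
               "")
  }
  lines
}
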