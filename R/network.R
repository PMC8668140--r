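#' Pearson correlation with t-based two-tailed p-value
#'
#' Computes the sample Pearson correlation of two paired vectors after
#' pairwise deletion of missing values, with the p-value obtained from the
#' Student t statistic `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom (two-tailed).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with elements `r`, `p`, `n`, `t`, `df`, and `status`
#'   (`"ok"`, `"insufficient_n"` if fewer than 3 complete pairs, or
#'   `"constant"` if either vector is constant; in those cases `r` and `p`
#'   are `NA`).
#' @export
#' @examples
#' pearson_r_p(1:5, c(1, 3, 2, 5, 4))
pearson_r_p <- function(x, y) {
  if (length(x) != length(y)) stop_value("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    return(list(r = NA_real_, p = NA_real_, n = n, t = NA_real_,
                df = NA_integer_, status = "insufficient_n"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, t = NA_real_,
                df = NA_integer_, status = "constant"))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  tt <- r_to_t(r, n)
  p <- if (is.infinite(tt$t)) 0 else 2 * stats::pt(-abs(tt$t), df = tt$df)
  list(r = r, p = p, n = n, t = tt$t, df = tt$df, status = "ok")
}

#' Fisher r-to-z transformation and its inverse
#'
#' `fisher_z()` computes `z = 1/2 * ln((1 + r) / (1 - r))`, the
#' variance-stabilizing transform of the Pearson correlation that makes
#' correlations from different conditions comparable by subtraction.
#' `inverse_fisher()` maps z back to a correlation in (-1, 1).
#'
#' With `clamp = TRUE` (the default) correlations of magnitude 1 — which can
#' arise from degenerate small-n data and have infinite z — are clamped to
#' `1 - 1e-12` before transforming, and a `clamped` attribute marks the
#' affected entries.
#'
#' @param r Numeric vector of correlations in \[-1, 1\].
#' @param z Numeric vector of Fisher z-scores.
#' @param clamp Clamp |r| = 1 to 1 - 1e-12 instead of raising an error.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' fisher_z(0.5)            # 0.5 * log(3)
#' inverse_fisher(fisher_z(0.3))
fisher_z <- function(r, clamp = TRUE) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop_value("|r| must be <= 1")
  hit <- abs(r) >= 1 & !is.na(r)
  if (any(hit)) {
    if (!clamp) stop_value("|r| = 1 has infinite z; enable clamp to proceed")
    r[hit] <- sign(r[hit]) * (1 - 1e-12)
  }
  z <- 0.5 * (log(1 + r) - log(1 - r))
  if (any(hit)) attr(z, "clamped") <- which(hit)
  z
}

#' @rdname fisher_z
#' @export
inverse_fisher <- function(z) {
  e <- exp(2 * z)
  r <- (e - 1) / (e + 1)
  r[is.infinite(z)] <- sign(z[is.infinite(z)])
  r
}

#' t statistic for a correlation coefficient
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `df = n - 2`. This is the
#' statistic used both for per-condition correlation testing and for
#' re-testing back-transformed differential correlations.
#'
#' @param r Correlation in \[-1, 1\].
#' @param n Number of paired observations (>= 3).
#' @return List with `t` and `df`. `|r| = 1` yields `t = Inf` (reported p is
#'   0 downstream and the pair is flagged).
#' @export
#' @examples
#' r_to_t(0.5, 11)
r_to_t <- function(r, n) {
  if (any(n < 3)) stop_value("n must be >= 3")
  if (any(abs(r) > 1, na.rm = TRUE)) stop_value("|r| must be <= 1")
  df <- n - 2
  t <- ifelse(abs(r) == 1, sign(r) * Inf, r * sqrt(df) / sqrt(1 - r^2))
  list(t = t, df = df)
}

new_fos_corr <- function(condition, regions, r, p, n, status) {
  dimnames(r) <- dimnames(p) <- dimnames(n) <- dimnames(status) <-
    list(regions, regions)
  structure(list(condition = condition, regions = regions,
                 r = r, p = p, n = n, status = status),
            class = "fos_corr")
}

#' Per-condition region-by-region correlation matrices
#'
#' For one experimental condition, computes the Pearson correlation, its
#' two-tailed p-value and the complete-case subject count for every pair of
#' regions, using pairwise deletion. Males and females are pooled by default,
#' as done to obtain adequate statistical power for network analysis; set
#' `sex` to fit a single-sex matrix.
#'
#' @param fos A validated `fos_table` (see [load_fos_table()]).
#' @param condition A condition code present in the table.
#' @param pool_sexes Pool males and females (default `TRUE`).
#' @param sex If `pool_sexes = FALSE`, which sex (`"F"` or `"M"`) to use.
#' @param regions Region ordering; defaults to the registry.
#' @return A `fos_corr` object: symmetric `r`, `p`, `n` matrices over the
#'   regions present, with `NA` and a `status` flag for pairs that are
#'   constant or have fewer than 3 complete cases.
#' @export
condition_correlation_matrix <- function(fos, condition, pool_sexes = TRUE,
                                         sex = NULL,
                                         regions = region_registry()) {
  sub <- fos[fos$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) stop_value(sprintf("condition '%s' not present", condition))
  if (!pool_sexes) {
    if (is.null(sex)) stop_usage("sex must be given when pool_sexes = FALSE")
    sub <- sub[sub$sex == sex, , drop = FALSE]
    if (nrow(sub) == 0L) stop_value(sprintf("no %s subjects in %s", sex, condition))
  }
  regs <- regions[regions %in% unique(sub$region)]
  wide <- tidyr::pivot_wider(sub[, c("subject_id", "region", "fos_count")],
                             names_from = "region", values_from = "fos_count")
  mat <- as.matrix(wide[, regs, drop = FALSE])
  k <- length(regs)
  if (nrow(mat) < 3L) stop_value("need at least 3 subjects for correlation")
  r <- p <- n <- matrix(NA_real_, k, k)
  status <- matrix("ok", k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      res <- pearson_r_p(mat[, i], mat[, j])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
      n[i, j] <- n[j, i] <- res$n
      status[i, j] <- status[j, i] <- res$status
    }
    n[i, i] <- sum(is.finite(mat[, i]))
  }
  new_fos_corr(if (pool_sexes) condition else paste0(condition, ":", sex),
               regs, r, p, n, status)
}

#' @export
print.fos_corr <- function(x, ...) {
  cat(sprintf("<fos_corr> condition %s: %d regions, n per pair %s-%s\n",
              x$condition, length(x$regions),
              min(x$n[upper.tri(x$n)], na.rm = TRUE),
              max(x$n[upper.tri(x$n)], na.rm = TRUE)))
  invisible(x)
}

region_pairs <- function(regions) {
  k <- length(regions)
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

new_fos_network <- function(condition, alpha, regions, edges) {
  edges <- tibble::as_tibble(edges)
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = regions))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  isolates <- regions[deg[regions] == 0]
  membership <- comp$membership[setdiff(regions, isolates)]
  # renumber components by first-region appearance in registry order
  if (length(membership) > 0) {
    first <- tapply(match(names(membership), regions), membership, min)
    relabel <- rank(first)
    membership <- stats::setNames(as.integer(relabel[as.character(membership)]),
                                  names(membership))
  } else {
    membership <- stats::setNames(integer(0), character(0))
  }
  adj <- matrix(0, length(regions), length(regions),
                dimnames = list(regions, regions))
  if (nrow(edges) > 0) {
    ia <- match(edges$node_a, regions); ib <- match(edges$node_b, regions)
    adj[cbind(ia, ib)] <- edges$r
    adj[cbind(ib, ia)] <- edges$r
  }
  structure(list(condition = condition, alpha = alpha, regions = regions,
                 edges = edges, isolates = isolates,
                 components = membership,
                 n_components = if (length(membership)) max(membership) else 0L,
                 adjacency = adj),
            class = "fos_network")
}

#' Significance-thresholded correlation network
#'
#' Retains exactly the region pairs whose correlation is statistically
#' significant (`p < alpha`, two-tailed); all other correlations are set to 0
#' in the adjacency matrix. Edges carry the correlation, its sign, p and the
#' per-pair n. Independent substructures are the connected components of the
#' retained undirected graph; regions with no retained edges are isolates.
#'
#' @param cr A `fos_corr` from [condition_correlation_matrix()].
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Optional multiple-testing correction applied to the
#'   upper-triangle p-values before thresholding, e.g. `"BH"`. The default
#'   `"none"` matches per-pair testing at `p < 0.05`.
#' @return A `fos_network`: `edges` tibble (`node_a, node_b, r, p, n, sign`),
#'   `isolates`, `components` (membership named by region), `n_components`,
#'   and the zero-filled `adjacency` matrix.
#' @export
threshold_network <- function(cr, alpha = 0.05, p_adjust = "none") {
  if (!inherits(cr, "fos_corr")) stop_usage("cr must be a fos_corr")
  if (!(alpha > 0 && alpha < 1)) stop_value("alpha must be in (0, 1)")
  regs <- cr$regions
  pairs <- region_pairs(regs)
  pvals <- cr$p[pairs]
  if (p_adjust != "none") pvals <- stats::p.adjust(pvals, method = p_adjust)
  keep <- which(!is.na(pvals) & pvals < alpha)
  edges <- tibble::tibble(
    node_a = regs[pairs[keep, 1]],
    node_b = regs[pairs[keep, 2]],
    r = cr$r[pairs[keep, , drop = FALSE]],
    p = pvals[keep],
    n = cr$n[pairs[keep, , drop = FALSE]],
    sign = ifelse(cr$r[pairs[keep, , drop = FALSE]] >= 0, "+", "-")
  )
  new_fos_network(cr$condition, alpha, regs, edges)
}

#' @export
print.fos_network <- function(x, ...) {
  cat(sprintf("<fos_network> %s (alpha = %g): %d edge(s), %d component(s), %d isolate(s)\n",
              x$condition, x$alpha, nrow(x$edges), x$n_components,
              length(x$isolates)))
  invisible(x)
}

#' Differential (subtraction) correlation network
#'
#' Compares a task condition against a control condition pair by pair: both
#' raw correlation matrices are Fisher z-transformed, the control z is
#' subtracted from the task z, the difference is back-transformed to a
#' correlation, and that correlation is re-tested with
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` (two-tailed, `df = n - 2`). Pairs
#' with `p < alpha` form the retained differential graph.
#'
#' The subtraction uses the full (unthresholded) correlation matrices;
#' thresholding first would convert sub-threshold control correlations into
#' spurious differences. Set `subtract_thresholded = TRUE` to zero
#' non-significant entries before subtracting instead.
#'
#' @param task,control `fos_corr` objects over the same region set.
#' @param alpha Significance level for retaining differential edges.
#' @param n_rule Which per-pair n feeds the t-test: the task condition's
#'   complete-case n (`"task_n"`, default), the control's (`"control_n"`), or
#'   the pairwise minimum (`"min_n"`).
#' @param subtract_thresholded Zero non-significant correlations (at `alpha`)
#'   before subtracting.
#' @return A `fos_diffnet`: `pairs` tibble with per-pair `r_task, r_control,
#'   z_task, z_control, z_diff, r_diff, t, df, p, n_used, retained`, the
#'   retained graph as `$network` (a `fos_network`), and `excluded` listing
#'   pairs missing in either input.
#' @export
differential_network <- function(task, control, alpha = 0.05,
                                 n_rule = c("task_n", "control_n", "min_n"),
                                 subtract_thresholded = FALSE) {
  if (!inherits(task, "fos_corr") || !inherits(control, "fos_corr")) {
    stop_usage("task and control must be fos_corr objects")
  }
  n_rule <- match.arg(n_rule)
  if (!identical(task$regions, control$regions)) {
    stop_value("task and control must cover the same region set, same order")
  }
  if (!(alpha > 0 && alpha < 1)) stop_value("alpha must be in (0, 1)")
  regs <- task$regions
  pairs <- region_pairs(regs)
  r_t <- task$r[pairs]; r_c <- control$r[pairs]
  if (subtract_thresholded) {
    r_t[!is.na(task$p[pairs]) & task$p[pairs] >= alpha] <- 0
    r_c[!is.na(control$p[pairs]) & control$p[pairs] >= alpha] <- 0
  }
  n_task <- task$n[pairs]; n_control <- control$n[pairs]
  n_used <- switch(n_rule,
                   task_n = n_task,
                   control_n = n_control,
                   min_n = pmin(n_task, n_control))
  ok <- !is.na(r_t) & !is.na(r_c) & n_used >= 3
  z_t <- ifelse(ok, fisher_z(ifelse(ok, r_t, 0)), NA_real_)
  z_c <- ifelse(ok, fisher_z(ifelse(ok, r_c, 0)), NA_real_)
  z_d <- z_t - z_c
  r_d <- inverse_fisher(z_d)
  df <- ifelse(ok, n_used - 2, NA_real_)
  t <- ifelse(ok, r_d * sqrt(df) / sqrt(pmax(1 - r_d^2, 0)), NA_real_)
  t[ok & abs(r_d) >= 1] <- sign(r_d[ok & abs(r_d) >= 1]) * Inf
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df = df))
  out <- tibble::tibble(
    node_a = regs[pairs[, 1]], node_b = regs[pairs[, 2]],
    r_task = r_t, r_control = r_c,
    z_task = z_t, z_control = z_c, z_diff = z_d,
    r_diff = r_d, t = t, df = df, p = p,
    n_used = n_used, retained = ok & !is.na(p) & p < alpha
  )
  edges <- out[out$retained, , drop = FALSE]
  net <- new_fos_network(
    paste0(task$condition, "-", control$condition), alpha, regs,
    tibble::tibble(node_a = edges$node_a, node_b = edges$node_b,
                   r = edges$r_diff, p = edges$p, n = edges$n_used,
                   sign = ifelse(edges$r_diff >= 0, "+", "-")))
  structure(list(task_condition = task$condition,
                 control_condition = control$condition,
                 alpha = alpha, n_rule = n_rule,
                 pairs = out,
                 excluded = out[!ok, c("node_a", "node_b")],
                 network = net),
            class = "fos_diffnet")
}

#' @export
print.fos_diffnet <- function(x, ...) {
  cat(sprintf("<fos_diffnet> %s - %s (alpha = %g, n_rule = %s): %d retained edge(s)\n",
              x$task_condition, x$control_condition, x$alpha, x$n_rule,
              sum(x$pairs$retained)))
  invisible(x)
}

#' Degree-based summary of a network
#'
#' Per-node degree (number of incident retained edges), a centrality ranking,
#' component count and isolate list. Degree centrality is the default notion
#' of how "central" a region is; betweenness is also reported for reference.
#' Ties in the ranking are broken by registry order.
#'
#' @param net A `fos_network` or `fos_diffnet`.
#' @return A `fos_network_summary` list: `ranking` tibble (`region, degree,
#'   betweenness`), `degrees` (named vector in registry order),
#'   `n_components`, `n_edges`, `isolates`, and `all_regions_involved`
#'   (`TRUE` when no region is an isolate).
#' @export
network_summary <- function(net) {
  if (inherits(net, "fos_diffnet")) net <- net$network
  if (!inherits(net, "fos_network")) stop_usage("net must be a network object")
  g <- as_igraph(net)
  deg <- igraph::degree(g)[net$regions]
  btw <- igraph::betweenness(g, directed = FALSE)[net$regions]
  ranking <- tibble::tibble(region = net$regions,
                            degree = as.integer(deg),
                            betweenness = as.numeric(btw))
  ranking <- ranking[order(-ranking$degree, match(ranking$region, net$regions)), ]
  structure(list(condition = net$condition,
                 ranking = ranking,
                 degrees = stats::setNames(as.integer(deg), net$regions),
                 n_components = net$n_components,
                 n_edges = nrow(net$edges),
                 isolates = net$isolates,
                 all_regions_involved = length(net$isolates) == 0L),
            class = "fos_network_summary")
}

#' @export
print.fos_network_summary <- function(x, ...) {
  cat(sprintf("<network summary> %s: %d edges, %d components; top region %s (degree %d)\n",
              x$condition, x$n_edges, x$n_components,
              x$ranking$region[1], x$ranking$degree[1]))
  invisible(x)
}

#' Adjacency matrix of a network
#'
#' Symmetric matrix in registry order with the retained correlation for each
#' significant pair and 0 elsewhere.
#'
#' @param net A `fos_network` or `fos_diffnet`.
#' @return Numeric matrix.
#' @export
network_adjacency <- function(net) {
  if (inherits(net, "fos_diffnet")) net <- net$network
  net$adjacency
}
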