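# Independent brute-force oracles used to cross-check the package.
# These deliberately avoid the package's code paths: explicit loops for
# moments, a numerically integrated t CDF, and BFS for components.

# Student-t upper tail by numerical integration of the density written out
# from gamma functions (independent of stats::pt).
oracle_t_tail <- function(t, df) {
  if (!is.finite(t)) return(if (t > 0) 0 else 1)
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, lower = abs(t), upper = Inf,
                   rel.tol = 1e-13, abs.tol = 1e-15)$value
}

oracle_p_two_tailed <- function(t, df) 2 * oracle_t_tail(abs(t), df)

# Pearson r with explicit loops; p from the t formula + integrated CDF
oracle_pearson <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  mx <- 0; my <- 0
  for (i in seq_len(n)) { mx <- mx + x[i]; my <- my + y[i] }
  mx <- mx / n; my <- my / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  if (sxx == 0 || syy == 0) return(list(r = NA_real_, p = NA_real_, n = n))
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- if (abs(r) >= 1) 0 else oracle_p_two_tailed(tt, n - 2)
  list(r = r, p = p, n = n)
}

# Edge set of the thresholded network on a subjects x regions matrix
oracle_threshold_edges <- function(mat, alpha) {
  regs <- colnames(mat)
  out <- list()
  for (i in seq_along(regs)) {
    for (j in seq_along(regs)) {
      if (i >= j) next
      res <- oracle_pearson(mat[, i], mat[, j])
      if (!is.na(res$p) && res$p < alpha) {
        out[[length(out) + 1]] <- data.frame(
          node_a = regs[i], node_b = regs[j], r = res$r, p = res$p, n = res$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(node_a = character(), node_b = character(),
                      r = numeric(), p = numeric(), n = numeric()))
  }
  do.call(rbind, out)
}

# Full differential chain per pair on two subjects x regions matrices
oracle_differential <- function(mat_task, mat_control, alpha,
                                n_rule = "task_n") {
  regs <- colnames(mat_task)
  out <- list()
  for (i in seq_along(regs)) {
    for (j in seq_along(regs)) {
      if (i >= j) next
      rt <- oracle_pearson(mat_task[, i], mat_task[, j])
      rc <- oracle_pearson(mat_control[, i], mat_control[, j])
      if (is.na(rt$r) || is.na(rc$r)) next
      n_used <- switch(n_rule, task_n = rt$n, control_n = rc$n,
                       min_n = min(rt$n, rc$n))
      zd <- atanh(min(max(rt$r, -1 + 1e-12), 1 - 1e-12)) -
        atanh(min(max(rc$r, -1 + 1e-12), 1 - 1e-12))
      rd <- tanh(zd)
      tt <- rd * sqrt(n_used - 2) / sqrt(1 - rd^2)
      p <- oracle_p_two_tailed(tt, n_used - 2)
      out[[length(out) + 1]] <- data.frame(
        node_a = regs[i], node_b = regs[j], r_diff = rd, t = tt, p = p,
        retained = p < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Connected components by breadth-first search over an explicit edge list
oracle_components <- function(nodes, edges) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges$node_a[k]; b <- edges$node_b[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  for (start in nodes) {
    if (!is.na(comp[start]) || length(adj[[start]]) == 0) next
    cid <- cid + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, setdiff(adj[[v]], names(comp)[!is.na(comp)]))
    }
  }
  comp[!is.na(comp)]
}

# Convert a subjects x regions matrix into a long fos table
mat_to_fos <- function(mat, condition = "BOT", sex = NULL) {
  n <- nrow(mat); regs <- colnames(mat)
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = n)
  df <- tibble::tibble(
    subject_id = rep(sprintf("%s_S%02d", condition, seq_len(n)), each = length(regs)),
    sex = rep(sex, each = length(regs)),
    condition = condition,
    region = rep(regs, times = n),
    fos_count = as.vector(t(mat))
  )
  validate_fos_table(df, regions = regs, conditions = condition)
}

# Random non-negative data matrix with named region columns
random_fos_matrix <- function(n_subj, n_reg, scale = 100) {
  regs <- region_registry()[seq_len(n_reg)]
  mat <- matrix(abs(rnorm(n_subj * n_reg, mean = scale, sd = scale / 3)),
                nrow = n_subj, dimnames = list(NULL, regs))
  mat
}

# Simulation harness: correlation matrices for one task/control pair with
# planted edges, via the package generator on a truncation-free calibration
flat_calibration <- function(conditions, regions = region_registry(),
                             mean = 100, sd = 20) {
  grid <- expand.grid(region = regions, condition = conditions,
                      sex = c("F", "M"), stringsAsFactors = FALSE)
  tibble::tibble(region = grid$region, condition = grid$condition,
                 sex = grid$sex, mean = mean, sd = sd)
}
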