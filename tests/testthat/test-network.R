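test_that("pearson_r_p matches hand-computed and oracle values", {
  expect_equal(pearson_r_p(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  expect_equal(pearson_r_p(1:4, 4:1)$r, -1.0)
  res <- pearson_r_p(1:5, c(1, 3, 2, 5, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)       # covariance 8 / sqrt(10*10)
  expect_equal(res$t, 2.3094, tolerance = 1e-4)
  expect_equal(res$df, 3)
  expect_equal(res$p, oracle_p_two_tailed(res$t, 3), tolerance = 1e-10)
  expect_equal(res$p, 0.104088, tolerance = 1e-5)
})

test_that("degenerate inputs are flagged, not fatal", {
  expect_equal(pearson_r_p(c(1, 1, 1), c(1, 2, 3))$status, "constant")
  expect_equal(pearson_r_p(c(1, 2), c(1, 2))$status, "insufficient_n")
  expect_true(is.na(pearson_r_p(c(1, 1, 1), c(1, 2, 3))$r))
})

test_that("the Fisher transform is the closed form and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-15)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(inverse_fisher(fisher_z(r)), r, tolerance = 1e-12)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-15)  # odd function
  # agreement with the base hyperbolic implementations (independent route)
  expect_equal(fisher_z(r), atanh(r), tolerance = 1e-14)
  z1 <- fisher_z(1)
  expect_equal(attr(z1, "clamped"), 1L)
  expect_error(fisher_z(1, clamp = FALSE), class = "fosnet_value_error")
  expect_error(fisher_z(1.2), class = "fosnet_value_error")
})

test_that("r_to_t reproduces the hand-computed statistics", {
  expect_equal(r_to_t(0, 7)$t, 0)
  t1 <- r_to_t(0.5, 11)
  expect_equal(t1$t, 1.7321, tolerance = 1e-4)   # 0.5 * 3 / sqrt(0.75)
  expect_equal(t1$df, 9)
  t2 <- r_to_t(0.9, 12)
  expect_equal(t2$t, 6.5293, tolerance = 1e-4)   # 0.9 * sqrt(10) / sqrt(0.19)
  expect_equal(t2$df, 10)
  expect_true(is.infinite(r_to_t(1, 10)$t))
  expect_error(r_to_t(0.5, 2), class = "fosnet_value_error")
})

test_that("condition matrices equal brute-force per-pair recomputation", {
  regs <- region_registry()
  set.seed(21)
  mat <- random_fos_matrix(9, 11)
  fos <- mat_to_fos(mat, condition = "BLT")
  cr <- condition_correlation_matrix(fos, "BLT")
  expect_equal(cr$regions, regs)
  for (i in 1:10) {
    for (j in (i + 1):11) {
      o <- oracle_pearson(mat[, i], mat[, j])
      expect_equal(cr$r[i, j], o$r, tolerance = 1e-12)
      expect_equal(cr$p[i, j], o$p, tolerance = 1e-10)
      expect_equal(cr$r[j, i], cr$r[i, j])
      expect_equal(cr$n[i, j], 9)
    }
  }
})

test_that("a perfectly correlated pair and a constant region are handled", {
  mat <- cbind(vmPFC = c(1, 2, 3, 4), aIC = c(2, 4, 6, 8), NAcC = c(5, 5, 5, 5))
  fos <- mat_to_fos(mat, condition = "AB")
  cr <- condition_correlation_matrix(fos, "AB", regions = colnames(mat))
  expect_equal(cr$r["vmPFC", "aIC"], 1.0)
  expect_true(is.na(cr$r["vmPFC", "NAcC"]))
  expect_equal(cr$status["aIC", "NAcC"], "constant")
  expect_error(condition_correlation_matrix(fos, "BLT"), class = "fosnet_value_error")
})

test_that("thresholding retains exactly the sub-alpha pairs and finds components", {
  regs <- region_registry()
  # no structure, absurdly strict alpha: empty graph, all regions isolated
  set.seed(5)
  fos <- mat_to_fos(random_fos_matrix(8, 11), condition = "COT")
  cr <- condition_correlation_matrix(fos, "COT")
  empty <- threshold_network(cr, alpha = 1e-9)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(empty$isolates, regs)
  expect_equal(empty$n_components, 0L)
  expect_true(all(network_adjacency(empty) == 0))

  # planted 3-node chain: A-B and B-C essentially deterministic
  n <- 10
  a <- rnorm(n)
  mat <- cbind(a, a, a) + matrix(rnorm(3 * n, 0, 0.01), n) + 10
  colnames(mat) <- regs[1:3]
  fos3 <- mat_to_fos(mat, condition = "BOT")
  cr3 <- condition_correlation_matrix(fos3, "BOT", regions = regs[1:3])
  net3 <- threshold_network(cr3)
  # all three pairs significant here: one component covering all 3 nodes
  comp_oracle <- oracle_components(regs[1:3], net3$edges)
  expect_equal(net3$n_components, max(comp_oracle))
  expect_equal(sort(names(net3$components)), sort(names(comp_oracle)))

  # forced single significant pair -> 1 edge, one 2-node component, rest isolated
  mat1 <- cbind(random_fos_matrix(12, 9),
                PVN = 1:12 * 10, VTA = 1:12 * 10 + rnorm(12, 0, 0.01))
  fos1 <- mat_to_fos(mat1, condition = "BLT")
  net1 <- threshold_network(condition_correlation_matrix(fos1, "BLT"), alpha = 1e-8)
  expect_equal(nrow(net1$edges), 1L)
  expect_equal(sort(c(net1$edges$node_a, net1$edges$node_b)), c("PVN", "VTA"))
  expect_equal(net1$n_components, 1L)
  expect_length(net1$isolates, 9L)
  expect_equal(net1$edges$sign, "+")
})

test_that("edge signs follow the correlation sign", {
  set.seed(8)
  x <- rnorm(10)
  mat <- cbind(vmPFC = x + 20, aIC = -x + 20, NAcC = x + 20 + rnorm(10, 0, 0.05))
  fos <- mat_to_fos(mat, condition = "AL")
  net <- threshold_network(condition_correlation_matrix(fos, "AL",
                                                        regions = colnames(mat)))
  neg <- net$edges[net$edges$node_b == "aIC" | net$edges$node_a == "aIC", ]
  expect_true(all(neg$sign == "-"))
  expect_true(all(net$edges$r[net$edges$sign == "-"] < 0))
})

test_that("differential networks reproduce the closed-form chain", {
  # identical inputs: z_diff = 0 everywhere, nothing retained
  set.seed(13)
  fos <- mat_to_fos(random_fos_matrix(10, 6), condition = "BOT")
  cr <- condition_correlation_matrix(fos, "BOT", regions = region_registry()[1:6])
  dn0 <- differential_network(cr, cr)
  expect_true(all(dn0$pairs$z_diff == 0))
  expect_true(all(dn0$pairs$t == 0))
  expect_equal(sum(dn0$pairs$retained), 0L)

  # hand-computed chain: r_task 0.9, r_control 0, n = 12
  z <- fisher_z(0.9) - fisher_z(0)
  expect_equal(z, 1.4722, tolerance = 1e-4)
  expect_equal(inverse_fisher(z), 0.9, tolerance = 1e-12)
  tt <- r_to_t(inverse_fisher(z), 12)
  expect_equal(tt$t, 6.5293, tolerance = 1e-4)
  expect_lt(2 * pt(-abs(tt$t), tt$df), 0.001)

  # small difference at small n falls below the critical t and is dropped
  z2 <- fisher_z(0.3) - fisher_z(0.25)
  r2 <- inverse_fisher(z2)
  expect_equal(r2, 0.0540541, tolerance = 1e-6)
  t2 <- r_to_t(r2, 8)
  expect_equal(t2$t, 0.1325987, tolerance = 1e-6)
  expect_lt(abs(t2$t), qt(0.975, df = 6))
})

test_that("differential networks match the brute-force oracle on real tables", {
  regs <- region_registry()[1:5]
  set.seed(31)
  mt <- random_fos_matrix(8, 5); mc <- random_fos_matrix(8, 5)
  task <- condition_correlation_matrix(mat_to_fos(mt, "BOT"), "BOT", regions = regs)
  ctrl <- condition_correlation_matrix(mat_to_fos(mc, "COT"), "COT", regions = regs)
  for (rule in c("task_n", "control_n", "min_n")) {
    dn <- differential_network(task, ctrl, n_rule = rule)
    o <- oracle_differential(mt, mc, alpha = 0.05, n_rule = rule)
    expect_equal(dn$pairs$r_diff, o$r_diff, tolerance = 1e-12)
    expect_equal(dn$pairs$p, o$p, tolerance = 1e-10)
    expect_equal(dn$pairs$retained, o$retained)
  }
  # mismatched region sets are rejected
  task4 <- condition_correlation_matrix(mat_to_fos(mt[, 1:4], "BOT"), "BOT",
                                        regions = regs[1:4])
  expect_error(differential_network(task4, ctrl), class = "fosnet_value_error")
})

test_that("relabeling regions permutes every output identically", {
  regs <- region_registry()[1:6]
  set.seed(17)
  mat <- random_fos_matrix(9, 6)
  perm <- sample(regs)
  map <- setNames(perm, regs)
  mat_perm <- mat
  colnames(mat_perm) <- unname(map[colnames(mat)])

  net <- threshold_network(condition_correlation_matrix(
    mat_to_fos(mat, "BOT"), "BOT", regions = regs), alpha = 0.2)
  net_p <- threshold_network(condition_correlation_matrix(
    mat_to_fos(mat_perm, "BOT"), "BOT", regions = regs), alpha = 0.2)

  canon <- function(e) {
    key <- apply(cbind(e$node_a, e$node_b), 1,
                 function(ab) paste(sort(ab), collapse = "|"))
    e <- e[order(key), ]
    data.frame(key = sort(key), r = e$r, p = e$p)
  }
  mapped <- net$edges
  mapped$node_a <- unname(map[mapped$node_a])
  mapped$node_b <- unname(map[mapped$node_b])
  expect_equal(canon(mapped), canon(net_p$edges), tolerance = 1e-12)
  expect_equal(sort(unname(map[net$isolates])), sort(net_p$isolates))
})

test_that("differential retention is a threshold rule in |z_diff| at fixed n", {
  set.seed(23)
  for (i in 1:5) {
    mt <- random_fos_matrix(10, 6); mc <- random_fos_matrix(10, 6)
    regs <- colnames(mt)
    dn <- differential_network(
      condition_correlation_matrix(mat_to_fos(mt, "BLT"), "BLT", regions = regs),
      condition_correlation_matrix(mat_to_fos(mc, "COT"), "COT", regions = regs))
    stopifnot(length(unique(dn$pairs$n_used)) == 1)
    zin <- abs(dn$pairs$z_diff[dn$pairs$retained])
    zout <- abs(dn$pairs$z_diff[!dn$pairs$retained])
    if (length(zin) && length(zout)) expect_gt(min(zin), max(zout))
  }
})

test_that("network summaries rank by degree and conserve degree totals", {
  # star graph: hub = first region connected to 4 leaves, near-deterministic
  regs <- region_registry()[1:5]
  n <- 12
  hub_sig <- rnorm(n)
  leaves <- sapply(1:4, function(i) 0.95 * hub_sig + rnorm(n, 0, 0.02) + i * 7)
  mat <- cbind(hub_sig + 10, leaves + 10)
  colnames(mat) <- regs
  mat <- abs(mat)
  net <- threshold_network(condition_correlation_matrix(
    mat_to_fos(mat, "BOT"), "BOT", regions = regs), alpha = 1e-6)
  s <- network_summary(net)
  expect_equal(s$ranking$region[1], regs[1])
  expect_equal(unname(s$degrees[regs[1]]), 4L)
  # degree conservation on random graphs
  set.seed(29)
  for (i in 1:5) {
    fos <- mat_to_fos(random_fos_matrix(8, 7), "COT")
    nt <- threshold_network(condition_correlation_matrix(
      fos, "COT", regions = region_registry()[1:7]), alpha = 0.4)
    ss <- network_summary(nt)
    expect_equal(sum(ss$degrees), 2L * ss$n_edges)
    expect_equal(ss$all_regions_involved, length(ss$isolates) == 0L)
  }
  # empty network: all degrees zero
  fos0 <- mat_to_fos(random_fos_matrix(6, 4), "AN")
  nt0 <- threshold_network(condition_correlation_matrix(
    fos0, "AN", regions = region_registry()[1:4]), alpha = 1e-9)
  expect_true(all(network_summary(nt0)$degrees == 0L))
})

test_that("planted-hub recovery matches the brute-force oracle replicate by replicate", {
  regs <- region_registry()
  hub <- "VTA"
  lv <- c("aIC", "NAcC", "BLA", "CeA")
  cmb <- t(combn(lv, 2))
  pe <- rbind(
    data.frame(region_a = hub, region_b = lv, target_r = 0.85),
    data.frame(region_a = cmb[, 1], region_b = cmb[, 2], target_r = 0.85^2))
  cfg <- synthetic_fos_config(
    calibration = flat_calibration(c("BOT", "COT")),
    n_per_group = c(F = 8, M = 7), conditions = c("BOT", "COT"),
    planted_edges = list(BOT = pe))
  set.seed(47)
  hits_pkg <- hits_oracle <- 0L
  reps <- 30
  for (i in seq_len(reps)) {
    fos <- simulate_fos(cfg, seed = sample.int(1e6, 1))
    wide <- function(cond) {
      sub <- fos[fos$condition == cond, ]
      as.matrix(tidyr::pivot_wider(sub[, c("subject_id", "region", "fos_count")],
                                   names_from = "region",
                                   values_from = "fos_count")[, regs])
    }
    dn <- differential_network(condition_correlation_matrix(fos, "BOT"),
                               condition_correlation_matrix(fos, "COT"))
    deg <- network_summary(dn)$degrees
    o <- oracle_differential(wide("BOT"), wide("COT"), alpha = 0.05)
    odeg <- setNames(integer(length(regs)), regs)
    for (k in which(o$retained)) {
      odeg[o$node_a[k]] <- odeg[o$node_a[k]] + 1L
      odeg[o$node_b[k]] <- odeg[o$node_b[k]] + 1L
    }
    expect_equal(deg, odeg)
    hits_pkg <- hits_pkg + (deg[hub] == max(deg))
    hits_oracle <- hits_oracle + (odeg[hub] == max(odeg))
  }
  expect_equal(hits_pkg, hits_oracle)
  expect_gt(hits_pkg / reps, 0)  # the hub is recoverable, rate set by the oracle
})
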