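grid_adjacency <- function(nr, nc) {
  n <- nr * nc
  a <- matrix(FALSE, n, n)
  idx <- function(r, c) (c - 1) * nr + r
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (r < nr) a[idx(r, c), idx(r + 1, c)] <- a[idx(r + 1, c), idx(r, c)] <- TRUE
    if (c < nc) a[idx(r, c), idx(r, c + 1)] <- a[idx(r, c + 1), idx(r, c)] <- TRUE
  }
  a
}

test_that("an injected connected effect is detected as a significant cluster", {
  set.seed(50)
  adj <- grid_adjacency(4, 6)                     # 24 nodes
  patch <- c(1, 2, 5, 6, 9, 10)                   # connected 6-node block
  n <- 15
  maps <- matrix(rnorm(n * 24, sd = 0.3), n, 24)
  maps[, patch] <- maps[, patch] + 1.5
  res <- cluster_perm_test(maps, adj, "one_sample",
                           config = stat_config(n_permutations = 500, seed = 1))
  sig <- res$clusters[res$clusters$significant & res$clusters$sign > 0, ]
  expect_gte(nrow(sig), 1)
  covered <- unique(unlist(sig$nodes))
  expect_gte(length(intersect(covered, patch)), 5)
  expect_true(all(res$clusters$p >= 1 / 501 & res$clusters$p <= 1))
})

test_that("cluster memberships agree with igraph components", {
  set.seed(51)
  adj <- grid_adjacency(5, 5)
  tmap <- rnorm(25)
  thr <- 0.8
  cl <- corticocereb:::clusters_from_tmap(tmap, thr, corticocereb:::adjacency_to_list(adj))
  pos_nodes <- which(tmap >= thr)
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  comp <- igraph::components(igraph::induced_subgraph(g, pos_nodes))
  ref <- lapply(seq_len(comp$no), function(i) sort(pos_nodes[comp$membership == i]))
  got <- lapply(cl[vapply(cl, function(x) x$sign, 0) > 0], `[[`, "nodes")
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(ref, paste, collapse = ","))
})

test_that("an edgeless graph makes every supra-threshold node its own cluster", {
  set.seed(52)
  adj <- matrix(FALSE, 10, 10)
  maps <- matrix(rnorm(8 * 10), 8, 10)
  maps[, c(2, 7)] <- maps[, c(2, 7)] + 3
  res <- cluster_perm_test(maps, adj, "one_sample",
                           config = stat_config(n_permutations = 100, seed = 2))
  expect_true(all(res$clusters$n_nodes == 1))
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(53)
  adj <- grid_adjacency(4, 6)
  n_rep <- 300
  fp <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    maps <- matrix(rnorm(12 * 24), 12, 24)
    res <- cluster_perm_test(maps, adj, "one_sample",
                             config = stat_config(n_permutations = 200,
                                                  seed = 1000 + r))
    fp[r] <- any(res$clusters$significant)
  }
  rate <- mean(fp)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_gte(rate, ci[1] - 1e-9)
  expect_lte(rate, ci[2] + 1e-9)
})

test_that("two-sample design detects group differences and respects labels", {
  set.seed(54)
  adj <- grid_adjacency(4, 6)
  g <- rep(c("a", "b"), c(12, 12))
  maps <- matrix(rnorm(24 * 24, sd = 0.4), 24, 24)
  maps[g == "a", 1:6] <- maps[g == "a", 1:6] + 1.5
  res <- cluster_perm_test(maps, adj, "two_sample", group = g,
                           config = stat_config(n_permutations = 300, seed = 3))
  expect_true(any(res$clusters$significant))
  expect_error(cluster_perm_test(maps, adj, "two_sample"), "group")
  expect_error(cluster_perm_test(maps, adj, "two_sample", group = rep("a", 24)),
               "two levels")
})

test_that("seeded permutation runs are bit-reproducible", {
  set.seed(55)
  adj <- grid_adjacency(3, 4)
  maps <- matrix(rnorm(10 * 12), 10, 12)
  r1 <- cluster_perm_test(maps, adj, config = stat_config(n_permutations = 150,
                                                          seed = 9))
  r2 <- cluster_perm_test(maps, adj, config = stat_config(n_permutations = 150,
                                                          seed = 9))
  expect_identical(r1, r2)
})

test_that("TFCE matches the hand-enumerable chain example and is monotone", {
  chain <- path_graph(3)
  out <- tfce(c(0, 2, 2), chain, E = 0.5, H = 2, dh = 1)
  expect_equal(out, c(0, sqrt(2) * 5, sqrt(2) * 5), tolerance = 1e-12)
  expect_equal(tfce(rep(0, 5), path_graph(5)), rep(0, 5))

  set.seed(56)
  m1 <- abs(rnorm(10))
  m2 <- m1 + 0.5
  adj <- path_graph(10)
  expect_true(all(tfce(m2, adj, dh = 0.1) >= tfce(m1, adj, dh = 0.1) - 1e-12))
  expect_error(tfce(c(1, NA, 2), chain), "finite")
  expect_error(tfce(c(1, 1, 2), chain, dh = -1), "dh")
})

test_that("TFCE equals exhaustive threshold enumeration on all small integer maps", {
  ring <- path_graph(5); ring[1, 5] <- ring[5, 1] <- TRUE
  star <- matrix(FALSE, 5, 5); star[1, 2:5] <- star[2:5, 1] <- TRUE
  edgeless <- matrix(FALSE, 5, 5)
  graphs <- list(path = path_graph(5), ring = ring, star = star,
                 edgeless = edgeless)
  vals <- as.matrix(expand.grid(0:3, 0:3, 0:3, 0:3, 0:3))
  pick <- seq(1, nrow(vals), by = 3)               # every third of 1024 maps
  for (gname in names(graphs)) {
    adj <- graphs[[gname]]
    for (i in pick) {
      m <- as.numeric(vals[i, ])
      got <- tfce(m, adj, E = 0.5, H = 2, dh = 1)
      ref <- oracle_tfce_integer(m, adj, E = 0.5, H = 2)
      if (max(abs(got - ref)) > 1e-10) {
        fail(sprintf("TFCE mismatch on %s graph, map %s", gname,
                     paste(m, collapse = ",")))
      }
    }
  }
  succeed()
  # signed maps as well
  set.seed(57)
  for (i in 1:50) {
    m <- sample(-3:3, 5, replace = TRUE)
    expect_equal(tfce(m, graphs$path, E = 0.5, H = 2, dh = 1),
                 oracle_tfce_integer(m, graphs$path, 0.5, 2), tolerance = 1e-10)
  }
})

test_that("Benjamini-Hochberg adjustment follows the step-up definition", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$adjusted, rep(0.04, 4))
  expect_equal(fdr_bh(0.2)$adjusted, 0.2)
  expect_equal(fdr_bh(rep(1, 5))$adjusted, rep(1, 5))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("ROI-pair tests control the null and detect injected coupling", {
  set.seed(58)
  n_pairs <- 12
  z1 <- matrix(rnorm(12 * n_pairs), 12)
  z2 <- matrix(rnorm(33 * n_pairs), 33)
  tab <- roi_pair_tests(z1, z2)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$p_between_adj >= tab$p_between))
  expect_lte(mean(abs(tab$t_between) > 2), 0.25)

  z1b <- z1
  z1b[, 3] <- z1b[, 3] + 2.5
  tab2 <- roi_pair_tests(z1b, z2, pair_names = sprintf("p%02d", 1:12))
  expect_true(tab2$sig_within_g1[3])
  expect_true(tab2$sig_between[3])
  expect_lte(sum(tab2$sig_within_g1), 2)
})

test_that("outlier screening applies the strict more-than rule", {
  d <- matrix(1, 3, 100)
  d[1, 1:6] <- 12                                  # 6% above 10 -> excluded
  d[2, 1:4] <- 12                                  # 4% -> kept
  scr <- screen_outliers(d)
  expect_equal(scr$excluded, 1L)
  expect_setequal(scr$kept, c(2L, 3L))
  expect_error(screen_outliers(d, d_threshold = -1), "positive")
})

test_that("noncentral-t power matches its limiting cases and the printed design", {
  expect_equal(power_two_means(0, 20, 20), 0.05, tolerance = 1e-10)
  expect_equal(round(power_two_means(0.5, 107, 33), 1), 0.7)
  expect_gt(power_two_means(5, 50, 50), 0.999)
  expect_gt(power_two_means(0.5, 107, 33, tails = 1),
            power_two_means(0.5, 107, 33, tails = 2))
  expect_error(power_two_means(0.5, 1, 10), "sizes")
})
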