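#' Permutation/statistics configuration
#'
#' @param n_permutations number of permutations (>= 100, default 2000).
#' @param alpha significance level (default 0.05).
#' @param threshold cluster-forming t-threshold; `NULL` uses the two-sided
#'   p = 0.05 critical t for the design's degrees of freedom.
#' @param tfce_e,tfce_h TFCE extent/height exponents (defaults 0.5 and 2).
#' @param tfce_dh TFCE integration step; `NULL` uses `max|t|/50`.
#' @param seed permutation seed.
#' @return a `stat_config` list.
#' @export
stat_config <- function(n_permutations = 2000L, alpha = 0.05, threshold = NULL,
                        tfce_e = 0.5, tfce_h = 2, tfce_dh = NULL, seed = 1L) {
  if (n_permutations < 100) stop_invalid("n_permutations must be >= 100")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 threshold = threshold, tfce_e = tfce_e, tfce_h = tfce_h,
                 tfce_dh = tfce_dh, seed = seed), class = "stat_config")
}

clusters_from_tmap <- function(tmap, thr, adj_list) {
  out <- list()
  for (sgn in c(1, -1)) {
    nodes <- which(sgn * tmap >= thr)
    for (comp in components_bfs(adj_list, nodes)) {
      out[[length(out) + 1L]] <- list(nodes = comp, sign = sgn,
                                      mass = sum(tmap[comp]))
    }
  }
  out
}

one_sample_t <- function(means, ss, n) {
  v <- (ss - n * means^2) / (n - 1)
  means / sqrt(pmax(v, 1e-300) / n)
}

two_sample_t <- function(s1, q1, n1, s2, q2, n2) {
  m1 <- s1 / n1; m2 <- s2 / n2
  sp2 <- ((q1 - n1 * m1^2) + (q2 - n2 * m2^2)) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(pmax(sp2, 1e-300) * (1 / n1 + 1 / n2))
}

#' Cluster-based permutation test on a node graph
#'
#' Computes the observed t-map (one-sample t against zero, or independent
#' two-sample t), forms clusters as supra-threshold connected components of
#' the adjacency graph scored by mass (sum of t), and builds the null
#' distribution of the maximum cluster mass by sign-flipping participant
#' maps (one-sample) or exchanging group labels (two-sample). Cluster
#' p-values use the finite-permutation +1 correction:
#' `p = (1 + #\{null >= observed\}) / (n_permutations + 1)`.
#'
#' @param maps participant x node matrix (one map per participant).
#' @param adjacency symmetric node adjacency (edgeless graphs make every
#'   supra-threshold node its own cluster).
#' @param design `"one_sample"` or `"two_sample"`.
#' @param group group label per participant (two-sample only; exactly two
#'   levels).
#' @param config a [stat_config()].
#' @return a `cluster_result`: `t_map`, `threshold`, `clusters` (tibble with
#'   nodes, sign, mass, p, significant), `null_max`, `alpha`.
#' @export
cluster_perm_test <- function(maps, adjacency,
                              design = c("one_sample", "two_sample"),
                              group = NULL, config = stat_config()) {
  design <- match.arg(design)
  if (!is.matrix(maps) || nrow(maps) < 2 || any(!is.finite(maps))) {
    stop_invalid("maps must be a finite participant x node matrix (>= 2 rows)")
  }
  n <- nrow(maps)
  n_nodes <- ncol(maps)
  if (n_nodes != nrow(adjacency)) stop_invalid("adjacency does not match maps")
  adj_list <- adjacency_to_list(adjacency)
  set.seed(config$seed)

  if (design == "one_sample") {
    df <- n - 1
    ss <- colSums(maps^2)                 # invariant under sign flips
    t_obs <- one_sample_t(colMeans(maps), ss, n)
  } else {
    if (is.null(group)) stop_invalid("two_sample design needs group labels")
    glev <- unique(group)
    if (length(glev) != 2) stop_invalid("group must have exactly two levels")
    g1 <- group == glev[1]
    n1 <- sum(g1); n2 <- n - n1
    df <- n - 2
    maps2 <- maps^2
    t_obs <- two_sample_t(colSums(maps[g1, , drop = FALSE]),
                          colSums(maps2[g1, , drop = FALSE]), n1,
                          colSums(maps[!g1, , drop = FALSE]),
                          colSums(maps2[!g1, , drop = FALSE]), n2)
  }
  thr <- if (is.null(config$threshold)) qt(1 - config$alpha / 2, df) else config$threshold
  obs_clusters <- clusters_from_tmap(t_obs, thr, adj_list)

  null_max <- numeric(config$n_permutations)
  for (p in seq_len(config$n_permutations)) {
    if (design == "one_sample") {
      s <- sample(c(-1, 1), n, replace = TRUE)
      tp <- one_sample_t(drop(s %*% maps) / n, ss, n)
    } else {
      idx <- sample.int(n, n1)
      sel <- logical(n); sel[idx] <- TRUE
      tp <- two_sample_t(colSums(maps[sel, , drop = FALSE]),
                         colSums(maps2[sel, , drop = FALSE]), n1,
                         colSums(maps[!sel, , drop = FALSE]),
                         colSums(maps2[!sel, , drop = FALSE]), n2)
    }
    cl <- clusters_from_tmap(tp, thr, adj_list)
    null_max[p] <- if (length(cl)) max(vapply(cl, function(x) abs(x$mass), 0)) else 0
  }

  if (length(obs_clusters)) {
    pvals <- vapply(obs_clusters, function(cl) {
      (1 + sum(null_max >= abs(cl$mass))) / (config$n_permutations + 1)
    }, 0)
    tab <- tibble::tibble(
      cluster = seq_along(obs_clusters),
      sign = vapply(obs_clusters, function(cl) cl$sign, 0),
      n_nodes = vapply(obs_clusters, function(cl) length(cl$nodes), 0L),
      mass = vapply(obs_clusters, function(cl) cl$mass, 0),
      p = pvals,
      significant = pvals < config$alpha,
      nodes = lapply(obs_clusters, function(cl) cl$nodes))
  } else {
    tab <- tibble::tibble(cluster = integer(0), sign = numeric(0),
                          n_nodes = integer(0), mass = numeric(0),
                          p = numeric(0), significant = logical(0),
                          nodes = list())
  }
  structure(list(t_map = t_obs, threshold = thr, clusters = tab,
                 null_max = null_max, alpha = config$alpha, design = design),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, threshold |t|>=%.3f: %d cluster(s), %d significant\n",
              x$design, x$threshold, nrow(x$clusters), sum(x$clusters$significant)))
  invisible(x)
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum_h e(v, h)^E h^H dh` over thresholds `h` from `dh` to the
#' map maximum, where `e(v, h)` is the extent of the supra-threshold cluster
#' containing `v` at height `h`. Negative values are enhanced on the negated
#' map and re-signed. Monotone: a pointwise-larger map yields a
#' pointwise-larger enhancement.
#'
#' @param stat_map finite numeric node map.
#' @param adjacency symmetric node adjacency.
#' @param E,H extent and height exponents (defaults 0.5, 2).
#' @param dh integration step; `NULL` uses `max|map|/50`.
#' @return enhanced map, same length as `stat_map`.
#' @export
tfce <- function(stat_map, adjacency, E = 0.5, H = 2, dh = NULL) {
  if (any(!is.finite(stat_map))) stop_invalid("stat_map must be finite")
  if (!is.null(dh) && dh <= 0) stop_invalid("dh must be positive")
  if (all(stat_map == 0)) return(stat_map * 0)
  if (is.null(dh)) dh <- max(abs(stat_map)) / 50
  adj_list <- adjacency_to_list(adjacency)
  enhance <- function(m) {
    out <- numeric(length(m))
    mx <- max(m)
    if (mx < dh) return(out)
    for (h in seq(dh, mx, by = dh)) {
      nodes <- which(m >= h)
      for (comp in components_bfs(adj_list, nodes)) {
        out[comp] <- out[comp] + length(comp)^E * h^H * dh
      }
    }
    out
  }
  enhance(pmax(stat_map, 0)) - enhance(pmax(-stat_map, 0))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (via `stats::p.adjust`) and decisions at
#' `alpha`.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param alpha decision level (default 0.05).
#' @return list with `adjusted` and logical `rejected`.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj < alpha)
}

#' Default cerebello-cortical ROI pairs
#'
#' Each cerebellar hemisphere against the six cortical analysis ROIs
#' (frontal, sensorimotor and temporo-parietal, both hemispheres).
#'
#' @return tibble with `roi_x`, `roi_y` (12 rows).
#' @export
default_pairs <- function() {
  cort <- c("frontal_L", "frontal_R", "sensorimotor_L", "sensorimotor_R",
            "TPJ_L", "TPJ_R")
  tibble::tibble(roi_x = rep(c("cerebellum_L", "cerebellum_R"), each = 6),
                 roi_y = rep(cort, 2))
}

#' FDR-corrected ROI-pair t-tests on Z contrasts
#'
#' Within each group a one-sample t-test of the per-participant Z values
#' against zero; between groups an independent two-sample t-test; each
#' family FDR-corrected across pairs. Cohen's d is reported for the
#' between-group comparison.
#'
#' @param z_group1,z_group2 participant x pair matrices of Z values (same
#'   columns).
#' @param pair_names pair labels; default column names.
#' @param alpha decision level.
#' @return tibble: one row per pair with t, p, adjusted p and decisions for
#'   the within-group and between-group tests.
#' @export
roi_pair_tests <- function(z_group1, z_group2, pair_names = NULL,
                           alpha = 0.05) {
  if (is.null(pair_names)) pair_names <- colnames(z_group1)
  if (is.null(pair_names)) pair_names <- sprintf("pair%02d", seq_len(ncol(z_group1)))
  n_pairs <- ncol(z_group1)
  res <- lapply(seq_len(n_pairs), function(j) {
    w1 <- t.test(z_group1[, j])
    w2 <- t.test(z_group2[, j])
    bt <- t.test(z_group1[, j], z_group2[, j], var.equal = TRUE)
    tibble::tibble(pair = pair_names[j],
                   t_within_g1 = unname(w1$statistic), p_within_g1 = w1$p.value,
                   t_within_g2 = unname(w2$statistic), p_within_g2 = w2$p.value,
                   t_between = unname(bt$statistic), p_between = bt$p.value,
                   d_between = cohens_d(z_group1[, j], z_group2[, j]))
  })
  out <- do.call(rbind, res)
  out$p_within_g1_adj <- fdr_bh(out$p_within_g1)$adjusted
  out$p_within_g2_adj <- fdr_bh(out$p_within_g2)$adjusted
  out$p_between_adj <- fdr_bh(out$p_between)$adjusted
  out$sig_within_g1 <- out$p_within_g1_adj < alpha
  out$sig_within_g2 <- out$p_within_g2_adj < alpha
  out$sig_between <- out$p_between_adj < alpha
  out
}

#' Screen participants with implausible effect-size maps
#'
#' A participant is excluded when more than `fraction_threshold` of sources
#' have a Cohen's d (task vs baseline) above `d_threshold` — strictly "more
#' than" on the fraction.
#'
#' @param d_maps participant x source matrix of Cohen's d values.
#' @param d_threshold effect-size cutoff (default 10).
#' @param fraction_threshold source-fraction cutoff (default 0.05).
#' @return list with `kept`, `excluded` (row indices) and `fraction` per
#'   participant.
#' @export
screen_outliers <- function(d_maps, d_threshold = 10, fraction_threshold = 0.05) {
  if (d_threshold <= 0 || fraction_threshold <= 0) {
    stop_invalid("thresholds must be positive")
  }
  frac <- rowMeans(d_maps > d_threshold)
  list(kept = which(frac <= fraction_threshold),
       excluded = which(frac > fraction_threshold),
       fraction = frac)
}

#' Power of the two-independent-means t-test
#'
#' Noncentral-t power with `df = n1 + n2 - 2` and noncentrality
#' `d sqrt(n1 n2 / (n1 + n2))` at the `tails`-sided alpha critical value.
#'
#' @param d standardized effect size.
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level.
#' @param tails 1 or 2 (default 2).
#' @return power (probability of rejecting the null).
#' @export
power_two_means <- function(d, n1, n2, alpha = 0.05, tails = 2) {
  if (n1 < 2 || n2 < 2) stop_invalid("group sizes must be >= 2")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == 2) {
    tc <- qt(1 - alpha / 2, df)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  } else {
    1 - pt(qt(1 - alpha, df), df, ncp)
  }
}
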