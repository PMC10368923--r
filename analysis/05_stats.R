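# Stage 5 — group statistics.
#
# Outlier screening (Cohen's d rule), cluster-based permutation tests of the
# theta Z maps on the source graph (within each group and between groups),
# TFCE maps, and FDR-corrected cerebello-cortical pair tests of the
# coherence Z contrasts. Writes the cluster table, the pair-test table and
# a JSON summary.

source("analysis/00_config.R")

cfg <- analysis_config()
head <- readRDS(file.path(paths$scratch, "head_model.rds"))
zmaps_tab <- utils::read.csv(file.path(paths$results, "source_theta_zmaps.csv"))
conn_tab <- utils::read.csv(file.path(paths$results, "connectivity_zscores.csv"))

ids <- unique(zmaps_tab$participant_id)
groups <- zmaps_tab$group[match(ids, zmaps_tab$participant_id)]
n_nodes <- max(zmaps_tab$node)
z_maps <- t(vapply(ids, function(id) {
  zmaps_tab$z_theta[zmaps_tab$participant_id == id]
}, numeric(n_nodes)))
d_maps <- t(vapply(ids, function(id) {
  zmaps_tab$cohens_d[zmaps_tab$participant_id == id]
}, numeric(n_nodes)))

scr <- screen_outliers(d_maps)
message("Outlier screening: ", length(scr$excluded), " participant(s) excluded.")

asd <- intersect(which(groups == "ASD-like"), scr$kept)
td <- intersect(which(groups == "TD-like"), scr$kept)

cl_asd <- cluster_perm_test(z_maps[asd, ], head$adjacency, "one_sample",
                            config = cfg$stat)
cl_td <- cluster_perm_test(z_maps[td, ], head$adjacency, "one_sample",
                           config = cfg$stat)
cl_bet <- cluster_perm_test(z_maps[c(asd, td), ], head$adjacency, "two_sample",
                            group = groups[c(asd, td)], config = cfg$stat)

tfce_asd <- tfce(cl_asd$t_map, head$adjacency)
message(sprintf("Affected-like group: %d significant cluster(s); TFCE peak %.1f",
                sum(cl_asd$clusters$significant), max(tfce_asd)))
message(sprintf("Control-like group: %d significant cluster(s)",
                sum(cl_td$clusters$significant)))

cluster_rows <- function(res, label) {
  cl <- res$clusters
  if (nrow(cl) == 0) return(NULL)
  tibble::tibble(analysis = label, cluster = cl$cluster, sign = cl$sign,
                 n_nodes = cl$n_nodes, mass = cl$mass, p = cl$p,
                 significant = cl$significant,
                 nodes = vapply(cl$nodes, paste, "", collapse = ";"))
}
clusters <- rbind(cluster_rows(cl_asd, "within_asd_like"),
                  cluster_rows(cl_td, "within_td_like"),
                  cluster_rows(cl_bet, "between_groups"))
utils::write.csv(clusters, file.path(paths$results, "theta_clusters.csv"),
                 row.names = FALSE)

coh <- conn_tab[conn_tab$metric == "coherence", ]
pair_names <- unique(coh$pair)
z_by <- function(g) {
  t(vapply(ids[groups == g], function(id) {
    coh$z[coh$participant_id == id][match(pair_names,
                                          coh$pair[coh$participant_id == id])]
  }, numeric(length(pair_names))))
}
pair_tab <- roi_pair_tests(z_by("ASD-like"), z_by("TD-like"), pair_names,
                           alpha = cfg$stat$alpha)
utils::write.csv(pair_tab, file.path(paths$results, "pair_tests.csv"),
                 row.names = FALSE)
message("Significant within-group coherence pairs (affected-like, FDR):")
print(pair_tab$pair[pair_tab$sig_within_g1])

summary <- list(
  seed = cfg$sim$seed,
  outliers_excluded = scr$excluded,
  n_sig_clusters_asd_like = sum(cl_asd$clusters$significant),
  n_sig_clusters_td_like = sum(cl_td$clusters$significant),
  n_sig_clusters_between = sum(cl_bet$clusters$significant),
  tfce_peak_asd_like = max(tfce_asd),
  sig_pairs_asd_like = pair_tab$pair[pair_tab$sig_within_g1],
  sig_pairs_td_like = pair_tab$pair[pair_tab$sig_within_g2])
jsonlite::write_json(summary, file.path(paths$results, "stats_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Stage 5 complete; tables under results/.")
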