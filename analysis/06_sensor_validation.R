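# Stage 6 — sensor-level validation contrasts.
#
# The two classic sanity checks, run with the same cluster machinery on the
# electrode k-nearest-neighbour graph: alpha power (8-13 Hz) should rise
# with eyes closed, and mu power (10-13 Hz) should fall over central
# sensors during the interaction task. Uses the cached cleaned epochs.

source("analysis/00_config.R")

cfg <- analysis_config()
head <- readRDS(file.path(paths$scratch, "head_model.rds"))
manifest <- utils::read.csv(file.path(paths$results, "cohort_manifest.csv"))

z_alpha <- z_mu <- NULL
for (i in seq_len(nrow(manifest))) {
  id <- manifest$participant_id[i]
  ep <- readRDS(file.path(paths$scratch, paste0(id, "_epochs.rds")))
  keep <- ep$status != "rejected"
  rs_open <- subset_epochs(ep, keep & ep$condition == "rs_eyes_open")
  rs_closed <- subset_epochs(ep, keep & ep$condition == "rs_eyes_closed")
  hdc <- subset_epochs(ep, keep & ep$condition %in%
                         c("hdc_inphase", "hdc_antiphase"))
  p_open <- psd_welch(rs_open$data, sfreq = rs_open$sfreq)
  p_closed <- psd_welch(rs_closed$data, sfreq = rs_closed$sfreq)
  p_hdc <- psd_welch(hdc$data, sfreq = hdc$sfreq)
  z_alpha <- rbind(z_alpha, band_zscore(p_closed$psd, p_open$psd,
                                        p_open$freqs, cfg$sim$bands$alpha)$z)
  z_mu <- rbind(z_mu, band_zscore(p_hdc$psd, p_open$psd,
                                  p_open$freqs, cfg$sim$bands$mu)$z)
}

adj <- electrode_adjacency(head)
cl_alpha <- cluster_perm_test(z_alpha, adj, "one_sample", config = cfg$stat)
cl_mu <- cluster_perm_test(z_mu, adj, "one_sample", config = cfg$stat)

pos <- head$electrode_positions
occipital <- which(pos[, 2] < -0.55 & pos[, 3] > -0.2)
central <- which(abs(pos[, 2]) < 0.45 & pos[, 3] > 0.6)
message(sprintf("Alpha (eyes closed vs open): %d significant cluster(s); mean occipital Z = %.2f",
                sum(cl_alpha$clusters$significant),
                mean(colMeans(z_alpha)[occipital])))
message(sprintf("Mu (interaction vs rest): %d significant negative cluster(s); mean central Z = %.2f",
                sum(cl_mu$clusters$significant & cl_mu$clusters$sign < 0),
                mean(colMeans(z_mu)[central])))

out <- rbind(
  tibble::tibble(contrast = "alpha_closed_vs_open", electrode = seq_len(ncol(z_alpha)),
                 mean_z = colMeans(z_alpha), t = cl_alpha$t_map),
  tibble::tibble(contrast = "mu_hdc_vs_rs", electrode = seq_len(ncol(z_mu)),
                 mean_z = colMeans(z_mu), t = cl_mu$t_map))
utils::write.csv(out, file.path(paths$results, "sensor_validation.csv"),
                 row.names = FALSE)
message("Sensor validation table written.")
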