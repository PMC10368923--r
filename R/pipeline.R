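#' Full-run configuration
#'
#' Bundles the stage configurations for the synth -> preprocess -> inverse ->
#' connectivity -> stats chain.
#'
#' @param sim a [sim_config()].
#' @param stat a [stat_config()].
#' @param filter a [filter_spec()].
#' @param inverse_method `"eLORETA"` or `"MNE"`.
#' @param lambda inverse regularization (relative; default 1/9).
#' @param shrinkage noise-covariance shrinkage.
#' @param kappa reject-vs-repair consensus fraction.
#' @param decim decimation factor after epoching.
#' @param n_folds rejection cross-validation folds.
#' @param band analysis band, Hz (default theta).
#' @param orthogonalize also compute leakage-corrected coherence.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(), stat = stat_config(),
                       filter = filter_spec(),
                       inverse_method = c("eLORETA", "MNE"),
                       lambda = 1 / 9, shrinkage = 0.1, kappa = 0.1,
                       decim = 4L, n_folds = 5L,
                       band = NULL, orthogonalize = TRUE) {
  inverse_method <- match.arg(inverse_method)
  if (is.null(band)) band <- sim$bands$theta
  structure(list(sim = sim, stat = stat, filter = filter,
                 inverse_method = inverse_method, lambda = lambda,
                 shrinkage = shrinkage, kappa = kappa, decim = decim,
                 n_folds = n_folds, band = band,
                 orthogonalize = orthogonalize), class = "run_config")
}

config_fingerprint <- function(cfg) {
  txt <- paste(deparse(cfg[!vapply(cfg, is.function, TRUE)]), collapse = "")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

hdc_labels <- function() c("hdc_inphase", "hdc_antiphase")

#' Preprocess one recording per the fixed pipeline order
#'
#' Band-pass filter, average reference, 1 s epoching of the resting-state
#' and interaction segments, decimation, then peak-to-peak rejection fitted
#' on the pooled epochs and applied to all of them.
#'
#' @param rec an `eeg_recording`.
#' @param head the `head_model` (electrode geometry for repairs).
#' @param cfg a [run_config()].
#' @return list with `epochs` (statuses set) and `model`.
#' @export
preprocess_recording <- function(rec, head, cfg) {
  rec <- bandpass(rec, cfg$filter)
  rec <- average_reference(rec)
  ep <- epoch_recording(rec, c("rs_eyes_open", "rs_eyes_closed", hdc_labels()))
  ep <- decimate_epochs(ep, cfg$decim)
  model <- fit_rejection(ep, n_folds = cfg$n_folds, kappa = cfg$kappa)
  ep <- apply_rejection(ep, model, head$electrode_positions)
  list(epochs = ep, model = model)
}

pair_values <- function(per_epoch_conn, rois, pairs) {
  # (epoch, roi, roi, freq) -> (epoch, pair, freq)
  ix <- match(pairs$roi_x, rois)
  iy <- match(pairs$roi_y, rois)
  d <- dim(per_epoch_conn)
  out <- array(0, dim = c(d[1], nrow(pairs), d[4]))
  for (k in seq_len(nrow(pairs))) {
    out[, k, ] <- per_epoch_conn[, ix[k], iy[k], ]
  }
  out
}

#' Single-participant analysis summary
#'
#' Runs preprocessing, source reconstruction and the spectral/connectivity
#' contrasts for one recording and returns the compact quantities the group
#' statistics consume: the source theta-power Z map, the per-source Cohen's
#' d map, Z contrasts of coherence / orthogonalized coherence / wPLI for the
#' cerebello-cortical pairs, and the sensor-level alpha and mu validation
#' contrasts.
#'
#' @param rec an `eeg_recording`.
#' @param head the `head_model`.
#' @param cfg a [run_config()].
#' @return a named list of summary quantities.
#' @export
participant_summary <- function(rec, head, cfg) {
  pp <- preprocess_recording(rec, head, cfg)
  ep <- pp$epochs
  keep <- ep$status != "rejected"
  rs_open <- subset_epochs(ep, keep & ep$condition == "rs_eyes_open")
  rs_closed <- subset_epochs(ep, keep & ep$condition == "rs_eyes_closed")
  hdc <- subset_epochs(ep, keep & ep$condition %in% hdc_labels())

  ncov <- estimate_noise_cov(rs_open, shrinkage = cfg$shrinkage)
  inv <- if (cfg$inverse_method == "eLORETA") {
    eloreta_weights(head$leadfield, ncov, lambda = cfg$lambda)
  } else {
    mne_weights(head$leadfield, ncov, lambda = cfg$lambda)
  }
  src_hdc <- apply_inverse(hdc, inv)
  src_rs <- apply_inverse(rs_open, inv)

  psd_a <- psd_welch(src_hdc$data, sfreq = src_hdc$sfreq)
  psd_b <- psd_welch(src_rs$data, sfreq = src_rs$sfreq)
  zc <- band_zscore(psd_a$psd, psd_b$psd, psd_a$freqs, cfg$band)
  pow_a <- band_average(psd_a$psd, psd_a$freqs, cfg$band)
  pow_b <- band_average(psd_b$psd, psd_b$freqs, cfg$band)
  d_map <- vapply(seq_len(ncol(pow_a)),
                  function(j) cohens_d(pow_a[, j], pow_b[, j]), 0)

  rois <- analysis_rois()
  pairs <- default_pairs()
  roi_a <- extract_roi(src_hdc, head$source_labels, rois)
  roi_b <- extract_roi(src_rs, head$source_labels, rois)
  csd_a <- welch_csd(roi_a)
  csd_b <- welch_csd(roi_b)
  coh_a <- pair_values(coherence(csd_a, per_epoch = TRUE), rois, pairs)
  coh_b <- pair_values(coherence(csd_b, per_epoch = TRUE), rois, pairs)
  z_coh <- band_zscore(coh_a, coh_b, csd_a$freqs, cfg$band)$z
  wpli_a <- pair_values(wpli(csd_a, per_epoch = TRUE), rois, pairs)
  wpli_b <- pair_values(wpli(csd_b, per_epoch = TRUE), rois, pairs)
  z_wpli <- band_zscore(wpli_a, wpli_b, csd_a$freqs, cfg$band)$z
  z_coh_orth <- NULL
  if (isTRUE(cfg$orthogonalize)) {
    csd_ao <- welch_csd(orthogonalize(roi_a))
    csd_bo <- welch_csd(orthogonalize(roi_b))
    coh_ao <- pair_values(coherence(csd_ao, per_epoch = TRUE), rois, pairs)
    coh_bo <- pair_values(coherence(csd_bo, per_epoch = TRUE), rois, pairs)
    z_coh_orth <- band_zscore(coh_ao, coh_bo, csd_ao$freqs, cfg$band)$z
  }

  # sensor-level band contrasts for the validation analyses
  spsd_hdc <- psd_welch(hdc$data, sfreq = hdc$sfreq)
  spsd_open <- psd_welch(rs_open$data, sfreq = rs_open$sfreq)
  spsd_closed <- psd_welch(rs_closed$data, sfreq = rs_closed$sfreq)
  z_alpha <- band_zscore(spsd_closed$psd, spsd_open$psd, spsd_open$freqs,
                         cfg$sim$bands$alpha)$z
  z_mu <- band_zscore(spsd_hdc$psd, spsd_open$psd, spsd_open$freqs,
                      cfg$sim$bands$mu)$z

  list(participant_id = rec$participant_id, group = rec$group,
       n_epochs = length(ep$status),
       n_kept = sum(ep$status == "kept"),
       n_repaired = sum(ep$status == "repaired"),
       n_rejected = sum(ep$status == "rejected"),
       inverse_converged = inv$converged, inverse_iters = inv$n_iter,
       z_theta = zc$z, d_map = d_map,
       z_coh = z_coh, z_wpli = z_wpli, z_coh_orth = z_coh_orth,
       z_alpha_sensor = z_alpha, z_mu_sensor = z_mu)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates the cohort, preprocesses each participant, reconstructs
#' sources, computes theta-power Z maps and cerebello-cortical connectivity
#' contrasts, screens outliers, and runs the cluster-permutation and
#' FDR-corrected pair statistics. Deterministic given the configuration
#' seeds: identical configs yield identical reports.
#'
#' @param cfg a [run_config()].
#' @return a `pipeline_report` list with sections `synth`, `preprocess`,
#'   `inverse`, `connectivity`, `stats` and a `meta` block (config
#'   fingerprint + master seed).
#' @export
run_pipeline <- function(cfg) {
  sim <- cfg$sim
  head <- build_head_model(sim$n_electrodes, sim$nodes_per_region,
                           seed = derive_seed(sim$seed, 999L))
  groups <- c(rep("ASD-like", sim$n_asd), rep("TD-like", sim$n_td))
  ids <- sprintf("sub-%02d", seq_along(groups))
  summaries <- vector("list", length(ids))
  manifest <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rec <- simulate_participant(head, sim, ids[i], groups[i],
                                derive_seed(sim$seed, i))
    summaries[[i]] <- participant_summary(rec, head, cfg)
    eff <- if (groups[i] == "TD-like") null_config(sim) else sim
    manifest[[i]] <- tibble::tibble(
      participant_id = ids[i], group = groups[i],
      n_artifact_windows = nrow(rec$artifacts),
      theta_gain = eff$theta_gain,
      n_coupling_pairs = length(eff$coupling_pairs))
    rm(rec)
  }
  manifest <- do.call(rbind, manifest)

  z_maps <- do.call(rbind, lapply(summaries, `[[`, "z_theta"))
  d_maps <- do.call(rbind, lapply(summaries, `[[`, "d_map"))
  scr <- screen_outliers(d_maps)
  asd <- which(groups == "ASD-like")
  td <- which(groups == "TD-like")
  asd_k <- intersect(asd, scr$kept)
  td_k <- intersect(td, scr$kept)

  stat_cl <- function(rows, design, grp = NULL) {
    cluster_perm_test(z_maps[rows, , drop = FALSE], head$adjacency,
                      design = design, group = grp, config = cfg$stat)
  }
  cl_asd <- if (length(asd_k) >= 2) stat_cl(asd_k, "one_sample") else NULL
  cl_td <- if (length(td_k) >= 2) stat_cl(td_k, "one_sample") else NULL
  cl_between <- if (length(asd_k) >= 2 && length(td_k) >= 2) {
    stat_cl(c(asd_k, td_k), "two_sample", groups[c(asd_k, td_k)])
  } else NULL

  pairs <- default_pairs()
  pair_names <- paste(pairs$roi_x, pairs$roi_y, sep = "~")
  get_pairs <- function(field, rows) {
    m <- do.call(rbind, lapply(summaries[rows], `[[`, field))
    colnames(m) <- pair_names
    m
  }
  pair_tab <- NULL
  if (length(asd_k) >= 2 && length(td_k) >= 2) {
    pair_tab <- roi_pair_tests(get_pairs("z_coh", asd_k),
                               get_pairs("z_coh", td_k),
                               pair_names, alpha = cfg$stat$alpha)
  }

  cl_section <- function(cl) {
    if (is.null(cl)) return(NULL)
    list(n_clusters = nrow(cl$clusters),
         n_significant = sum(cl$clusters$significant),
         clusters = cl$clusters[, c("cluster", "sign", "n_nodes", "mass",
                                    "p", "significant", "nodes")])
  }
  report <- list(
    meta = list(seed = sim$seed, config_fingerprint = config_fingerprint(cfg),
                inverse_method = cfg$inverse_method),
    synth = list(n_recordings = length(ids), manifest = manifest),
    preprocess = list(epochs = tibble::tibble(
      participant_id = ids,
      n_epochs = vapply(summaries, `[[`, 0L, "n_epochs"),
      kept = vapply(summaries, `[[`, 0L, "n_kept"),
      repaired = vapply(summaries, `[[`, 0L, "n_repaired"),
      rejected = vapply(summaries, `[[`, 0L, "n_rejected"))),
    inverse = list(method = cfg$inverse_method, lambda = cfg$lambda,
                   shrinkage = cfg$shrinkage,
                   all_converged = all(vapply(summaries, `[[`, TRUE,
                                              "inverse_converged"))),
    connectivity = list(pairs = pair_names,
                        mean_z_coh_asd = if (length(asd_k))
                          colMeans(get_pairs("z_coh", asd_k)) else NULL,
                        mean_z_wpli_asd = if (length(asd_k))
                          colMeans(get_pairs("z_wpli", asd_k)) else NULL),
    stats = list(outliers_excluded = scr$excluded,
                 cluster_within_asd = cl_section(cl_asd),
                 cluster_within_td = cl_section(cl_td),
                 cluster_between = cl_section(cl_between),
                 pair_tests = pair_tab))
  structure(c(report, list(
    head = head, summaries = summaries, z_maps = z_maps, d_maps = d_maps,
    groups = groups, kept = scr$kept,
    cluster_results = list(asd = cl_asd, td = cl_td, between = cl_between))),
    class = "pipeline_report")
}

#' Sensor-level validation contrasts
#'
#' The classic sanity checks run at the sensor level with the same cluster
#' machinery on the electrode k-nearest-neighbour graph: alpha power
#' (8-13 Hz) should increase with eyes closed, and mu power (10-13 Hz)
#' should decrease over central sensors during the interaction task.
#'
#' @param cfg a [run_config()].
#' @param report optionally a [run_pipeline()] result to reuse (avoids
#'   re-simulating); otherwise a fresh cohort is processed.
#' @return list with `alpha` and `mu` cluster results plus summary scalars
#'   (mean Z over occipital / central sensors).
#' @export
sensor_validation <- function(cfg, report = NULL) {
  if (is.null(report)) report <- run_pipeline(cfg)
  head <- report$head
  adj <- electrode_adjacency(head)
  z_alpha <- do.call(rbind, lapply(report$summaries, `[[`, "z_alpha_sensor"))
  z_mu <- do.call(rbind, lapply(report$summaries, `[[`, "z_mu_sensor"))
  cl_alpha <- cluster_perm_test(z_alpha, adj, "one_sample", config = cfg$stat)
  cl_mu <- cluster_perm_test(z_mu, adj, "one_sample", config = cfg$stat)
  pos <- head$electrode_positions
  occipital <- which(pos[, 2] < -0.55 & pos[, 3] > -0.2)
  central <- which(abs(pos[, 2]) < 0.45 & pos[, 3] > 0.6)
  list(alpha = cl_alpha, mu = cl_mu,
       mean_alpha_z_occipital = mean(colMeans(z_alpha)[occipital]),
       mean_mu_z_central = mean(colMeans(z_mu)[central]))
}
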