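# Stage 4 — cerebello-cortical connectivity.
#
# ROI time courses (8 analysis regions), Welch cross-spectra (125-sample
# segments, 62-sample overlap), per-epoch coherence / orthogonalized
# coherence / wPLI, and the theta-band Z contrast (interaction vs baseline)
# for the 12 cerebello-cortical pairs. Writes one tidy table of Z values.

source("analysis/00_config.R")

cfg <- analysis_config()
head <- readRDS(file.path(paths$scratch, "head_model.rds"))
manifest <- utils::read.csv(file.path(paths$results, "cohort_manifest.csv"))
theta <- cfg$sim$bands$theta
rois <- analysis_rois()
pairs <- default_pairs()
pair_names <- paste(pairs$roi_x, pairs$roi_y, sep = "~")

pair_vals <- function(conn, csd) {
  ix <- match(pairs$roi_x, rois); iy <- match(pairs$roi_y, rois)
  out <- array(0, dim = c(dim(conn)[1], nrow(pairs), dim(conn)[4]))
  for (k in seq_len(nrow(pairs))) out[, k, ] <- conn[, ix[k], iy[k], ]
  out
}

rows <- list()
for (i in seq_len(nrow(manifest))) {
  id <- manifest$participant_id[i]
  src <- readRDS(file.path(paths$scratch, paste0(id, "_sources.rds")))
  roi_a <- extract_roi(src$src_hdc, head$source_labels, rois)
  roi_b <- extract_roi(src$src_rs, head$source_labels, rois)
  for (metric in c("coherence", "coherence_orth", "wpli")) {
    ra <- roi_a; rb <- roi_b
    if (metric == "coherence_orth") {
      ra <- orthogonalize(ra); rb <- orthogonalize(rb)
    }
    csd_a <- welch_csd(ra); csd_b <- welch_csd(rb)
    if (metric == "wpli") {
      va <- pair_vals(wpli(csd_a, per_epoch = TRUE), csd_a)
      vb <- pair_vals(wpli(csd_b, per_epoch = TRUE), csd_b)
    } else {
      va <- pair_vals(coherence(csd_a, per_epoch = TRUE), csd_a)
      vb <- pair_vals(coherence(csd_b, per_epoch = TRUE), csd_b)
    }
    z <- band_zscore(va, vb, csd_a$freqs, theta)$z
    rows[[length(rows) + 1L]] <- tibble::tibble(
      participant_id = id, group = manifest$group[i], metric = metric,
      pair = pair_names, band = "theta", z = z)
  }
  message(id, ": connectivity contrasts done")
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, file.path(paths$results, "connectivity_zscores.csv"),
                 row.names = FALSE)
coh_asd <- tab[tab$metric == "coherence" & tab$group == "ASD-like", ]
message("Mean within-group coherence Z by pair (affected-like group):")
print(sort(round(tapply(coh_asd$z, coh_asd$pair, mean), 2), decreasing = TRUE))
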