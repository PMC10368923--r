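# Stage 2 — preprocessing.
#
# Re-reads each EDF, applies the fixed chain (0.5-48 Hz zero-phase FIR,
# average reference, 1 s epochs of the resting-state and interaction
# segments, decimation by 4, peak-to-peak rejection fitted on the pooled
# epochs) and caches the cleaned epochs. Writes a per-participant rejection
# log.

source("analysis/00_config.R")

cfg <- analysis_config()
head <- readRDS(file.path(paths$scratch, "head_model.rds"))
manifest <- utils::read.csv(file.path(paths$results, "cohort_manifest.csv"))

log <- list()
for (i in seq_len(nrow(manifest))) {
  id <- manifest$participant_id[i]
  rec <- read_edf(file.path(paths$scratch, paste0(id, ".edf")))
  rec$group <- manifest$group[i]
  pp <- preprocess_recording(rec, head, cfg)
  saveRDS(pp$epochs, file.path(paths$scratch, paste0(id, "_epochs.rds")))
  log[[i]] <- tibble::tibble(
    participant_id = id, group = manifest$group[i],
    n_epochs = length(pp$epochs$status),
    kept = sum(pp$epochs$status == "kept"),
    repaired = sum(pp$epochs$status == "repaired"),
    rejected = sum(pp$epochs$status == "rejected"),
    median_threshold_uV = median(pp$model$thresholds))
  message(sprintf("%s: %d kept / %d repaired / %d rejected",
                  id, log[[i]]$kept, log[[i]]$repaired, log[[i]]$rejected))
}
log <- do.call(rbind, log)
utils::write.csv(log, file.path(paths$results, "rejection_log.csv"),
                 row.names = FALSE)
message(sprintf("Overall retention: %.1f%% of epochs kept or repaired.",
                100 * sum(log$kept + log$repaired) / sum(log$n_epochs)))
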