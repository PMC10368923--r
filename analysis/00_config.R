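# Shared configuration for the analysis drivers.
#
# The cohort emulates the study conditions at desk scale: an affected-like
# group carrying a doubled theta amplitude over cerebellar and frontal
# regions plus zero-lag cerebello-cortical phase coupling, and a null
# control-like group. Problem sizes (32 electrodes, 2 nodes per region,
# shortened blocks) keep a full run in minutes; the package functions are
# size-agnostic.

library(corticocereb)

MASTER_SEED <- 2026L

analysis_config <- function(seed = MASTER_SEED) {
  run_config(
    sim = sim_config(n_asd = 12L, n_td = 6L, n_electrodes = 32L,
                     nodes_per_region = 2L, rs_block_s = 15, rs_repeats = 2L,
                     hdc_blocks = 2L, trials_per_block = 5L,
                     interaction_s = 10, seed = seed),
    stat = stat_config(n_permutations = 1000L, seed = seed + 1L))
}

paths <- list(
  scratch = "scratch/analysis",
  results = "results"
)
for (p in paths) dir.create(p, recursive = TRUE, showWarnings = FALSE)
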