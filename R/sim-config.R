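#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults encode
#' the study protocol (resting state: eyes-open then eyes-closed 30 s blocks,
#' repeated three times; coordination task: 4 blocks x 10 trials, each trial
#' 3 s metronome warm-up, 1 s transient, ~15 s interaction, 1 s transient;
#' 1000 Hz sampling) and effect sizes that a theta-band social-interaction
#' study would consider realistic: a doubling of theta amplitude at the
#' affected regions and strongly phase-locked cerebello-cortical coupling in
#' the affected group only.
#'
#' @param n_asd,n_td participants per group (affected-like / control-like).
#' @param sfreq sampling rate, Hz.
#' @param n_electrodes,nodes_per_region head-model size.
#' @param bands named list of frequency bands (Hz); see [default_bands()].
#' @param theta_gain multiplicative theta-amplitude factor applied during the
#'   interaction condition at `theta_rois`.
#' @param theta_rois region labels receiving the theta gain.
#' @param coupling_pairs list of `list(roi_x, roi_y, lag, strength)` entries;
#'   `lag` in radians, `strength` in `[0, 1]` (1 = perfect phase locking).
#' @param snr sensor-level signal-to-noise amplitude ratio.
#' @param artifact_rate fraction of 1 s windows carrying a high-amplitude
#'   transient artifact.
#' @param artifact_amplitude artifact size, microvolts.
#' @param rs_block_s,rs_repeats resting-state block length (s) and number of
#'   eyes-open/eyes-closed repetitions.
#' @param hdc_blocks,trials_per_block,interaction_s coordination-task
#'   structure; each trial is 3 s metronome + 1 s transient + interaction +
#'   1 s transient.
#' @param theta_amp,alpha_amp,mu_amp oscillation amplitudes (source units).
#' @param alpha_closed_gain eyes-closed multiplicative alpha boost
#'   (occipital).
#' @param mu_hdc_gain multiplicative mu-amplitude factor during interaction
#'   (sensorimotor; < 1 = mu suppression).
#' @param seed master seed.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_asd = 12L, n_td = 6L,
                       sfreq = 1000,
                       n_electrodes = 128L, nodes_per_region = 8L,
                       bands = default_bands(),
                       theta_gain = 2,
                       theta_rois = c("cerebellum_L", "cerebellum_R",
                                      "frontal_L", "frontal_R"),
                       coupling_pairs = list(
                         list(roi_x = "cerebellum_R", roi_y = "frontal_L",
                              lag = 0, strength = 0.9),
                         list(roi_x = "cerebellum_L", roi_y = "sensorimotor_R",
                              lag = 0, strength = 0.9)),
                       snr = 5,
                       artifact_rate = 0.05, artifact_amplitude = 500,
                       rs_block_s = 30, rs_repeats = 3L,
                       hdc_blocks = 4L, trials_per_block = 10L,
                       interaction_s = 15,
                       theta_amp = 4, alpha_amp = 3, mu_amp = 2,
                       alpha_closed_gain = 2, mu_hdc_gain = 0.5,
                       seed = 1L) {
  check_bands(bands, sfreq)
  if (artifact_rate < 0 || artifact_rate > 1) {
    stop_invalid("artifact_rate must be in [0, 1]")
  }
  for (cp in coupling_pairs) {
    if (cp$strength < 0 || cp$strength > 1) {
      stop_invalid("coupling strength must be in [0, 1]")
    }
    bad <- setdiff(c(cp$roi_x, cp$roi_y), region_labels())
    if (length(bad)) stop_invalid("unknown coupling ROI: %s", bad[1])
  }
  if (length(bad <- setdiff(theta_rois, region_labels()))) {
    stop_invalid("unknown theta ROI: %s", bad[1])
  }
  if (n_asd < 1 || n_td < 0) stop_invalid("need at least one participant per group")
  structure(as.list(environment()), class = "sim_config")
}

#' Null (no-effect) variant of a simulation configuration
#'
#' @param config a `sim_config`.
#' @return the same configuration with theta gain 1 and no coupling pairs.
#' @export
null_config <- function(config) {
  config$theta_gain <- 1
  config$coupling_pairs <- list()
  config
}
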