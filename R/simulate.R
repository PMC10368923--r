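#' 1/f ("pink") background noise by spectral shaping
#'
#' Gaussian noise whose amplitude spectrum falls as 1/sqrt(f) (power ~ 1/f),
#' with a flat spectral floor below `floor_hz`, unit variance.
#'
#' @param n_series number of independent series (rows).
#' @param n samples per series.
#' @param sfreq sampling rate, Hz.
#' @param floor_hz spectral floor frequency, Hz.
#' @return `n_series x n` matrix.
#' @export
pink_noise <- function(n_series, n, sfreq, floor_hz = 0.5) {
  freqs <- seq(0, sfreq, length.out = n + 1)[1:n]
  freqs <- pmin(freqs, sfreq - freqs)          # two-sided axis
  amp <- 1 / sqrt(pmax(freqs, floor_hz))
  amp[1] <- 0                                  # no DC
  z <- matrix(complex(real = rnorm(n_series * n), imaginary = rnorm(n_series * n)),
              n_series, n)
  x <- Re(t(stats::mvfft(t(z) * amp, inverse = TRUE))) / n
  s <- sqrt(rowMeans(x^2))
  x / ifelse(s > 0, s, 1)
}

# smooth stationary noise: white noise low-passed below `cutoff`, unit sd
smooth_noise <- function(n_series, n, sfreq, cutoff = 1) {
  freqs <- seq(0, sfreq, length.out = n + 1)[1:n]
  freqs <- pmin(freqs, sfreq - freqs)
  keep <- as.numeric(freqs > 0 & freqs <= cutoff)
  z <- matrix(complex(real = rnorm(n_series * n), imaginary = rnorm(n_series * n)),
              n_series, n)
  x <- Re(t(stats::mvfft(t(z) * keep, inverse = TRUE))) / n
  s <- sqrt(rowMeans(x^2))
  x / ifelse(s > 0, s, 1)
}

#' Simulate labelled source-node time courses
#'
#' Every node carries a pink (1/f) background plus narrowband oscillations:
#' theta (5.5 Hz centre) at all nodes, alpha (10.5 Hz) at occipital nodes
#' (boosted when `eyes_closed`), and mu (11.5 Hz) at sensorimotor nodes
#' (suppressed during `interaction`). In the interaction condition the theta
#' amplitude at `config$theta_rois` is multiplied by `config$theta_gain`, and
#' each active coupling pair shares a common theta phase process offset by
#' the configured lag, blended with independent smooth phase noise whose
#' standard deviation is `(1 - strength) * pi` radians.
#'
#' @param head a `head_model`.
#' @param config a `sim_config`.
#' @param condition `"rest"` or `"interaction"`.
#' @param duration_s segment duration, seconds.
#' @param seed integer seed.
#' @param eyes_closed logical; eyes-closed resting-state variant.
#' @return `n_sources x n_samples` matrix (source units).
#' @export
simulate_sources <- function(head, config, condition, duration_s, seed,
                             eyes_closed = FALSE) {
  condition <- match.arg(condition, c("rest", "interaction"))
  set.seed(seed)
  fs <- config$sfreq
  n <- round(duration_s * fs)
  labs <- head$source_labels
  n_src <- length(labs)
  tt <- seq_len(n) / fs

  x <- pink_noise(n_src, n, fs)

  # centre frequencies deliberately non-commensurate with the 1 s epoch
  # grid so oscillation phase is not locked across epochs
  f_theta <- 5.37; f_alpha <- 10.23; f_mu <- 11.61
  drift <- 1.2 * smooth_noise(n_src, n, fs, cutoff = 1)

  theta_amp <- rep(config$theta_amp, n_src)
  if (condition == "interaction") {
    theta_amp[labs %in% config$theta_rois] <-
      config$theta_amp * config$theta_gain
  }

  # independent theta phase per node, overridden below for coupled pairs
  phase <- matrix(rep(2 * pi * f_theta * tt, each = n_src), n_src, n) + drift
  if (condition == "interaction" && length(config$coupling_pairs)) {
    for (cp in config$coupling_pairs) {
      base <- 2 * pi * f_theta * tt +
        1.2 * smooth_noise(1, n, fs, cutoff = 1)[1, ]
      sig <- (1 - cp$strength) * pi
      members_x <- which(labs == cp$roi_x)
      members_y <- which(labs == cp$roi_y)
      # per-node phase jitter decorrelates within an epoch (faster cutoff
      # than the shared drift) so residual imaginary cross-spectra change
      # sign across Welch segments at zero lag
      eta <- smooth_noise(length(members_x) + length(members_y), n, fs, cutoff = 4)
      for (j in seq_along(members_x)) {
        phase[members_x[j], ] <- base + sig * eta[j, ]
      }
      for (j in seq_along(members_y)) {
        phase[members_y[j], ] <- base + cp$lag +
          sig * eta[length(members_x) + j, ]
      }
    }
  }
  x <- x + theta_amp * cos(phase)

  occ <- which(labs %in% c("occipital_L", "occipital_R"))
  if (length(occ)) {
    a <- config$alpha_amp * (if (eyes_closed) config$alpha_closed_gain else 1)
    ph <- matrix(rep(2 * pi * f_alpha * tt, each = length(occ)), length(occ), n) +
      1.2 * smooth_noise(length(occ), n, fs, cutoff = 1)
    x[occ, ] <- x[occ, ] + a * cos(ph)
  }
  sm <- which(labs %in% c("sensorimotor_L", "sensorimotor_R"))
  if (length(sm)) {
    a <- config$mu_amp * (if (condition == "interaction") config$mu_hdc_gain else 1)
    ph <- matrix(rep(2 * pi * f_mu * tt, each = length(sm)), length(sm), n) +
      1.2 * smooth_noise(length(sm), n, fs, cutoff = 1)
    x[sm, ] <- x[sm, ] + a * cos(ph)
  }
  x
}

#' Event schedule of the simulated protocol
#'
#' Resting state: `rs_repeats` repetitions of an eyes-open then an
#' eyes-closed block of `rs_block_s` seconds. Coordination task: `hdc_blocks`
#' blocks of `trials_per_block` trials with in-phase/anti-phase instructions
#' alternating across blocks; each trial is 3 s metronome, 1 s transient,
#' `interaction_s` seconds of interaction (labelled with the block
#' instruction), 1 s transient. Only interaction segments carry the
#' `hdc_*` labels and are epoch-eligible downstream.
#'
#' @param config a `sim_config`.
#' @return tibble with `onset_sample`, `duration_samples`, `label`.
#' @export
make_events_schedule <- function(config) {
  fs <- config$sfreq
  rows <- list()
  cursor <- 0L
  add <- function(dur_s, label) {
    d <- as.integer(round(dur_s * fs))
    rows[[length(rows) + 1L]] <<- list(onset_sample = cursor,
                                       duration_samples = d, label = label)
    cursor <<- cursor + d
  }
  for (r in seq_len(config$rs_repeats)) {
    add(config$rs_block_s, "rs_eyes_open")
    add(config$rs_block_s, "rs_eyes_closed")
  }
  for (b in seq_len(config$hdc_blocks)) {
    lab <- if (b %% 2 == 1) "hdc_inphase" else "hdc_antiphase"
    for (tr in seq_len(config$trials_per_block)) {
      add(3, "metronome")
      add(1, "transient")
      add(config$interaction_s, lab)
      add(1, "transient")
    }
  }
  tibble::as_tibble(do.call(rbind, lapply(rows, as.data.frame)))
}

#' Project source activity to the sensors and add noise and artifacts
#'
#' Sensor data = leadfield x sources + white sensor noise scaled so that the
#' signal/noise RMS amplitude ratio equals `config$snr`. With probability
#' `config$artifact_rate` each 1 s window receives, on 1-3 random channels, a
#' high-amplitude transient pulse of `config$artifact_amplitude` microvolts;
#' injected windows are recorded in the `artifacts` table for ground-truth
#' recovery tests.
#'
#' @param head a `head_model`.
#' @param sources `n_sources x n_samples` matrix.
#' @param config a `sim_config`.
#' @param seed integer seed (noise + artifact placement).
#' @param events event table; defaults to [make_events_schedule()] of
#'   `config`, whose total extent must not exceed the source duration.
#' @param participant_id,group bookkeeping labels.
#' @return an `eeg_recording`: `data` (channels x time, microvolts), `sfreq`,
#'   `events`, `participant_id`, `group`, `artifacts`.
#' @export
make_recording <- function(head, sources, config, seed, events = NULL,
                           participant_id = "sim01", group = "ASD-like") {
  if (nrow(sources) != ncol(head$leadfield)) {
    stop_invalid("sources rows (%d) must match leadfield columns (%d)",
                 nrow(sources), ncol(head$leadfield))
  }
  set.seed(seed)
  if (is.null(events)) events <- make_events_schedule(config)
  n <- ncol(sources)
  if (max(events$onset_sample + events$duration_samples) > n) {
    stop_invalid("event schedule extends beyond the source data")
  }
  data <- head$leadfield %*% sources
  rms <- sqrt(mean(data^2))
  data <- data + matrix(rnorm(length(data), sd = rms / config$snr),
                        nrow(data), ncol(data))

  fs <- config$sfreq
  win <- as.integer(round(fs))            # epoch-length (1 s) windows
  n_win <- n %/% win
  art <- list()
  if (config$artifact_rate > 0 && n_win > 0) {
    hit <- runif(n_win) < config$artifact_rate
    pulse_len <- max(8L, as.integer(round(0.2 * fs)))
    pulse <- config$artifact_amplitude * sin(pi * seq_len(pulse_len) / (pulse_len + 1))
    for (w in which(hit)) {
      chans <- sample.int(nrow(data), sample(1:3, 1))
      offset <- sample.int(win - pulse_len, 1)
      idx <- (w - 1L) * win + offset + seq_len(pulse_len)
      sgn <- sample(c(-1, 1), 1)
      for (ch in chans) data[ch, idx] <- data[ch, idx] + sgn * pulse
      art[[length(art) + 1L]] <- list(window_start = (w - 1L) * win,
                                      window_samples = win,
                                      channels = paste(chans, collapse = ";"))
    }
  }
  artifacts <- if (length(art)) {
    tibble::as_tibble(do.call(rbind, lapply(art, as.data.frame)))
  } else {
    tibble::tibble(window_start = integer(0), window_samples = integer(0),
                   channels = character(0))
  }
  structure(list(data = data, sfreq = fs, events = events,
                 participant_id = participant_id, group = group,
                 artifacts = artifacts),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d ch x %d samples @ %g Hz, %d events\n",
              x$participant_id, x$group, nrow(x$data), ncol(x$data), x$sfreq,
              nrow(x$events)))
  invisible(x)
}

#' Simulate one participant's full protocol recording
#'
#' Builds the event schedule, simulates each segment's sources with the
#' condition-appropriate effects (control-like participants receive the null
#' configuration: no theta gain, no coupling), concatenates them and projects
#' to the sensors.
#'
#' @param head a `head_model`.
#' @param config a `sim_config`.
#' @param participant_id label.
#' @param group `"ASD-like"` (receives the configured effects) or
#'   `"TD-like"` (null effects).
#' @param seed integer seed.
#' @return an `eeg_recording`.
#' @export
simulate_participant <- function(head, config, participant_id, group, seed) {
  eff <- if (group == "TD-like") null_config(config) else config
  events <- make_events_schedule(config)
  segs <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    lab <- events$label[i]
    condition <- if (lab %in% c("hdc_inphase", "hdc_antiphase")) "interaction" else "rest"
    segs[[i]] <- simulate_sources(
      head, eff, condition,
      duration_s = events$duration_samples[i] / config$sfreq,
      seed = derive_seed(seed, i),
      eyes_closed = identical(lab, "rs_eyes_closed"))
  }
  sources <- do.call(cbind, segs)
  make_recording(head, sources, eff, seed = derive_seed(seed, 0L),
                 events = events, participant_id = participant_id,
                 group = group)
}

#' Generate a cohort of synthetic recordings with a ground-truth manifest
#'
#' Affected-like participants receive the configured theta gain and coupling;
#' control-like participants receive null effects. Per-participant seeds are
#' derived deterministically from the master seed, so an identical
#' configuration reproduces an identical cohort.
#'
#' @param config a `sim_config`.
#' @param head optional pre-built `head_model` (built from `config` sizes
#'   otherwise).
#' @return list with `head`, `recordings` (list of `eeg_recording`) and
#'   `manifest` (tibble: participant, group, seed, injected effects).
#' @export
generate_cohort <- function(config, head = NULL) {
  if (is.null(head)) {
    head <- build_head_model(config$n_electrodes, config$nodes_per_region,
                             seed = derive_seed(config$seed, 999L))
  }
  groups <- c(rep("ASD-like", config$n_asd), rep("TD-like", config$n_td))
  ids <- sprintf("sub-%02d", seq_along(groups))
  recs <- vector("list", length(ids))
  man <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sd_i <- derive_seed(config$seed, i)
    recs[[i]] <- simulate_participant(head, config, ids[i], groups[i], sd_i)
    eff <- if (groups[i] == "TD-like") null_config(config) else config
    injected <- character(0)
    if (eff$theta_gain != 1) {
      injected <- c(injected, sprintf("theta_gain=%g@%s", eff$theta_gain,
                                      paste(eff$theta_rois, collapse = "+")))
    }
    for (cp in eff$coupling_pairs) {
      injected <- c(injected, sprintf("coupling:%s~%s(lag=%g,strength=%g)",
                                      cp$roi_x, cp$roi_y, cp$lag, cp$strength))
    }
    man[[i]] <- tibble::tibble(
      participant_id = ids[i], group = groups[i], seed = sd_i,
      n_artifact_windows = nrow(recs[[i]]$artifacts),
      injected_effects = paste(injected, collapse = "|"))
  }
  list(head = head, recordings = recs, manifest = do.call(rbind, man))
}
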