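pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

#' Write a recording as EDF (16-bit) with a BIDS-style events TSV
#'
#' Minimal European Data Format writer: one data record per second, physical
#' units microvolts, per-channel physical scaling over the full 16-bit
#' digital range. Trailing samples short of a whole record are dropped. The
#' companion `*_events.tsv` has columns `onset` (s), `duration` (s),
#' `trial_type`.
#'
#' @param recording an `eeg_recording`.
#' @param path output EDF path; the events table is written next to it with
#'   the `.edf` extension replaced by `_events.tsv`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  fs <- recording$sfreq
  if (fs != round(fs)) stop_invalid("EDF writer requires an integer sampling rate")
  ns <- nrow(data)
  spr <- as.integer(fs)
  n_rec <- ncol(data) %/% spr
  if (n_rec < 1) stop_invalid("recording shorter than one 1 s data record")
  data <- data[, seq_len(n_rec * spr), drop = FALSE]

  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-6
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii(recording$participant_id, 80),
    pad_ascii(paste("group", recording$group), 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 * (ns + 1), 8),
    pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii(1, 8), pad_ascii(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    list(16, sprintf("EEG%03d", seq_len(ns))),
    list(80, rep("AgAgCl electrode", ns)),
    list(8, rep("uV", ns)),
    list(8, sprintf("%.6g", pmin_)),
    list(8, sprintf("%.6g", pmax_)),
    list(8, rep(dmin, ns)),
    list(8, rep(dmax, ns)),
    list(80, rep("", ns)),
    list(8, rep(spr, ns)),
    list(32, rep("", ns)))
  for (f in fields) {
    writeChar(paste(vapply(f[[2]], pad_ascii, "", width = f[[1]]),
                    collapse = ""), con, eos = NULL)
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * spr + seq_len(spr)
    dig <- round((data[, idx, drop = FALSE] - pmin_) / gain + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }

  ev_path <- sub("\\.edf$", "_events.tsv", path)
  ev <- recording$events
  utils::write.table(
    data.frame(onset = ev$onset_sample / fs,
               duration = ev$duration_samples / fs,
               trial_type = ev$label),
    ev_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_ascii <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

#' Read an EDF recording (and its events TSV if present)
#'
#' @param path EDF file path.
#' @return an `eeg_recording` (group/artifact fields empty unless recorded
#'   in the header strings).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                       # version
  pid <- read_ascii(con, 80)
  read_ascii(con, 80); read_ascii(con, 8); read_ascii(con, 8)
  read_ascii(con, 8)                       # header bytes
  read_ascii(con, 44)
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  grab <- function(width) vapply(seq_len(ns), function(i) read_ascii(con, width), "")
  grab(16); grab(80); grab(8)
  pmin_ <- as.numeric(grab(8)); pmax_ <- as.numeric(grab(8))
  dmin <- as.numeric(grab(8)); dmax <- as.numeric(grab(8))
  grab(80)
  spr <- as.integer(grab(8))
  grab(32)
  stopifnot(length(unique(spr)) == 1)
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw_ <- readBin(con, "integer", n = ns * spr[1], size = 2,
                    endian = "little")
    block <- matrix(raw_, nrow = spr[1])   # samples x channels
    idx <- (r - 1L) * spr[1] + seq_len(spr[1])
    data[, idx] <- t((block - rep(dmin, each = spr[1])) *
                       rep(gain, each = spr[1]) + rep(pmin_, each = spr[1]))
  }
  ev_path <- sub("\\.edf$", "_events.tsv", path)
  events <- if (file.exists(ev_path)) {
    tab <- utils::read.table(ev_path, sep = "\t", header = TRUE)
    tibble::tibble(onset_sample = as.integer(round(tab$onset * fs)),
                   duration_samples = as.integer(round(tab$duration * fs)),
                   label = tab$trial_type)
  } else {
    tibble::tibble(onset_sample = integer(0), duration_samples = integer(0),
                   label = character(0))
  }
  structure(list(data = data, sfreq = fs, events = events,
                 participant_id = pid, group = NA_character_,
                 artifacts = tibble::tibble(window_start = integer(0),
                                            window_samples = integer(0),
                                            channels = character(0))),
            class = "eeg_recording")
}
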