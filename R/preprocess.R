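#' Band-pass filter specification
#'
#' Zero-phase FIR band-pass, Hamming-window design. The filter order follows
#' the 3.3/transition-width rule; zero-phase response is obtained by applying
#' the squared magnitude response (forward-backward equivalent), which
#' doubles the stop-band attenuation and leaves no net group delay.
#'
#' @param low_cut,high_cut band edges, Hz (defaults 0.5 and 48).
#' @param trans_width transition width, Hz; default `min(max(low_cut, 0.5), 2)`.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 48, trans_width = NULL) {
  if (low_cut <= 0 || high_cut <= low_cut) {
    stop_invalid("need 0 < low_cut < high_cut")
  }
  if (is.null(trans_width)) trans_width <- min(max(low_cut, 0.5), 2)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 trans_width = trans_width), class = "filter_spec")
}

design_fir <- function(spec, sfreq) {
  nyq <- sfreq / 2
  if (spec$high_cut >= nyq) stop_invalid("high_cut must be below Nyquist")
  n_taps <- ceiling(3.3 * sfreq / spec$trans_width)
  n_taps <- n_taps + (n_taps %% 2)           # even order -> odd length
  h <- signal::fir1(n_taps, c(spec$low_cut, spec$high_cut) / nyq,
                    type = "pass", window = signal::hamming(n_taps + 1))
  as.numeric(h)
}

# zero-phase FIR by frequency-domain |H|^2 with reflection padding;
# equivalent to forward-backward application of h
fft_zerophase <- function(data, h) {
  n <- ncol(data)
  L <- length(h)
  pad <- min(n - 1L, L)
  nfft <- next_pow2(n + 2L * pad)
  H2 <- Mod(fft(c(h, rep(0, nfft - L))))^2
  out <- data
  for (i in seq_len(nrow(data))) {
    x <- data[i, ]
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    y <- Re(fft(fft(c(xp, rep(0, nfft - length(xp)))) * H2, inverse = TRUE)) / nfft
    out[i, ] <- y[pad + seq_len(n)]
  }
  out
}

#' Band-pass filter a recording
#'
#' @param recording an `eeg_recording` (or plain channels x time matrix with
#'   attribute-free use via `sfreq`).
#' @param spec a [filter_spec()].
#' @param sfreq sampling rate; taken from the recording when omitted.
#' @return the filtered recording (same class).
#' @export
bandpass <- function(recording, spec = filter_spec(), sfreq = NULL) {
  is_rec <- inherits(recording, "eeg_recording")
  data <- if (is_rec) recording$data else recording
  fs <- if (is_rec) recording$sfreq else sfreq
  if (is.null(fs)) stop_invalid("sampling rate required")
  h <- design_fir(spec, fs)
  if (ncol(data) <= 3 * length(h)) {
    stop_invalid("recording (%d samples) must be longer than 3x filter length (%d)",
                 ncol(data), length(h))
  }
  filt <- fft_zerophase(data, h)
  if (is_rec) {
    recording$data <- filt
    recording
  } else {
    filt
  }
}

#' Average-reference projection
#'
#' Removes the all-ones (common reference) component: at every sample the
#' channel mean becomes zero. Idempotent; channel differences are preserved.
#'
#' @param recording an `eeg_recording` or channels x time matrix.
#' @return re-referenced object of the same kind.
#' @export
average_reference <- function(recording) {
  is_rec <- inherits(recording, "eeg_recording")
  data <- if (is_rec) recording$data else recording
  if (nrow(data) < 2) stop_invalid("need >= 2 channels")
  data <- sweep(data, 2, colMeans(data))
  if (is_rec) {
    recording$data <- data
    recording
  } else {
    data
  }
}

#' Segment a recording into fixed-length epochs
#'
#' Tiles non-overlapping windows of `length_s` seconds inside every event
#' segment whose label is requested; partial trailing windows are dropped.
#' Each epoch inherits its segment's label as condition.
#'
#' @param recording an `eeg_recording`.
#' @param labels event labels to epoch (e.g. `"rs_eyes_open"`).
#' @param length_s epoch length in seconds (default 1).
#' @return an `eeg_epochs` object: `data` (epoch x channel x time),
#'   `sfreq`, `condition`, `onsets` (sample of epoch start), `status`,
#'   `interpolated` (per-epoch channel indices), `participant_id`.
#' @export
epoch_recording <- function(recording, labels, length_s = 1) {
  ev <- recording$events[recording$events$label %in% labels, , drop = FALSE]
  len <- as.integer(round(length_s * recording$sfreq))
  onsets <- integer(0)
  cond <- character(0)
  if (nrow(ev) == 0) {
    warning("no events match the requested labels; returning empty epochs")
  } else {
    for (i in seq_len(nrow(ev))) {
      k <- ev$duration_samples[i] %/% len
      if (k < 1) next
      onsets <- c(onsets, ev$onset_sample[i] + (seq_len(k) - 1L) * len)
      cond <- c(cond, rep(ev$label[i], k))
    }
  }
  n_ep <- length(onsets)
  n_ch <- nrow(recording$data)
  arr <- array(0, dim = c(n_ep, n_ch, len))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- recording$data[, onsets[e] + seq_len(len)]
  }
  structure(list(data = arr, sfreq = recording$sfreq, condition = cond,
                 onsets = onsets, status = rep("kept", n_ep),
                 interpolated = rep(list(integer(0)), n_ep),
                 participant_id = recording$participant_id),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d ch x %d samples @ %g Hz (%s)\n",
              d[1], d[2], d[3], x$sfreq,
              paste(sprintf("%s:%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Decimate epochs by an integer factor
#'
#' Keeps every `factor`-th sample; the data must already be low-passed below
#' the new Nyquist frequency (the 0.5-48 Hz band-pass guarantees this for
#' factor 4 at 1000 Hz).
#'
#' @param epochs an `eeg_epochs`.
#' @param factor integer decimation factor (default 4).
#' @return decimated `eeg_epochs` with `sfreq/factor`.
#' @export
decimate_epochs <- function(epochs, factor = 4L) {
  n_time <- dim(epochs$data)[3]
  if (factor < 1 || n_time %% factor != 0) {
    stop_invalid("factor must divide the epoch length (%d)", n_time)
  }
  if (factor == 1L) return(epochs)
  idx <- seq(1L, n_time, by = factor)
  epochs$data <- epochs$data[, , idx, drop = FALSE]
  epochs$sfreq <- epochs$sfreq / factor
  epochs
}

#' Subset epochs
#'
#' @param epochs an `eeg_epochs`.
#' @param idx integer or logical epoch index.
#' @return subset `eeg_epochs`.
#' @export
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$condition <- epochs$condition[idx]
  epochs$onsets <- epochs$onsets[idx]
  epochs$status <- epochs$status[idx]
  epochs$interpolated <- epochs$interpolated[idx]
  epochs
}
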