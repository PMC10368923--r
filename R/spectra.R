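welch_window <- function(n, window = c("hann", "hamming", "rect")) {
  window <- match.arg(window)
  switch(window,
         hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
         hamming = 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
         rect = rep(1, n))
}

segment_starts <- function(n_time, fft_length, overlap) {
  step <- fft_length - overlap
  seq(1L, n_time - fft_length + 1L, by = step)
}

#' Welch cross-spectral density over epoched time courses
#'
#' Per epoch, segments of `fft_length` samples starting every
#' `fft_length - overlap` samples are mean-detrended, tapered and FFT'd;
#' `S_xy(f) = X(f) conj(Y(f))` with one-sided density scaling
#' `1/(fs * sum(w^2))` (and doubling of the interior bins) so that summing
#' `S_xx` over frequencies times the bin width recovers the tapered segment
#' variance.
#'
#' @param x a `roi_timecourses` or an epoch x series x time array.
#' @param sfreq sampling rate; taken from the object when omitted.
#' @param fft_length segment/FFT length in samples (default 125).
#' @param overlap overlap between consecutive segments in samples
#'   (default 62).
#' @param window taper (default Hann).
#' @return a `cross_spectra` object: complex `S` with dimensions
#'   (epoch, segment, series, series, frequency), `freqs` (Hz), `labels`,
#'   `condition`, `fft_length`, `overlap`.
#' @export
welch_csd <- function(x, sfreq = NULL, fft_length = 125L, overlap = 62L,
                      window = "hann") {
  if (inherits(x, "roi_timecourses")) {
    arr <- x$data; fs <- x$sfreq; labels <- x$rois; condition <- x$condition
  } else {
    arr <- x; fs <- sfreq; labels <- dimnames(x)[[2]]; condition <- NULL
  }
  if (is.null(fs)) stop_invalid("sampling rate required")
  if (overlap >= fft_length) stop_invalid("overlap must be below fft_length")
  d <- dim(arr)
  if (d[3] < fft_length) stop_invalid("epoch length must be >= fft_length")
  starts <- segment_starts(d[3], fft_length, overlap)
  n_seg <- length(starts)
  n_bins <- fft_length %/% 2 + 1L
  freqs <- (seq_len(n_bins) - 1) * fs / fft_length
  w <- welch_window(fft_length, window)
  scale <- 1 / (fs * sum(w^2))
  one_sided <- rep(2, n_bins)
  one_sided[1] <- 1
  if (fft_length %% 2 == 0) one_sided[n_bins] <- 1

  s <- array(complex(real = 0), dim = c(d[1], n_seg, d[2], d[2], n_bins))
  for (e in seq_len(d[1])) {
    for (g in seq_len(n_seg)) {
      seg <- arr[e, , starts[g] + seq_len(fft_length) - 1L, drop = TRUE]
      if (is.null(dim(seg))) seg <- matrix(seg, nrow = d[2])
      seg <- (seg - rowMeans(seg)) * rep(w, each = d[2])
      xf <- stats::mvfft(t(seg))[seq_len(n_bins), , drop = FALSE]  # bins x series
      for (f in seq_len(n_bins)) {
        s[e, g, , , f] <- (scale * one_sided[f]) *
          outer(xf[f, ], Conj(xf[f, ]))
      }
    }
  }
  structure(list(S = s, freqs = freqs, labels = labels, condition = condition,
                 fft_length = fft_length, overlap = overlap, sfreq = fs),
            class = "cross_spectra")
}

#' Welch power spectral density (diagonal-only fast path)
#'
#' @inheritParams welch_csd
#' @param per_epoch if `TRUE` (default) average segments within each epoch;
#'   otherwise pool everything.
#' @return list with `psd` (epoch x series x frequency array, or series x
#'   frequency when pooled) and `freqs`.
#' @export
psd_welch <- function(x, sfreq = NULL, fft_length = 125L, overlap = 62L,
                      window = "hann", per_epoch = TRUE) {
  if (inherits(x, "roi_timecourses")) {
    arr <- x$data; fs <- x$sfreq
  } else {
    arr <- x; fs <- sfreq
  }
  if (is.null(fs)) stop_invalid("sampling rate required")
  if (overlap >= fft_length) stop_invalid("overlap must be below fft_length")
  d <- dim(arr)
  starts <- segment_starts(d[3], fft_length, overlap)
  n_bins <- fft_length %/% 2 + 1L
  freqs <- (seq_len(n_bins) - 1) * fs / fft_length
  w <- welch_window(fft_length, window)
  scale <- 1 / (fs * sum(w^2))
  one_sided <- rep(2, n_bins)
  one_sided[1] <- 1
  if (fft_length %% 2 == 0) one_sided[n_bins] <- 1
  psd <- array(0, dim = c(d[1], d[2], n_bins))
  for (e in seq_len(d[1])) {
    acc <- matrix(0, d[2], n_bins)
    for (g in seq_along(starts)) {
      seg <- arr[e, , starts[g] + seq_len(fft_length) - 1L, drop = TRUE]
      if (is.null(dim(seg))) seg <- matrix(seg, nrow = d[2])
      seg <- (seg - rowMeans(seg)) * rep(w, each = d[2])
      xf <- stats::mvfft(t(seg))[seq_len(n_bins), , drop = FALSE]
      acc <- acc + t(Mod(xf)^2 * (scale * one_sided))
    }
    psd[e, , ] <- acc / length(starts)
  }
  if (!per_epoch) psd <- apply(psd, c(2, 3), mean)
  list(psd = psd, freqs = freqs)
}

pool_csd <- function(csd, per_epoch) {
  d <- dim(csd$S)
  if (per_epoch) {
    # mean over segments within epoch -> (epoch, x, y, f)
    out <- array(complex(real = 0), dim = d[-2])
    for (e in seq_len(d[1])) {
      out[e, , , ] <- colMeans(array(csd$S[e, , , , , drop = TRUE],
                                     dim = d[2:5]), dims = 1)
    }
    out
  } else {
    # mean over epochs x segments jointly -> (x, y, f)
    colMeans(array(csd$S, dim = c(d[1] * d[2], d[3], d[4], d[5])), dims = 1)
  }
}

#' Magnitude-squared-free spectral coherence
#'
#' `coh_xy(f) = |<S_xy(f)>| / sqrt(<S_xx(f)> <S_yy(f)>)` with the average
#' taken over the pooled segment axis (epochs x segments jointly, or within
#' epoch when `per_epoch = TRUE`). Bins with zero power are set to 0 with a
#' warning.
#'
#' @param csd a [welch_csd()] result.
#' @param per_epoch return per-epoch values instead of pooling everything.
#' @return array (series, series, frequency), or (epoch, series, series,
#'   frequency) when `per_epoch`.
#' @export
coherence <- function(csd, per_epoch = FALSE) {
  sm <- pool_csd(csd, per_epoch)
  coh_from_mean <- function(m) {
    nf <- dim(m)[3]
    out <- array(0, dim = dim(m))
    warned <- FALSE
    for (f in seq_len(nf)) {
      px <- Re(diag(m[, , f]))
      denom <- sqrt(outer(px, px))
      num <- Mod(m[, , f])
      zero <- denom <= 0
      if (any(zero) && !warned) {
        warning("zero power in at least one frequency bin; coherence set to 0")
        warned <- TRUE
      }
      v <- num
      v[!zero] <- num[!zero] / denom[!zero]
      v[zero] <- 0
      out[, , f] <- v
    }
    out
  }
  if (per_epoch) {
    d <- dim(sm)
    out <- array(0, dim = d)
    for (e in seq_len(d[1])) {
      out[e, , , ] <- coh_from_mean(array(sm[e, , , , drop = TRUE], dim = d[-1]))
    }
    out
  } else {
    coh_from_mean(sm)
  }
}

#' Weighted phase lag index
#'
#' `wPLI_xy(f) = |<Im S_xy(f)>| / <|Im S_xy(f)|>` over the pooled segment
#' axis; defined as 0 when the denominator falls below `eps` (e.g. a signal
#' against itself). Insensitive to zero-lag coupling by construction.
#'
#' @param csd a [welch_csd()] result.
#' @param per_epoch return per-epoch values.
#' @param eps degenerate-denominator guard.
#' @return array like [coherence()].
#' @export
wpli <- function(csd, per_epoch = FALSE, eps = 1e-15) {
  d <- dim(csd$S)
  im <- Im(csd$S)
  if (per_epoch) {
    num <- abs(colMeans(aperm(im, c(2, 1, 3, 4, 5)), dims = 1))
    den <- colMeans(aperm(abs(im), c(2, 1, 3, 4, 5)), dims = 1)
  } else {
    flat <- array(im, dim = c(d[1] * d[2], d[3], d[4], d[5]))
    num <- abs(colMeans(flat, dims = 1))
    den <- colMeans(abs(flat), dims = 1)
  }
  out <- num
  out[den < eps] <- 0
  out[den >= eps] <- num[den >= eps] / den[den >= eps]
  out
}

#' Symmetric (Loewdin) orthogonalization of ROI time courses
#'
#' Per epoch, replaces the ROI x time matrix by the closest set of mutually
#' orthogonal time courses in the least-squares sense: the orthonormal polar
#' factor of the time x ROI matrix, rescaled to each ROI's original norm.
#' Used to remove zero-lag source-leakage correlations before recomputing
#' coherence.
#'
#' @param roi_tc a `roi_timecourses`.
#' @param rcond rank-deficiency cutoff on the singular-value ratio.
#' @return orthogonalized `roi_timecourses`.
#' @export
orthogonalize <- function(roi_tc, rcond = 1e-10) {
  d <- dim(roi_tc$data)
  if (d[3] < d[2]) stop_invalid("need at least as many time samples as ROIs")
  out <- roi_tc
  for (e in seq_len(d[1])) {
    m <- t(roi_tc$data[e, , , drop = TRUE])       # time x ROI
    sv <- svd(m)
    if (min(sv$d) < rcond * max(sv$d)) {
      stop_invalid("rank-deficient ROI time courses in epoch %d", e)
    }
    q <- sv$u %*% t(sv$v)
    norms <- sqrt(colSums(m^2))
    out$data[e, , ] <- t(q * rep(norms, each = nrow(q)))
  }
  out
}
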