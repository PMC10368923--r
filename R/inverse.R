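#' Shrinkage-regularized noise covariance
#'
#' `C = (1 - s) C_emp + s (tr(C_emp)/n) I`, with `C_emp` the empirical
#' channel covariance of the supplied resting-state epochs (channel means
#' removed). The `lowpass8Hz` variant low-passes the epochs at 8 Hz first so
#' that only low-frequency activity enters the noise model (keeps intrinsic
#' alpha out of the noise estimate).
#'
#' @param epochs resting-state (eyes-open) `eeg_epochs`.
#' @param shrinkage shrinkage coefficient `s` in `[0, 1]`.
#' @param variant `"broadband"` or `"lowpass8Hz"`.
#' @return a `noise_cov`: `matrix`, `shrinkage`, `variant`.
#' @export
estimate_noise_cov <- function(epochs, shrinkage = 0.1,
                               variant = c("broadband", "lowpass8Hz")) {
  variant <- match.arg(variant)
  if (shrinkage < 0 || shrinkage > 1) stop_invalid("shrinkage must be in [0, 1]")
  d <- dim(epochs$data)
  dat <- epochs$data
  if (variant == "lowpass8Hz") {
    nyq <- epochs$sfreq / 2
    n_taps <- ceiling(3.3 * epochs$sfreq / 4)
    n_taps <- n_taps + (n_taps %% 2)
    h <- as.numeric(signal::fir1(n_taps, 8 / nyq, type = "low",
                                 window = signal::hamming(n_taps + 1)))
    for (e in seq_len(d[1])) {
      dat[e, , ] <- fft_zerophase(dat[e, , , drop = TRUE], h)
    }
  }
  x <- matrix(aperm(dat, c(2, 3, 1)), nrow = d[2])   # channels x all samples
  if (ncol(x) < d[2]) {
    warning("fewer samples than channels; covariance estimate is rank deficient")
  }
  x <- x - rowMeans(x)
  c_emp <- tcrossprod(x) / ncol(x)
  mu <- sum(diag(c_emp)) / nrow(c_emp)
  m <- (1 - shrinkage) * c_emp + shrinkage * mu * diag(nrow(c_emp))
  structure(list(matrix = m, shrinkage = shrinkage, variant = variant),
            class = "noise_cov")
}

whiten_leadfield <- function(leadfield, noise_cov) {
  wh <- sym_pinv_sqrt(noise_cov$matrix)
  list(wh = wh, lw = wh %*% leadfield)
}

#' eLORETA inverse operator
#'
#' Exact low-resolution electromagnetic tomography with scalar (fixed
#' orientation) sources: diagonal source weights are iterated as
#' `w_i <- sqrt( l_i' (L W^-1 L' + alpha I)^+ l_i )` in the whitened sensor
#' space until the maximum relative weight change falls below `tol`; the
#' resulting operator `W^-1 L' (L W^-1 L' + alpha I)^+` has the exact
#' point-source localization property as the regularization vanishes.
#' `alpha = lambda * tr(L W^-1 L')/n_channels`.
#'
#' @param leadfield average-referenced n_channels x n_sources matrix.
#' @param noise_cov a [estimate_noise_cov()] result (identity for noiseless
#'   fixtures).
#' @param lambda relative regularization; default `1/9` (the common
#'   assumed-SNR-of-3 heuristic).
#' @param tol convergence tolerance on the relative weight change.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   change trace.
#' @return an `inverse_operator`: `method`, `K` (n_sources x n_channels,
#'   maps raw sensor data to source amplitudes), `lambda`, `n_iter`, `tol`,
#'   `converged`, `trace`.
#' @export
eloreta_weights <- function(leadfield, noise_cov, lambda = 1 / 9,
                            tol = 1e-6, max_iter = 100L) {
  wl <- whiten_leadfield(leadfield, noise_cov)
  lw <- wl$lw
  n_ch <- nrow(lw)
  n_src <- ncol(lw)
  w <- rep(1, n_src)
  trace <- numeric(0)
  minv <- NULL
  for (it in seq_len(max_iter)) {
    g <- lw %*% (t(lw) / w)
    alpha <- lambda * sum(diag(g)) / n_ch
    minv <- sym_pinv(g + alpha * diag(n_ch))
    w_new <- sqrt(pmax(colSums(lw * (minv %*% lw)), 0))
    w_new[w_new < 1e-300] <- 1e-300
    change <- max(abs(w_new - w) / pmax(w, 1e-300))
    trace <- c(trace, change)
    w <- w_new
    if (change < tol) {
      k <- (t(lw) / w) %*% minv
      return(structure(list(method = "eLORETA", K = k %*% wl$wh,
                            lambda = lambda, n_iter = it, tol = tol,
                            converged = TRUE, trace = trace,
                            weights = w),
                       class = "inverse_operator"))
    }
  }
  stop_invalid("eLORETA did not converge in %d iterations (last changes: %s)",
               max_iter, paste(signif(tail(trace, 5), 3), collapse = ", "))
}

#' Minimum-norm (Tikhonov) inverse operator
#'
#' `K = L' (L L' + alpha I)^+` in the whitened sensor space, with
#' `alpha = lambda * tr(L L')/n_channels`.
#'
#' @inheritParams eloreta_weights
#' @return an `inverse_operator`.
#' @export
mne_weights <- function(leadfield, noise_cov, lambda = 1 / 9) {
  wl <- whiten_leadfield(leadfield, noise_cov)
  lw <- wl$lw
  g <- tcrossprod(lw)
  alpha <- lambda * sum(diag(g)) / nrow(lw)
  k <- t(lw) %*% sym_pinv(g + alpha * diag(nrow(lw)))
  structure(list(method = "MNE", K = k %*% wl$wh, lambda = lambda,
                 n_iter = 0L, tol = NA_real_, converged = TRUE,
                 trace = numeric(0)),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %s: %d sources x %d channels (lambda=%g)\n",
              x$method, nrow(x$K), ncol(x$K), x$lambda))
  invisible(x)
}

#' Apply an inverse operator to sensor epochs
#'
#' @param epochs `eeg_epochs` (epoch x channel x time).
#' @param inv an `inverse_operator`.
#' @return a `source_epochs` object (epoch x source x time) carrying the
#'   epoch metadata unchanged.
#' @export
apply_inverse <- function(epochs, inv) {
  d <- dim(epochs$data)
  if (ncol(inv$K) != d[2]) {
    stop_invalid("operator expects %d channels, epochs have %d", ncol(inv$K), d[2])
  }
  out <- array(0, dim = c(d[1], nrow(inv$K), d[3]))
  for (e in seq_len(d[1])) {
    out[e, , ] <- inv$K %*% epochs$data[e, , , drop = TRUE]
  }
  res <- epochs
  res$data <- out
  class(res) <- c("source_epochs", "eeg_epochs")
  res
}

#' Analysis regions of interest
#'
#' The eight regions entering the connectivity analysis: cerebellar,
#' temporo-parietal, sensorimotor and frontal areas, both hemispheres.
#'
#' @return character vector of ROI labels.
#' @export
analysis_rois <- function() {
  c("cerebellum_L", "cerebellum_R", "TPJ_L", "TPJ_R",
    "sensorimotor_L", "sensorimotor_R", "frontal_L", "frontal_R")
}

#' Average source time courses inside regions of interest
#'
#' Arithmetic mean over member nodes per ROI and time point (no sign-flip
#' alignment; equal-and-opposite member nodes cancel, a documented
#' limitation of unsigned averaging).
#'
#' @param source_epochs a `source_epochs` object.
#' @param labels region label per source node.
#' @param rois ROI labels to extract (default [analysis_rois()]).
#' @return a `roi_timecourses` object: `data` (epoch x ROI x time), `rois`,
#'   `sfreq`, `condition`.
#' @export
extract_roi <- function(source_epochs, labels, rois = analysis_rois()) {
  d <- dim(source_epochs$data)
  if (length(labels) != d[2]) {
    stop_invalid("labels length (%d) must match source count (%d)",
                 length(labels), d[2])
  }
  out <- array(0, dim = c(d[1], length(rois), d[3]))
  for (r in seq_along(rois)) {
    members <- which(labels == rois[r])
    if (length(members) == 0) stop_invalid("ROI '%s' has no member nodes", rois[r])
    if (length(members) == 1) {
      out[, r, ] <- source_epochs$data[, members, ]
    } else {
      for (e in seq_len(d[1])) {
        out[e, r, ] <- colMeans(source_epochs$data[e, members, , drop = TRUE])
      }
    }
  }
  structure(list(data = out, rois = rois, sfreq = source_epochs$sfreq,
                 condition = source_epochs$condition),
            class = "roi_timecourses")
}
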