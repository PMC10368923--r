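#' Rejection model: per-channel peak-to-peak thresholds
#'
#' @param thresholds per-channel peak-to-peak thresholds, microvolts.
#' @param kappa consensus fraction: the largest fraction of bad channels an
#'   epoch may have and still be repaired rather than rejected.
#' @return a `rejection_model`.
#' @export
rejection_model <- function(thresholds, kappa = 0.1) {
  if (any(thresholds <= 0)) stop_invalid("thresholds must be positive")
  if (kappa < 0 || kappa > 1) stop_invalid("kappa must be in [0, 1]")
  structure(list(thresholds = thresholds, kappa = kappa),
            class = "rejection_model")
}

epoch_p2p <- function(epochs) {
  # epoch x channel matrix of peak-to-peak amplitudes
  apply(epochs$data, c(1, 2), function(v) max(v) - min(v))
}

#' Fit per-channel peak-to-peak rejection thresholds by cross-validation
#'
#' For each channel independently, candidate thresholds are scored by k-fold
#' cross-validation: epochs whose peak-to-peak amplitude exceeds the
#' candidate are dropped from the training folds, and the RMS distance
#' between the mean of the surviving training epochs and the per-sample
#' median of the held-out epochs is minimized (a grid-search variant of the
#' Autoreject objective). On zero-mean oscillatory epochs this objective has
#' a known pathology: it rewards excluding loud-but-clean epochs (it acts as
#' a variance minimizer), with a smooth, shallow error gradient toward small
#' thresholds. Selection therefore walks the candidate grid downward from
#' full retention and accepts a smaller threshold only when it yields an
#' abrupt improvement exceeding one cross-validation standard error — the
#' signature of excluding genuine artifact epochs — and otherwise stays at
#' the retention end.
#'
#' Because a single high-amplitude epoch among many barely moves a
#' cross-validated mean, the CV choice alone is insensitive to sparse
#' artifacts; each channel's threshold is therefore additionally capped by
#' a robust outlier fence, `Q3 + fence_k * IQR` of that channel's
#' peak-to-peak distribution (default `fence_k = 4`, far outside the bulk
#' of clean epochs yet well below transient artifacts, and robust to up to
#' 25% contamination).
#'
#' @param epochs an `eeg_epochs` (pooled across protocols).
#' @param n_folds folds (default 5).
#' @param candidate_grid candidate thresholds, microvolts; default: deciles
#'   of the observed peak-to-peak distribution up to 1.05 x the maximum.
#' @param kappa consensus fraction stored in the returned model.
#' @param fence_k robust-fence multiplier (see Details).
#' @return a [rejection_model()].
#' @export
fit_rejection <- function(epochs, n_folds = 5L, candidate_grid = NULL,
                          kappa = 0.1, fence_k = 4) {
  n_ep <- dim(epochs$data)[1]
  if (n_ep < 2 * n_folds) {
    stop_invalid("need at least %d epochs for %d folds", 2 * n_folds, n_folds)
  }
  p2p <- epoch_p2p(epochs)
  if (is.null(candidate_grid)) {
    # deciles for the bulk plus percentile resolution near the top, where
    # the clean/artifact boundary lives
    probs <- c(seq(0.1, 0.9, by = 0.1), seq(0.91, 1, by = 0.01))
    candidate_grid <- unique(c(quantile(p2p, probs), 1.05 * max(p2p)))
  }
  candidate_grid <- sort(candidate_grid)
  folds <- rep_len(seq_len(n_folds), n_ep)
  n_ch <- dim(epochs$data)[2]
  thr <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    mat <- epochs$data[, ch, , drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = n_ep)
    errs <- matrix(0, length(candidate_grid), n_folds)
    for (f in seq_len(n_folds)) {
      test <- folds == f
      med <- apply(mat[test, , drop = FALSE], 2, median)
      for (g in seq_along(candidate_grid)) {
        keep <- !test & p2p[, ch] <= candidate_grid[g]
        errs[g, f] <- if (!any(keep)) Inf else {
          sqrt(mean((colMeans(mat[keep, , drop = FALSE]) - med)^2))
        }
      }
    }
    mean_err <- rowMeans(errs)
    se <- apply(errs, 1, function(v) {
      if (any(!is.finite(v))) Inf else sd(v) / sqrt(n_folds)
    })
    cur <- length(candidate_grid)
    while (cur > 1 &&
           is.finite(mean_err[cur - 1]) &&
           mean_err[cur - 1] < mean_err[cur] - se[cur - 1]) {
      cur <- cur - 1
    }
    fence <- quantile(p2p[, ch], 0.75) + fence_k * stats::IQR(p2p[, ch])
    thr[ch] <- min(candidate_grid[cur], fence)
  }
  rejection_model(thr, kappa = kappa)
}

#' Apply a rejection model: repair or reject noisy epochs
#'
#' Channels whose peak-to-peak amplitude exceeds their threshold are "bad".
#' Epochs with no bad channel are kept unchanged; epochs whose bad-channel
#' fraction is at most `kappa` are repaired by replacing each bad channel
#' with the inverse-distance-weighted mean of its nearest good channels;
#' epochs above `kappa` (or with every channel bad) are rejected.
#'
#' @param epochs an `eeg_epochs`.
#' @param model a [rejection_model()].
#' @param electrode_positions n_channels x 3 matrix (for neighbour
#'   distances).
#' @param n_neighbours good channels used per repair (default 4).
#' @return `eeg_epochs` with updated `data`, `status`, `interpolated`.
#' @export
apply_rejection <- function(epochs, model, electrode_positions,
                            n_neighbours = 4L) {
  n_ch <- dim(epochs$data)[2]
  if (length(model$thresholds) != n_ch) {
    stop_invalid("model fitted on %d channels, epochs have %d",
                 length(model$thresholds), n_ch)
  }
  p2p <- epoch_p2p(epochs)
  d <- as.matrix(dist(electrode_positions))
  for (e in seq_len(dim(epochs$data)[1])) {
    bad <- which(p2p[e, ] > model$thresholds)
    if (length(bad) == 0) next
    frac <- length(bad) / n_ch
    if (frac > model$kappa || length(bad) == n_ch) {
      epochs$status[e] <- "rejected"
      next
    }
    good <- setdiff(seq_len(n_ch), bad)
    for (ch in bad) {
      nb <- good[order(d[ch, good])][seq_len(min(n_neighbours, length(good)))]
      w <- 1 / pmax(d[ch, nb], 1e-6)
      w <- w / sum(w)
      epochs$data[e, ch, ] <- drop(w %*% epochs$data[e, nb, , drop = TRUE])
    }
    epochs$status[e] <- "repaired"
    epochs$interpolated[[e]] <- bad
  }
  epochs
}
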