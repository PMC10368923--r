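#' Average spectral values over a frequency band
#'
#' Band edges are inclusive on both sides (a [3, 8] band on a 2 Hz axis uses
#' bins 4, 6 and 8).
#'
#' @param values array whose last dimension indexes frequency.
#' @param freqs frequency axis, Hz.
#' @param band two-element `c(f_lo, f_hi)`, Hz.
#' @return array with the frequency dimension averaged out.
#' @export
band_average <- function(values, freqs, band) {
  sel <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  if (length(sel) == 0) stop_invalid("no frequency bins inside [%g, %g] Hz",
                                     band[1], band[2])
  d <- dim(values)
  nd <- length(d)
  if (is.null(d) || nd == 1) return(mean(values[sel]))
  sub <- apply(values, seq_len(nd - 1), function(v) mean(v[sel]))
  sub
}

#' Z-scored condition contrast after band averaging
#'
#' `Z = (mu_A - mu_B) / sigma_B`, where `mu_A` and `mu_B` are the means over
#' epochs of the band-averaged values in conditions A (task) and B
#' (baseline), and `sigma_B` is the standard deviation over baseline epochs.
#' Applies identically to power and connectivity values.
#'
#' @param values_a,values_b arrays with epochs on the first dimension and
#'   frequency on the last (epoch x unit x freq, or epoch x unit x unit x
#'   freq for pairwise metrics).
#' @param freqs frequency axis, Hz.
#' @param band two-element band, Hz.
#' @return a `band_contrast`: `band`, `mu_a`, `mu_b`, `sigma_b`, `z` (unit
#'   vector or unit x unit matrix).
#' @export
band_zscore <- function(values_a, values_b, freqs, band) {
  if (dim(values_b)[1] < 2) stop_invalid("need >= 2 baseline epochs")
  a <- band_average(values_a, freqs, band)
  b <- band_average(values_b, freqs, band)
  if (is.null(dim(a))) { a <- matrix(a, ncol = 1); b <- matrix(b, ncol = 1) }
  da <- dim(a)
  am <- matrix(a, nrow = da[1])
  bm <- matrix(b, nrow = dim(b)[1])
  mu_a <- colMeans(am)
  mu_b <- colMeans(bm)
  sigma_b <- apply(bm, 2, sd)
  if (any(sigma_b == 0)) {
    stop_invalid("zero baseline standard deviation at unit(s): %s",
                 paste(which(sigma_b == 0), collapse = ", "))
  }
  z <- (mu_a - mu_b) / sigma_b
  shape <- if (length(da) > 2) da[-1] else da[2]
  reshape <- function(v) if (length(shape) > 1) array(v, dim = shape) else v
  structure(list(band = band, mu_a = reshape(mu_a), mu_b = reshape(mu_b),
                 sigma_b = reshape(sigma_b), z = reshape(z)),
            class = "band_contrast")
}

#' Cohen's d (pooled standard deviation, n-1 weights)
#'
#' @param a,b numeric samples (each length >= 2).
#' @return standardized mean difference `(mean(a) - mean(b)) / s_pooled`.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_invalid("both samples need size >= 2")
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}
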