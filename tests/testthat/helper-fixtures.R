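# Shared fixtures and independent oracles for the test suite.

tiny_head <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_head_model(32, 2, seed = 42)
    cache
  }
})

# small epochs object built from plain arrays
make_epochs <- function(data, sfreq, condition = NULL, onsets = NULL) {
  n_ep <- dim(data)[1]
  structure(list(
    data = data, sfreq = sfreq,
    condition = condition %||% rep("a", n_ep),
    onsets = onsets %||% seq_len(n_ep),
    status = rep("kept", n_ep),
    interpolated = rep(list(integer(0)), n_ep),
    participant_id = "test"), class = "eeg_epochs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal recording wrapper
make_recording_obj <- function(data, sfreq, events) {
  structure(list(data = data, sfreq = sfreq, events = events,
                 participant_id = "test", group = "ASD-like",
                 artifacts = tibble::tibble(window_start = integer(0),
                                            window_samples = integer(0),
                                            channels = character(0))),
            class = "eeg_recording")
}

events_tbl <- function(onset, duration, label) {
  tibble::tibble(onset_sample = as.integer(onset),
                 duration_samples = as.integer(duration), label = label)
}

# analytic signal via FFT (for phase extraction in simulation tests)
analytic_signal <- function(x) {
  n <- length(x)
  xf <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(xf * h, inverse = TRUE) / n
}

narrowband_filter <- function(x, sfreq, lo, hi) {
  n <- length(x)
  f <- seq(0, sfreq, length.out = n + 1)[1:n]
  f <- pmin(f, sfreq - f)
  keep <- as.numeric(f >= lo & f <= hi)
  Re(fft(fft(x) * keep, inverse = TRUE) / n)
}

# --- brute-force direct-DFT cross-spectral oracle -------------------------
# segments: list of (series x n) matrices; rectangular window, no scaling
# subtleties: plain DFT products averaged over segments.
oracle_cross <- function(segments) {
  n_s <- nrow(segments[[1]])
  n <- ncol(segments[[1]])
  n_bins <- n %/% 2 + 1
  acc <- array(complex(real = 0), dim = c(n_s, n_s, n_bins))
  for (seg in segments) {
    seg <- seg - rowMeans(seg)
    for (k in seq_len(n_bins)) {
      xk <- complex(real = 0, imaginary = 0)
      X <- vapply(seq_len(n_s), function(s) {
        sum(seg[s, ] * exp(-2i * pi * (k - 1) * (seq_len(n) - 1) / n))
      }, complex(1))
      for (a in seq_len(n_s)) {
        for (b in seq_len(n_s)) {
          acc[a, b, k] <- acc[a, b, k] + X[a] * Conj(X[b])
        }
      }
    }
  }
  acc / length(segments)
}

oracle_coherence <- function(segments) {
  s <- oracle_cross(segments)
  out <- array(0, dim = dim(s))
  for (k in seq_len(dim(s)[3])) {
    px <- Re(diag(s[, , k]))
    den <- sqrt(outer(px, px))
    out[, , k] <- ifelse(den > 0, Mod(s[, , k]) / den, 0)
  }
  out
}

oracle_wpli <- function(segments, eps = 1e-15) {
  n_s <- nrow(segments[[1]])
  n <- ncol(segments[[1]])
  n_bins <- n %/% 2 + 1
  num <- den <- array(0, dim = c(n_s, n_s, n_bins))
  for (seg in segments) {
    seg <- seg - rowMeans(seg)
    for (k in seq_len(n_bins)) {
      X <- vapply(seq_len(n_s), function(s) {
        sum(seg[s, ] * exp(-2i * pi * (k - 1) * (seq_len(n) - 1) / n))
      }, complex(1))
      for (a in seq_len(n_s)) {
        for (b in seq_len(n_s)) {
          im <- Im(X[a] * Conj(X[b]))
          num[a, b, k] <- num[a, b, k] + im
          den[a, b, k] <- den[a, b, k] + abs(im)
        }
      }
    }
  }
  out <- abs(num)
  out[den / length(segments) < eps] <- 0
  sel <- den / length(segments) >= eps
  out[sel] <- abs(num[sel]) / den[sel]
  out
}

# --- TFCE threshold-enumeration oracle (igraph components) ----------------
oracle_tfce_integer <- function(stat_map, adjacency, E, H) {
  g <- igraph::graph_from_adjacency_matrix(adjacency * 1, mode = "undirected")
  enhance <- function(m) {
    out <- numeric(length(m))
    if (max(m) < 1) return(out)
    for (h in seq_len(max(m))) {
      nodes <- which(m >= h)
      if (!length(nodes)) next
      sg <- igraph::induced_subgraph(g, nodes)
      comp <- igraph::components(sg)
      for (ci in seq_len(comp$no)) {
        members <- nodes[comp$membership == ci]
        out[members] <- out[members] + length(members)^E * h^H
      }
    }
    out
  }
  enhance(pmax(stat_map, 0)) - enhance(pmax(-stat_map, 0))
}

path_graph <- function(n) {
  a <- matrix(FALSE, n, n)
  if (n > 1) for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- TRUE
  a
}
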