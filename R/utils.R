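#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft qt pt sd var median rnorm runif t.test p.adjust
#'   quantile complete.cases
#' @importFrom utils head tail
NULL

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Derive a per-unit seed from a master seed
#'
#' Deterministic stream splitting for cohort members, permutation runs and
#' replicates. Keeps derived seeds inside the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param index non-negative integer offset.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(index)) %% 2147483587L + 1)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Canonical frequency bands (Hz)
#'
#' Theta 3-8 Hz, alpha 8-13 Hz, upper-alpha (mu) 10-13 Hz, broadband 0.5-48 Hz.
#'
#' @return named list of two-element numeric vectors.
#' @export
default_bands <- function() {
  list(theta = c(3, 8), alpha = c(8, 13), mu = c(10, 13), broadband = c(0.5, 48))
}

check_bands <- function(bands, sfreq) {
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] <= 0 || b[1] >= b[2] ||
        b[2] >= sfreq / 2) {
      stop_invalid("band '%s' must be ordered, positive and below Nyquist", nm)
    }
  }
  invisible(TRUE)
}

# connected components on an adjacency list, restricted to `nodes` (integer
# indices); hand-rolled BFS because this sits inside the permutation loop.
# Cross-checked against igraph::components in the test suite.
components_bfs <- function(adj_list, nodes) {
  if (length(nodes) == 0) return(list())
  inset <- logical(length(adj_list))
  inset[nodes] <- TRUE
  seen <- logical(length(adj_list))
  out <- list()
  for (v in nodes) {
    if (seen[v]) next
    comp <- integer(0)
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, u)
      nb <- adj_list[[u]]
      nb <- nb[inset[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

adjacency_to_list <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  lapply(seq_len(nrow(adjacency)), function(i) which(adjacency[i, ] != 0))
}

# symmetric pseudo-inverse via eigendecomposition, relative cutoff
sym_pinv <- function(m, rcond = 1e-12) {
  e <- eigen(m, symmetric = TRUE)
  keep <- e$values > max(abs(e$values)) * rcond
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / e$values[keep])
}

# symmetric inverse square root (pseudo) for whitening
sym_pinv_sqrt <- function(m, rcond = 1e-12) {
  e <- eigen(m, symmetric = TRUE)
  keep <- e$values > max(abs(e$values)) * rcond
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / sqrt(e$values[keep]))
}
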