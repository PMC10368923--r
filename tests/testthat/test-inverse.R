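identity_cov <- function(n) {
  structure(list(matrix = diag(n), shrinkage = 1, variant = "broadband"),
            class = "noise_cov")
}

test_that("shrinkage covariance interpolates between empirical and scaled identity", {
  set.seed(20)
  arr <- array(rnorm(30 * 6 * 50), dim = c(30, 6, 50))
  arr[, 1, ] <- arr[, 1, ] * 3          # heterogeneous variances
  ep <- make_epochs(arr, 100)
  c0 <- estimate_noise_cov(ep, shrinkage = 0)
  x <- matrix(aperm(arr, c(2, 3, 1)), nrow = 6)
  x <- x - rowMeans(x)
  expect_equal(c0$matrix, tcrossprod(x) / ncol(x), tolerance = 1e-12)
  c1 <- estimate_noise_cov(ep, shrinkage = 1)
  mu <- mean(diag(c0$matrix))
  expect_equal(c1$matrix, mu * diag(6), tolerance = 1e-12)
  for (s in c(0.1, 0.5)) {
    cs <- estimate_noise_cov(ep, shrinkage = s)
    ev <- eigen(cs$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), s * mean(diag(c0$matrix)) - 1e-10)
    expect_true(isSymmetric(cs$matrix))
  }
  expect_error(estimate_noise_cov(ep, shrinkage = 2), "shrinkage")
  expect_warning(estimate_noise_cov(make_epochs(array(rnorm(12), c(1, 6, 2)), 10)),
                 "rank")
})

test_that("the low-passed covariance variant suppresses high-frequency power", {
  set.seed(21)
  fs <- 250
  n_ep <- 12
  arr <- array(0, dim = c(n_ep, 4, fs))
  t <- seq_len(fs) / fs
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- rbind(sin(2 * pi * 20 * t + runif(1, 0, 6)),
                        sin(2 * pi * 20 * t + runif(1, 0, 6)),
                        sin(2 * pi * 4 * t + runif(1, 0, 6)),
                        sin(2 * pi * 4 * t + runif(1, 0, 6))) +
      rnorm(4 * fs, sd = 0.05)
  }
  ep <- make_epochs(arr, fs)
  cb <- estimate_noise_cov(ep, shrinkage = 0, variant = "broadband")
  cl <- estimate_noise_cov(ep, shrinkage = 0, variant = "lowpass8Hz")
  # 20 Hz channels lose most variance, 4 Hz channels keep theirs
  expect_lt(cl$matrix[1, 1] / cb$matrix[1, 1], 0.05)
  expect_gt(cl$matrix[3, 3] / cb$matrix[3, 3], 0.8)
})

test_that("eLORETA localizes every noiseless point source exactly", {
  hm <- tiny_head()
  inv <- eloreta_weights(hm$leadfield, identity_cov(32), lambda = 1e-12,
                         tol = 1e-8, max_iter = 200)
  expect_true(inv$converged)
  expect_true(all(inv$weights > 0))
  res <- inv$K %*% hm$leadfield          # resolution matrix
  hits <- vapply(seq_len(ncol(res)), function(j) which.max(abs(res[, j])), 0L)
  expect_equal(hits, seq_len(ncol(res)))
})

test_that("inverse operators are linear and fail loudly when not converged", {
  hm <- tiny_head()
  inv <- eloreta_weights(hm$leadfield, identity_cov(32), lambda = 1 / 9)
  expect_equal(drop(inv$K %*% rep(0, 32)), rep(0, ncol(hm$leadfield)))
  y <- hm$leadfield[, 5]
  expect_equal(drop(inv$K %*% (3 * y)), 3 * drop(inv$K %*% y), tolerance = 1e-12)
  expect_error(eloreta_weights(hm$leadfield, identity_cov(32), max_iter = 1L),
               "converge")
})

test_that("minimum-norm estimates vanish with infinite regularization and invert orthonormal leadfields", {
  hm <- tiny_head()
  inv_inf <- mne_weights(hm$leadfield, identity_cov(32), lambda = 1e9)
  y <- hm$leadfield[, 3]
  expect_lt(max(abs(inv_inf$K %*% y)), 1e-6 * max(abs(y)))

  # orthonormal rows: K with lambda ~ 0 is the least-squares pseudo-inverse
  set.seed(22)
  l <- qr.Q(qr(matrix(rnorm(12 * 6), 12, 6)))   # 12 x 6 orthonormal columns
  inv0 <- mne_weights(l, identity_cov(12), lambda = 1e-14)
  s_true <- rnorm(6)
  expect_equal(drop(inv0$K %*% (l %*% s_true)), s_true, tolerance = 1e-5)
})

test_that("minimum-norm localization error stays within two graph hops", {
  hm <- tiny_head()
  inv <- mne_weights(hm$leadfield, identity_cov(32), lambda = 1e-10)
  res <- inv$K %*% hm$leadfield
  hops <- vapply(seq_len(ncol(res)), function(j) {
    jj <- which.max(abs(res[, j]))
    if (jj == j) 0 else graph_hops(hm$adjacency, jj, j)
  }, 0)
  expect_true(all(is.finite(hops)))
  expect_lte(max(hops), 2)
})

test_that("localization error does not worsen as sensor noise decreases", {
  hm <- tiny_head()
  inv <- eloreta_weights(hm$leadfield, identity_cov(32), lambda = 1 / 9)
  set.seed(23)
  mean_hops <- vapply(c(1, 5, 20), function(snr) {
    errs <- vapply(seq_len(ncol(hm$leadfield)), function(j) {
      y <- hm$leadfield[, j]
      y <- y + rnorm(length(y), sd = sqrt(mean(y^2)) / snr)
      jj <- which.max(abs(inv$K %*% y))
      if (jj == j) 0 else {
        h <- graph_hops(hm$adjacency, jj, j)
        if (is.finite(h)) h else ncol(hm$leadfield)
      }
    }, 0)
    mean(errs)
  }, 0)
  expect_true(all(diff(mean_hops) <= 0.25))   # non-increasing up to noise
})

test_that("applying the inverse maps epochs linearly into source space", {
  hm <- tiny_head()
  inv <- eloreta_weights(hm$leadfield, identity_cov(32), lambda = 1 / 9)
  set.seed(24)
  arr <- array(rnorm(3 * 32 * 40), dim = c(3, 32, 40))
  arr[1, , ] <- 0
  ep <- make_epochs(arr, 100)
  src <- apply_inverse(ep, inv)
  expect_equal(dim(src$data), c(3, ncol(hm$leadfield), 40))
  expect_true(all(src$data[1, , ] == 0))
  expect_equal(src$data[2, , ] + src$data[3, , ],
               (inv$K %*% (arr[2, , ] + arr[3, , ])), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(apply_inverse(make_epochs(array(0, c(1, 5, 10)), 10), inv),
               "channels")
})

test_that("forward-projected source estimates reproduce the sensor data", {
  hm <- tiny_head()
  set.seed(25)
  cfg <- sim_config(coupling_pairs = list(), snr = 10)
  src <- simulate_sources(hm, cfg, "rest", 2, seed = 77)
  sensor <- hm$leadfield %*% src
  sensor <- sensor + rnorm(length(sensor), sd = sqrt(mean(sensor^2)) / 10)
  ep <- make_epochs(array(sensor, dim = c(1, nrow(sensor), ncol(sensor))),
                    cfg$sfreq)
  inv <- eloreta_weights(hm$leadfield, identity_cov(32), lambda = 1 / 100)
  est <- apply_inverse(ep, inv)
  refit <- hm$leadfield %*% est$data[1, , ]
  expect_gt(cor(as.vector(refit), as.vector(sensor)), 0.9)
})

test_that("ROI extraction averages member nodes and flags empty ROIs", {
  labels <- c("cerebellum_L", "cerebellum_R", "TPJ_L", "TPJ_R")
  arr <- array(rnorm(2 * 4 * 10), dim = c(2, 4, 10))
  src <- structure(list(data = arr, sfreq = 100, condition = c("a", "a")),
                   class = c("source_epochs", "eeg_epochs"))
  roi <- extract_roi(src, labels, rois = labels)
  expect_equal(roi$data, arr)                      # one node per ROI: identity
  # duplicated nodes: mean equals either; opposite nodes cancel
  labels2 <- c("cerebellum_L", "cerebellum_L", "TPJ_L", "TPJ_L")
  arr2 <- arr
  arr2[, 2, ] <- arr2[, 1, ]
  arr2[, 4, ] <- -arr2[, 3, ]
  src2 <- structure(list(data = arr2, sfreq = 100, condition = c("a", "a")),
                    class = c("source_epochs", "eeg_epochs"))
  roi2 <- extract_roi(src2, labels2, rois = c("cerebellum_L", "TPJ_L"))
  expect_equal(roi2$data[, 1, ], arr2[, 1, ], tolerance = 1e-12)
  expect_equal(max(abs(roi2$data[, 2, ])), 0)
  expect_error(extract_roi(src2, labels2, rois = c("frontal_L")), "frontal_L")
})
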