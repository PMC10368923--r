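test_that("band-pass keeps in-band tones, kills out-of-band tones and DC", {
  fs <- 250
  t <- seq_len(30 * fs) / fs
  x10 <- sin(2 * pi * 10 * t)
  x60 <- sin(2 * pi * 60 * t)
  dc <- rep(100, length(t))
  data <- rbind(x10, x60, dc, x10 + x60 + dc)
  spec <- filter_spec(0.5, 48)
  y <- bandpass(data, spec, sfreq = fs)
  trim <- (5 * fs):(25 * fs)
  amp10 <- max(abs(y[1, trim]))
  expect_true(amp10 >= 0.9 && amp10 <= 1.1)
  expect_lt(max(abs(y[2, trim])), 0.01)
  expect_lt(abs(mean(y[3, trim])), 1)
  # linearity / time invariance: response to a sum is the sum of responses
  expect_equal(y[4, trim], y[1, trim] + y[2, trim] + y[3, trim],
               tolerance = 1e-8)
  expect_error(bandpass(data, filter_spec(0.5, 200), sfreq = fs), "Nyquist")
  expect_error(bandpass(data[, 1:100], spec, sfreq = fs), "longer")
})

test_that("zero-phase filtering leaves no net group delay", {
  fs <- 250
  t <- seq_len(40 * fs) / fs
  x <- sin(2 * pi * 8 * t)
  y <- bandpass(rbind(x, x), filter_spec(2, 45), sfreq = fs)[1, ]
  trim <- (10 * fs):(30 * fs)
  # cross-correlation peak at zero lag
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    sum(x[trim] * y[trim + l])
  }, 0)
  expect_equal(lags[which.max(cc)], 0)
})

test_that("average reference zeroes the channel mean and is an idempotent projection", {
  set.seed(4)
  data <- matrix(rnorm(5 * 100), 5, 100) + 7
  r1 <- average_reference(data)
  expect_lt(max(abs(colMeans(r1))), 1e-9)
  expect_equal(average_reference(r1), r1, tolerance = 1e-12)
  expect_equal(r1[2, ] - r1[4, ], data[2, ] - data[4, ], tolerance = 1e-12)
  expect_error(average_reference(data[1, , drop = FALSE]), "channels")
})

test_that("epoching tiles labelled segments and drops partial windows", {
  fs <- 1000
  ev <- events_tbl(c(0, 30000, 61000),
                   c(30000, 20400, 5000),
                   c("rs_eyes_open", "hdc_inphase", "metronome"))
  rec <- make_recording_obj(matrix(rnorm(2 * 70000), 2), fs, ev)
  ep_rs <- epoch_recording(rec, "rs_eyes_open")
  expect_equal(dim(ep_rs$data)[1], 30)
  ep_hdc <- epoch_recording(rec, "hdc_inphase")
  expect_equal(dim(ep_hdc$data)[1], 20)     # 0.4 s dropped
  expect_warning(ep0 <- epoch_recording(rec, "rs_eyes_closed"), "no events")
  expect_equal(dim(ep0$data)[1], 0)
})

test_that("the full resting-state protocol yields 90 eyes-open epochs", {
  cfg <- sim_config()
  ev <- make_events_schedule(cfg)
  n <- sum(ev$duration_samples)
  rec <- make_recording_obj(matrix(0, 2, n), cfg$sfreq, ev)
  rec$data[] <- rnorm(length(rec$data))
  ep <- epoch_recording(rec, "rs_eyes_open")
  expect_equal(dim(ep$data)[1], 90)
})

test_that("decimation divides the rate, keeps every factor-th sample and band variance", {
  fs <- 1000
  set.seed(9)
  n_ep <- 4
  base <- vapply(seq_len(n_ep), function(i) {
    narrowband_filter(rnorm(60000), fs, 3, 8)
  }, numeric(60000))
  arr <- array(0, dim = c(n_ep, 1, 60000))
  for (i in seq_len(n_ep)) arr[i, 1, ] <- base[, i]
  ep <- make_epochs(arr, fs)
  dec <- decimate_epochs(ep, 4L)
  expect_equal(dec$sfreq, 250)
  expect_equal(dim(dec$data)[3], 15000)
  expect_equal(dec$data[1, 1, 1:5], ep$data[1, 1, seq(1, 17, by = 4)])
  v0 <- var(as.vector(ep$data))
  v1 <- var(as.vector(dec$data))
  expect_lt(abs(v1 / v0 - 1), 0.01)
  expect_identical(decimate_epochs(ep, 1L), ep)
  expect_error(decimate_epochs(ep, 7L), "divide")
  # 1000-sample epochs at 1000 Hz -> 250 samples at 250 Hz
  ep1s <- make_epochs(array(rnorm(2 * 3 * 1000), dim = c(2, 3, 1000)), 1000)
  expect_equal(dim(decimate_epochs(ep1s, 4L)$data)[3], 250)
})

test_that("clean epochs keep all data at thresholds above their amplitudes", {
  set.seed(12)
  fs <- 250
  n_ep <- 40
  arr <- array(0, dim = c(n_ep, 4, fs))
  t <- seq_len(fs) / fs
  for (e in seq_len(n_ep)) {
    amp <- runif(4, 20, 35)
    for (ch in 1:4) {
      arr[e, ch, ] <- amp[ch] * sin(2 * pi * 6 * t + runif(1, 0, 2 * pi)) +
        rnorm(fs, sd = 0.8)
    }
  }
  ep <- make_epochs(arr, fs)
  p2p <- max(apply(arr, c(1, 2), function(v) max(v) - min(v)))
  expect_lte(p2p, 80)
  m <- fit_rejection(ep, candidate_grid = seq(50, 1000, by = 50))
  expect_true(all(m$thresholds >= 80))
  out <- apply_rejection(ep, m, matrix(rnorm(12), 4, 3))
  expect_true(all(out$status == "kept"))
  expect_identical(out$data, ep$data)
})

test_that("injected artifact epochs are flagged with high sensitivity", {
  set.seed(13)
  fs <- 250
  n_ep <- 100
  n_ch <- 8
  arr <- array(rnorm(n_ep * n_ch * fs, sd = 10), dim = c(n_ep, n_ch, fs))
  bad <- sort(sample(n_ep, 20))
  for (e in bad) {
    ch <- sample(n_ch, sample(1:2, 1))
    arr[e, ch, 100:150] <- arr[e, ch, 100:150] + 500
  }
  ep <- make_epochs(arr, fs)
  m <- fit_rejection(ep)
  out <- apply_rejection(ep, m, matrix(rnorm(n_ch * 3), n_ch, 3))
  flagged <- which(out$status != "kept")
  sens <- mean(bad %in% flagged)
  spec_ <- mean(!(setdiff(seq_len(n_ep), bad) %in% flagged))
  expect_gte(sens, 0.9)
  expect_gte(spec_, 0.9)
})

test_that("threshold fitting is invariant to epoch order for exchangeable epochs", {
  set.seed(14)
  one <- array(rnorm(1 * 3 * 100), dim = c(1, 3, 100))
  arr <- one[rep(1, 20), , , drop = FALSE]
  ep <- make_epochs(arr, 100)
  m1 <- fit_rejection(ep, n_folds = 5)
  ep_shuffled <- subset_epochs(ep, sample(20))
  m2 <- fit_rejection(ep_shuffled, n_folds = 5)
  expect_identical(m1$thresholds, m2$thresholds)
})

test_that("repair-vs-reject follows the consensus fraction", {
  set.seed(15)
  fs <- 100
  n_ch <- 16
  arr <- array(rnorm(6 * n_ch * fs, sd = 5), dim = c(6, n_ch, fs))
  arr[2, 1, 40:60] <- arr[2, 1, 40:60] + 400          # 1 of 16 bad (6%)
  arr[3, 1:10, 40:60] <- arr[3, 1:10, 40:60] + 400    # 60% bad
  ep <- make_epochs(arr, fs)
  pos <- cbind(cos(seq_len(n_ch)), sin(seq_len(n_ch)), seq_len(n_ch) / n_ch)
  model <- rejection_model(rep(100, n_ch), kappa = 0.1)
  out <- apply_rejection(ep, model, pos)
  expect_equal(out$status[2], "repaired")
  expect_equal(out$interpolated[[2]], 1L)
  p2p_rep <- max(out$data[2, 1, ]) - min(out$data[2, 1, ])
  expect_lt(p2p_rep, 100)
  expect_equal(out$status[3], "rejected")
  expect_true(all(out$status[c(1, 4, 5, 6)] == "kept"))
  # model dimensioned for another montage is refused
  expect_error(apply_rejection(ep, rejection_model(rep(100, 4)), pos), "channels")
  expect_error(rejection_model(c(-1, 5)), "positive")
  expect_error(fit_rejection(make_epochs(array(0, c(4, 2, 10)), 10)), "epochs")
})
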