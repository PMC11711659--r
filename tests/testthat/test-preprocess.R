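# Filtering, differential referencing, epoch averaging, artifact rejection.

test_that("band-pass response matches its design at key frequencies", {
  fs <- 50000
  t <- seq(0, 0.2, by = 1 / fs)
  core <- seq(2000, length(t) - 2000)
  rms <- function(x) sqrt(mean(x[core]^2))
  x550 <- sin(2 * pi * 550 * t)            # near geometric mean of 100-3000
  expect_lt(abs(rms(bandpass_abr(x550, fs)) / rms(x550) - 1), 0.05)
  xdc <- rep(3, length(t))                 # DC is outside the passband
  expect_lt(max(abs(bandpass_abr(xdc, fs)[core])), 0.01 * 3)
  x10k <- sin(2 * pi * 10000 * t)          # deep stopband
  expect_lt(rms(bandpass_abr(x10k, fs)) / rms(x10k), 0.05)
})

test_that("filtering is zero-phase: pulse peak latency is unshifted", {
  fs <- 20000
  t <- seq(-0.01, 0.02, by = 1 / fs)
  x <- exp(-(t - 0.005)^2 / (2 * 0.0005^2))
  for (m in c("filtfilt", "fft")) {
    y <- bandpass_abr(x, fs, method = m)
    expect_equal(t[which.max(y)], t[which.max(x)], info = m)
  }
})

test_that("fft and filtfilt paths agree in the interior", {
  set.seed(21)
  x <- rnorm(30000)
  y1 <- bandpass_abr(x, 20000, method = "filtfilt")
  y2 <- bandpass_abr(x, 20000, method = "fft")
  core <- 2000:28000
  expect_lt(max(abs(y1[core] - y2[core])), 1e-8 * sd(y1[core]))
})

test_that("bandpass_abr rejects too-low sampling rates", {
  expect_error(bandpass_abr(rnorm(100), fs = 5000), "sampling rate")
})

test_that("differential referencing is plain subtraction", {
  v <- sin(seq(0, 10, length.out = 200))
  expect_equal(differential_abr(v, v), rep(0, 200))
  expect_equal(differential_abr(v, rep(0, 200)), v)
  expect_equal(differential_abr(v, -v), 2 * v)
  expect_error(differential_abr(v, v[-1]), "equal length")
})

test_that("epoch averaging has the right closed forms", {
  time_ms <- seq(-10, 150, by = 1)
  v <- gauss_bump(time_ms, 40, 5, 10)
  # identical epochs: mean is the epoch, sem is zero
  eps <- matrix(rep(v, 10), nrow = 10, byrow = TRUE)
  avg <- average_epochs(eps, time_ms, baseline = FALSE)
  expect_equal(avg$mean, v)
  expect_equal(avg$sem, rep(0, length(v)))
  # +v and -v: mean zero, sem = |v|
  avg2 <- average_epochs(rbind(v, -v), time_ms, baseline = FALSE)
  expect_equal(avg2$mean, rep(0, length(v)))
  expect_equal(avg2$sem, abs(v))
  # single epoch: SEM undefined and flagged
  expect_warning(avg1 <- average_epochs(matrix(v, 1), time_ms), "SEM undefined")
  expect_false(attr(avg1, "sem_valid"))
  expect_true(all(is.na(avg1$sem)))
})

test_that("baseline correction subtracts the pre-stimulus mean per epoch", {
  time_ms <- seq(-10, 20, by = 1)
  v <- gauss_bump(time_ms, 10, 3, 2)
  eps <- rbind(v + 7, v - 2)   # epoch-specific offsets
  avg <- average_epochs(eps, time_ms, baseline = TRUE)
  expect_equal(avg$mean, v - mean(v[time_ms < 0]), tolerance = 1e-12)
  expect_equal(max(avg$sem), 0, tolerance = 1e-12)
})

test_that("averaging is invariant to epoch order", {
  set.seed(31)
  eps <- matrix(rnorm(50 * 30), nrow = 50)
  t_ms <- seq(-5, 24, by = 1)
  a1 <- average_epochs(eps, t_ms)
  a2 <- average_epochs(eps[sample(50), ], t_ms)
  expect_equal(a1$mean, a2$mean)
  expect_equal(a1$sem, a2$sem)
})

test_that("SEM scales as 1/sqrt(n) and matches noise_sd/sqrt(n)", {
  set.seed(41)
  sd0 <- 2.5
  t_ms <- seq(-10, 40, by = 1)
  sems <- vapply(c(100, 400, 1600), function(n) {
    eps <- matrix(rnorm(n * length(t_ms), 0, sd0), nrow = n)
    median(average_epochs(eps, t_ms, baseline = FALSE)$sem)
  }, numeric(1))
  expect_equal(sems, sd0 / sqrt(c(100, 400, 1600)), tolerance = 0.1)
  expect_equal(sems[1] / sems[2], 2, tolerance = 0.1)
  expect_equal(sems[2] / sems[3], 2, tolerance = 0.1)
})

test_that("filtering commutes with epoching away from edges", {
  set.seed(51)
  fs <- 20000
  p <- ear_sim_params(true_threshold = 30)
  rec <- with(list(), {
    s <- simulate_ear_session(p, "click_series", seed = 3, rep_fraction = 0.04)
    s$protocols$click_series[[13]]$abr    # 80 dB condition, 20 epochs
  })
  tr <- differential_abr(rec$channels$vertex, rec$channels$bulla)
  # filter whole trace then epoch
  a1 <- epoch_and_average(bandpass_abr(tr, fs), fs, rec$events, c(-1, 12))
  # epoch with padding margin, filter epochs, trim to the same window
  ep <- epoch_trace(tr, fs, rec$events$onset_s, c(-15, 26))
  filt <- bandpass_abr(ep$epochs, fs, method = "filtfilt")
  keep <- ep$time_ms >= -1 - 1e-9 & ep$time_ms <= 12 + 1e-9
  a2 <- average_epochs(filt[, keep], ep$time_ms[keep])
  expect_equal(a1$mean, a2$mean, tolerance = 0.02)
})

test_that("artifact rejection keeps homogeneous epochs and drops gross outliers", {
  set.seed(61)
  eps <- matrix(rnorm(40 * 100), nrow = 40)
  res <- reject_artifact_epochs(eps, k = 5)
  expect_equal(res$retained, 1:40)
  expect_equal(nrow(res$rejected), 0)
  # one epoch at 100x the median peak-to-peak is rejected, order preserved
  eps2 <- eps
  eps2[17, ] <- eps2[17, ] * 100
  res2 <- reject_artifact_epochs(eps2, k = 5)
  expect_equal(res2$rejected$index, 17)
  expect_equal(res2$retained, setdiff(1:40, 17))
  # a single epoch can never beat k * its own median for k < 1
  expect_warning(res3 <- reject_artifact_epochs(eps[1, , drop = FALSE], k = 0.5),
                 "all epochs rejected")
  expect_true(res3$all_rejected)
})

test_that("rejection lowers average error when heartbeat transients contaminate epochs", {
  set.seed(71)
  # weak evoked response so noise dominates the clean peak-to-peak range
  p <- quiet_params(aep_scale = 0.05)
  det <- render_epoch(aep_template(), p, list(level_db = 80, iti_ms = 300),
                      fs = 2000)
  t_ms <- attr(det, "time_ms")
  n <- 200
  noise_sd <- 5
  eps <- matrix(rnorm(n * length(t_ms), 0, noise_sd), nrow = n)
  eps <- sweep(eps, 2, as.numeric(det), "+")
  # 10% of epochs carry a biphasic heartbeat transient at 20x the noise SD
  bad <- sample(n, n / 10)
  for (i in bad) {
    t0 <- runif(1, 10, 130)
    eps[i, ] <- eps[i, ] + 20 * noise_sd *
      (gauss_bump(t_ms, t0, 1, 3) - gauss_bump(t_ms, t0 + 10, 1, 6))
  }
  res <- reject_artifact_epochs(eps, k = 5)
  expect_true(all(res$rejected$index %in% bad))
  expect_gt(nrow(res$rejected), 0)
  rmse <- function(m) sqrt(mean((m - as.numeric(det))^2))
  raw <- average_epochs(eps, t_ms, baseline = FALSE)
  cleaned <- average_epochs(res$epochs, t_ms, baseline = FALSE)
  expect_lt(rmse(cleaned$mean), rmse(raw$mean))
})

test_that("epoch_and_average respects condition filters and window bounds", {
  fs <- 1000
  tr <- rep(0, 5000)
  events <- data.frame(onset_s = c(0.5, 1.5, 2.5), level_db = c(70, 80, 70))
  avg <- epoch_and_average(tr, fs, events, c(-10, 100),
                           condition = list(level_db = 70))
  expect_equal(avg$n_epochs, 2)
  expect_equal(avg$condition$level_db, 70)
  expect_error(epoch_and_average(tr, fs, events, c(-10, 100),
                                 condition = list(level_db = 99)), "no events")
  expect_error(epoch_trace(tr, fs, 4.99, c(-10, 100)), "inside the recording")
})
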