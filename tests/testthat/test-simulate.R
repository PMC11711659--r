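# Simulator: deterministic rendering, protocol structure, cohort statistics.

test_that("noise-free epochs equal the deterministic scaled template", {
  p <- quiet_params(true_threshold = 40, level_gain = 0.05)
  tpl <- abr_template()
  tr <- render_epoch(tpl, p, list(level_db = 70, iti_ms = 50), fs = 20000)
  t_ms <- attr(tr, "time_ms")
  expected <- rep(0, length(t_ms))
  for (i in seq_len(nrow(tpl))) {
    expected <- expected + tpl$polarity[i] * tpl$amplitude_uv[i] *
      0.05 * 30 * exp(-(t_ms - tpl$latency_ms[i])^2 / (2 * tpl$width_ms[i]^2))
  }
  expect_equal(as.numeric(tr), expected, tolerance = 1e-12)
  # rendering twice is identical (no hidden state)
  tr2 <- render_epoch(tpl, p, list(level_db = 70, iti_ms = 50), fs = 20000)
  expect_identical(as.numeric(tr), as.numeric(tr2))
})

test_that("ABR components are identically zero at and below threshold", {
  p <- quiet_params(true_threshold = 60)
  for (lvl in c(20, 45, 60)) {
    tr <- render_epoch(abr_template(), p, list(level_db = lvl, iti_ms = 50),
                       fs = 20000)
    expect_true(all(tr == 0), info = sprintf("level %d", lvl))
  }
  tr <- render_epoch(abr_template(), p, list(level_db = 65, iti_ms = 50),
                     fs = 20000)
  expect_gt(max(abs(tr)), 0)
})

test_that("AEP adaptation follows the stated exponential ITI recovery", {
  tau <- 150
  p <- quiet_params(adaptation_tau = tau)
  peak_at <- function(iti) {
    tr <- render_epoch(aep_template(), p, list(level_db = 80, iti_ms = iti),
                       fs = 2000)
    max(tr)
  }
  # closed-form evaluation of the adaptation factor, computed independently
  expected_ratio <- (1 - exp(-200 / tau)) / (1 - exp(-450 / tau))
  expect_equal(peak_at(200) / peak_at(450), expected_ratio, tolerance = 1e-10)
})

test_that("render_epoch rejects invalid stimuli", {
  p <- quiet_params()
  expect_error(render_epoch(abr_template(), p, list(level_db = 130, iti_ms = 50),
                            fs = 20000), "level")
  expect_error(render_epoch(aep_template(), p, list(level_db = 80, iti_ms = -5),
                            fs = 2000), "interval")
  expect_error(render_epoch(abr_template(), p, list(level_db = 80, iti_ms = 50),
                            fs = 5000), "sampling rate")
})

test_that("protocols have the standard condition and repetition structure", {
  p <- quiet_params()
  s <- simulate_ear_session(p, c("click_series", "iti_series"), seed = 1)
  clicks <- s$protocols$click_series
  expect_length(clicks, 15)
  expect_equal(vapply(clicks, `[[`, numeric(1), "level_db"), seq(20, 90, by = 5))
  expect_true(all(vapply(clicks, function(cc) nrow(cc$abr$events), 1L) == 500))
  itis <- s$protocols$iti_series
  expect_length(itis, 5)
  expect_equal(vapply(itis, `[[`, numeric(1), "iti_ms"),
               c(200, 250, 300, 350, 450))
  expect_true(all(vapply(itis, function(cc) nrow(cc$aep_epochs), 1L) == 1000))
  expect_error(simulate_ear_session(p, "clicks"), "unknown protocol")
})

test_that("identical seeds give bit-identical sessions", {
  p <- ear_sim_params(heartbeat_amp = 10)
  s1 <- simulate_ear_session(p, c("click_series", "tone_80db"), seed = 11,
                             rep_fraction = 0.02)
  s2 <- simulate_ear_session(p, c("click_series", "tone_80db"), seed = 11,
                             rep_fraction = 0.02)
  expect_identical(s1, s2)
  s3 <- simulate_ear_session(p, c("click_series", "tone_80db"), seed = 12,
                             rep_fraction = 0.02)
  expect_false(identical(s1$protocols$tone_80db[[1]]$aep_epochs,
                         s3$protocols$tone_80db[[1]]$aep_epochs))
})

test_that("rendered amplitudes are monotone in level and ITI", {
  p <- quiet_params(true_threshold = 40)
  abr_peaks <- vapply(seq(20, 90, by = 10), function(lvl) {
    max(abs(render_epoch(abr_template(), p, list(level_db = lvl, iti_ms = 50),
                         fs = 20000)))
  }, numeric(1))
  expect_true(all(diff(abr_peaks) >= 0))
  aep_peaks <- vapply(c(200, 250, 300, 350, 450), function(iti) {
    max(abs(render_epoch(aep_template(), p, list(level_db = 80, iti_ms = iti),
                         fs = 2000)))
  }, numeric(1))
  expect_true(all(diff(aep_peaks) >= 0))
})

test_that("empty cohorts are handled", {
  cohort <- simulate_cohort(cohort_sim_config(n_wt = 0, n_df1 = 0, seed = 1))
  expect_length(cohort$animals, 0)
  expect_equal(nrow(true_thresholds(cohort)), 0)
})

test_that("Df1 mixture weight follows the binomial law", {
  # well-separated components so the HI fraction is directly observable
  cfg <- cohort_sim_config(
    n_wt = 0, n_df1 = 200, seed = 4,
    df1_mixture = list(p_hi = 0.6, nh = c(mean = 30, sd = 1),
                       hi = c(mean = 80, sd = 1)))
  thr <- true_thresholds(simulate_cohort(cfg))
  frac_hi <- mean(thr$true_threshold > 55)
  expect_lt(abs(frac_hi - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(thr)))
})

test_that("left/right thresholds are uncorrelated when ears are independent", {
  cfg <- cohort_sim_config(n_wt = 0, n_df1 = 500, seed = 9)
  cohort <- simulate_cohort(cfg)
  thr <- true_thresholds(cohort)
  wide <- reshape(thr[, c("animal_id", "ear", "true_threshold")],
                  idvar = "animal_id", timevar = "ear", direction = "wide")
  r <- cor(wide$true_threshold.left, wide$true_threshold.right)
  expect_lt(abs(r), 0.1)
  # shared draw when independence is off
  cfg2 <- cohort_sim_config(n_wt = 0, n_df1 = 50, seed = 9,
                            ear_independence = FALSE)
  thr2 <- true_thresholds(simulate_cohort(cfg2))
  wide2 <- reshape(thr2[, c("animal_id", "ear", "true_threshold")],
                   idvar = "animal_id", timevar = "ear", direction = "wide")
  expect_identical(wide2$true_threshold.left, wide2$true_threshold.right)
})

test_that("genotype effects are applied to Df1 ears only", {
  cfg <- cohort_sim_config(n_wt = 2, n_df1 = 2, seed = 5)
  cohort <- simulate_cohort(cfg)
  g <- vapply(cohort$animals, `[[`, character(1), "genotype")
  wt <- cohort$animals[[which(g == "WT")[1]]]$ears$left$params
  df1 <- cohort$animals[[which(g == "Df1")[1]]]$ears$left$params
  expect_equal(df1$aep_scale, wt$aep_scale + 0.3)
  expect_equal(df1$adaptation_tau, wt$adaptation_tau + 80)
  expect_equal(df1$latency_shift, wt$latency_shift + 3)
  expect_equal(df1$level_gain, wt$level_gain)  # peripheral gain untouched
})
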