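# Synthetic ABR/AEP generator.
#
# The generative model renders, for one ear, per-trial voltage traces for the
# four stimulus protocols used in the recordings this package analyses:
#   click_series  clicks 20-90 dB SPL in 5 dB steps, 500 reps, 50 ms IOI
#   tone_80db     16 kHz tones, 80 dB SPL, 1000 reps, 300 ms ITI
#   level_series  16 kHz tones at 70/80/90/100 dB SPL, 1000 reps each
#   iti_series    16 kHz tones, 80 dB SPL, ITIs 200/250/300/350/450 ms
#
# ABR morphology scales with level above threshold; AEP morphology scales with
# a saturating exponential recovery from repetition suppression in the
# inter-tone interval and a linear level-dependent cortical gain.

PROTOCOL_NAMES <- c("click_series", "tone_80db", "level_series", "iti_series")

#' Single-ear simulation parameters
#'
#' Ground-truth parameters of the generative model for one ear. Defaults are
#' chosen to mimic subdermal recordings in anesthetized mice: ABR wave-1
#' amplitudes of a few microvolts at high sensation levels, tens of microvolts
#' of single-trial cortical EEG noise, and AEP complexes of roughly 10-15 uV.
#'
#' @param true_threshold hearing threshold in dB SPL (in \[20, 90\]). ABR
#'   components are zero at and below this level and grow linearly above it.
#' @param level_gain ABR growth rate: template multiplier per dB above
#'   threshold (so wave 1 at 80 dB SPL for a 35 dB ear is
#'   `1.2 * level_gain * 45` uV).
#' @param aep_scale dimensionless multiplier on the AEP template; models
#'   cortical response magnitude independent of peripheral input.
#' @param aep_level_slope relative AEP growth per dB about the 80 dB reference
#'   level (cortical excitability; drives the level-dependent AEP slope).
#' @param adaptation_tau exponential ITI recovery constant in ms; AEP
#'   components scale by `1 - exp(-ITI/adaptation_tau)`.
#' @param latency_shift ms added to the N1 and P2 peak latencies.
#' @param noise_sd single-trial Gaussian noise SD (uV) on each ABR electrode
#'   pair (split across vertex and bulla so the differential trace has this SD).
#' @param aep_noise_sd single-trial Gaussian noise SD (uV) on the cortical
#'   electrode.
#' @param heartbeat_rate heartbeat artifact rate in Hz (>= 0).
#' @param heartbeat_amp heartbeat artifact amplitude in uV (0 disables).
#' @param abr_lat_slope ABR latency increase (ms/dB) per dB of sensation level
#'   below 60 dB; models the conventional latency decrease with level.
#' @param aep_lat_level_slope AEP latency change (ms/dB) about 80 dB SPL.
#' @param aep_lat_iti_slope AEP latency change per unit ln(ITI/300 ms).
#' @return An object of class `ear_sim_params`.
#' @export
ear_sim_params <- function(true_threshold = 35,
                           level_gain = 0.05,
                           aep_scale = 1,
                           aep_level_slope = 0.02,
                           adaptation_tau = 150,
                           latency_shift = 0,
                           noise_sd = 1.5,
                           aep_noise_sd = 20,
                           heartbeat_rate = 5,
                           heartbeat_amp = 0,
                           abr_lat_slope = 0.005,
                           aep_lat_level_slope = -0.05,
                           aep_lat_iti_slope = -1.5) {
  stop_if_not(is_number(true_threshold) && true_threshold >= 20 &&
                true_threshold <= 90, "true_threshold must lie in [20, 90]")
  stop_if_not(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(is_number(aep_noise_sd) && aep_noise_sd >= 0,
              "aep_noise_sd must be >= 0")
  stop_if_not(is_number(adaptation_tau) && adaptation_tau > 0,
              "adaptation_tau must be > 0")
  stop_if_not(is_number(heartbeat_rate) && heartbeat_rate >= 0,
              "heartbeat_rate must be >= 0")
  out <- list(true_threshold = true_threshold, level_gain = level_gain,
              aep_scale = aep_scale, aep_level_slope = aep_level_slope,
              adaptation_tau = adaptation_tau, latency_shift = latency_shift,
              noise_sd = noise_sd, aep_noise_sd = aep_noise_sd,
              heartbeat_rate = heartbeat_rate, heartbeat_amp = heartbeat_amp,
              abr_lat_slope = abr_lat_slope,
              aep_lat_level_slope = aep_lat_level_slope,
              aep_lat_iti_slope = aep_lat_iti_slope)
  class(out) <- "ear_sim_params"
  out
}

# Biphasic heartbeat transient sampled at times t_ms relative to its onset.
heartbeat_transient <- function(t_ms, amp) {
  amp * (exp(-(t_ms)^2 / (2 * 3^2)) - exp(-(t_ms - 10)^2 / (2 * 6^2)))
}

# Per-component scale factors and latencies of the generative model.
component_scales <- function(template, params, level_db, iti_ms) {
  kind <- attr(template, "kind")
  if (kind == "abr") {
    sl <- max(0, level_db - params$true_threshold)   # sensation level, dB
    scale <- rep(params$level_gain * sl, nrow(template))
    lat <- template$latency_ms + params$abr_lat_slope * max(0, 60 - sl)
  } else {
    adapt <- 1 - exp(-iti_ms / params$adaptation_tau)
    levfac <- max(0, 1 + params$aep_level_slope * (level_db - 80))
    scale <- rep(params$aep_scale * adapt * levfac, nrow(template))
    lat <- template$latency_ms +
      params$aep_lat_level_slope * (level_db - 80) +
      params$aep_lat_iti_slope * (log(iti_ms) - log(300))
    late <- template$component %in% c("N1", "P2")
    lat[late] <- lat[late] + params$latency_shift
  }
  list(scale = scale, latency_ms = lat)
}

#' Render one stimulus-locked epoch
#'
#' Evaluates the deterministic template response for one trial plus (optional)
#' Gaussian noise and heartbeat artifact. ABR components scale by
#' `level_gain * max(0, level - true_threshold)`; AEP components scale by
#' `aep_scale * (1 - exp(-ITI/adaptation_tau))` and a linear level factor.
#'
#' @param template a [wave_template()].
#' @param params an [ear_sim_params()].
#' @param stimulus list with `level_db` (dB SPL, in \[0, 120\]) and `iti_ms`
#'   (preceding interval in ms, > 0; ignored for ABR templates).
#' @param fs sampling rate in Hz (>= 10000 for ABR templates).
#' @param window_ms epoch window `c(pre, post)` in ms relative to onset.
#' @param noise add Gaussian noise? (uses the current RNG state).
#' @param heartbeat_onsets_ms optional heartbeat onset times (ms, same time
#'   base as `window_ms`); transients are added where they intersect the epoch.
#' @return Numeric vector of voltages (uV) with attribute `time_ms`.
#' @export
render_epoch <- function(template, params, stimulus, fs,
                         window_ms = NULL, noise = TRUE,
                         heartbeat_onsets_ms = NULL) {
  kind <- attr(template, "kind")
  level <- stimulus$level_db
  iti <- if (is.null(stimulus$iti_ms)) 300 else stimulus$iti_ms
  stop_if_not(is_number(level) && level >= 0 && level <= 120,
              "stimulus level must lie in [0, 120] dB SPL")
  stop_if_not(is_number(iti) && iti > 0,
              "preceding interval must be positive")
  if (is.null(window_ms)) {
    window_ms <- if (kind == "abr") c(-1, 12) else c(-10, 150)
  }
  if (kind == "abr") {
    stop_if_not(fs >= 10000, "sampling rate must be >= 10 kHz for ABR epochs")
    stop_if_not(diff(window_ms) >= 12, "ABR epochs must span >= 12 ms")
  } else {
    stop_if_not(fs >= 1000, "sampling rate must be >= 1 kHz for AEP epochs")
    stop_if_not(diff(window_ms) >= 150, "AEP epochs must span >= 150 ms")
  }
  time_ms <- seq(window_ms[1], window_ms[2], by = 1000 / fs)
  cs <- component_scales(template, params, level, iti)
  trace <- numeric(length(time_ms))
  for (i in seq_len(nrow(template))) {
    if (cs$scale[i] == 0) next
    trace <- trace + template$polarity[i] * template$amplitude_uv[i] *
      cs$scale[i] * exp(-(time_ms - cs$latency_ms[i])^2 /
                          (2 * template$width_ms[i]^2))
  }
  sd <- if (kind == "abr") params$noise_sd else params$aep_noise_sd
  if (noise && sd > 0) trace <- trace + stats::rnorm(length(trace), 0, sd)
  if (!is.null(heartbeat_onsets_ms) && params$heartbeat_amp > 0) {
    for (t0 in heartbeat_onsets_ms) {
      trace <- trace + heartbeat_transient(time_ms - t0, params$heartbeat_amp)
    }
  }
  attr(trace, "time_ms") <- time_ms
  trace
}

#' A continuous multi-channel recording
#'
#' @param channels named list of equal-length numeric traces (uV).
#' @param fs sampling rate in Hz.
#' @param events data frame with at least `onset_s` (strictly increasing) and
#'   per-event stimulus attributes (`level_db`, `iti_ms`, `kind`).
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(channels, fs, events) {
  stop_if_not(is.list(channels) && length(channels) >= 1 &&
                !is.null(names(channels)), "channels must be a named list")
  len <- unique(vapply(channels, length, 1L))
  stop_if_not(length(len) == 1L, "all channels must have equal length")
  stop_if_not(all(diff(events$onset_s) > 0), "events must be strictly increasing")
  out <- list(channels = channels, fs = fs, events = events,
              n_samples = len)
  class(out) <- "continuous_recording"
  out
}

# Render the ABR part of one condition as a continuous two-channel
# (vertex, bulla) recording: deterministic template response tiled at each
# onset plus independent channel noise and an (optional) ongoing periodic
# heartbeat on the vertex channel.
render_abr_condition <- function(params, level_db, ioi_ms, n_reps,
                                 fs = 20000, template = abr_template()) {
  lead_ms <- 25
  n_total <- round((lead_ms + n_reps * ioi_ms + 25) * fs / 1000)
  onsets_s <- (lead_ms + (seq_len(n_reps) - 1) * ioi_ms) / 1000
  det <- render_epoch(template, params,
                      list(level_db = level_db, iti_ms = ioi_ms),
                      fs = fs, window_ms = c(0, 12), noise = FALSE)
  sd_ch <- params$noise_sd / sqrt(2)   # differential noise SD = noise_sd
  vertex <- stats::rnorm(n_total, 0, sd_ch)
  bulla <- stats::rnorm(n_total, 0, sd_ch)
  if (any(det != 0)) {
    idx0 <- round(onsets_s * fs)
    for (i0 in idx0) {
      span <- i0 + seq_along(det)
      vertex[span] <- vertex[span] + det
    }
  }
  if (params$heartbeat_amp > 0 && params$heartbeat_rate > 0) {
    phase_ms <- stats::runif(1, 0, 1000 / params$heartbeat_rate)
    beats_ms <- seq(phase_ms, n_total / fs * 1000, by = 1000 / params$heartbeat_rate)
    t_ms <- seq_len(n_total) / fs * 1000
    for (b in beats_ms) {
      span <- which(t_ms >= b - 20 & t_ms <= b + 40)
      vertex[span] <- vertex[span] +
        heartbeat_transient(t_ms[span] - b, params$heartbeat_amp)
    }
  }
  continuous_recording(
    channels = list(vertex = vertex, bulla = bulla), fs = fs,
    events = data.frame(onset_s = onsets_s, level_db = level_db,
                        iti_ms = ioi_ms, kind = "click"))
}

# Render the AEP part of one condition as an epochs x samples matrix on the
# cortical channel (2 kHz, -10..150 ms window).
render_aep_condition <- function(params, level_db, iti_ms, n_reps,
                                 fs = 2000, template = aep_template()) {
  det <- render_epoch(template, params,
                      list(level_db = level_db, iti_ms = iti_ms),
                      fs = fs, window_ms = c(-10, 150), noise = FALSE)
  time_ms <- attr(det, "time_ms")
  ns <- length(time_ms)
  epochs <- matrix(stats::rnorm(n_reps * ns, 0, params$aep_noise_sd),
                   nrow = n_reps, ncol = ns, byrow = TRUE)
  epochs <- sweep(epochs, 2, as.numeric(det), "+")
  if (params$heartbeat_amp > 0 && params$heartbeat_rate > 0) {
    period_ms <- 1000 / params$heartbeat_rate
    phase_ms <- stats::runif(1, 0, period_ms)
    onset_ms <- (seq_len(n_reps) - 1) * iti_ms    # global trial onsets
    for (i in seq_len(n_reps)) {
      lo <- onset_ms[i] + time_ms[1] - 40
      hi <- onset_ms[i] + time_ms[ns] + 20
      beats <- seq(phase_ms + period_ms * floor((lo - phase_ms) / period_ms),
                   hi, by = period_ms)
      beats <- beats[beats >= lo & beats <= hi] - onset_ms[i]
      for (b in beats) {
        epochs[i, ] <- epochs[i, ] +
          heartbeat_transient(time_ms - b, params$heartbeat_amp)
      }
    }
  }
  list(epochs = epochs, time_ms = time_ms)
}

protocol_conditions <- function(protocol, rep_fraction = 1) {
  reps <- function(n) max(2L, as.integer(round(n * rep_fraction)))
  switch(protocol,
    click_series = data.frame(kind = "click", level_db = seq(20, 90, by = 5),
                              iti_ms = 50, n_reps = reps(500),
                              abr = TRUE, aep = FALSE),
    tone_80db = data.frame(kind = "tone", level_db = 80, iti_ms = 300,
                           n_reps = reps(1000), abr = TRUE, aep = TRUE),
    level_series = data.frame(kind = "tone", level_db = c(70, 80, 90, 100),
                              iti_ms = 300, n_reps = reps(1000),
                              abr = FALSE, aep = TRUE),
    iti_series = data.frame(kind = "tone", level_db = 80,
                            iti_ms = c(200, 250, 300, 350, 450),
                            n_reps = reps(1000), abr = FALSE, aep = TRUE),
    stop(sprintf("unknown protocol '%s'", protocol), call. = FALSE)
  )
}

#' Simulate all recordings for one ear
#'
#' Renders per-trial traces for every requested protocol with the standard
#' repetition counts and step sizes (clicks 20-90 dB SPL in 5 dB steps at
#' 500 reps; 16 kHz tones at 1000 reps; level series 70-100 dB SPL; ITI series
#' 200-450 ms). ABR-bearing conditions are stored as continuous vertex/bulla
#' recordings (20 kHz) with event times; AEP-bearing conditions as cortical
#' epoch matrices (2 kHz, -10..150 ms).
#'
#' @param params an [ear_sim_params()].
#' @param protocols subset of
#'   `c("click_series", "tone_80db", "level_series", "iti_series")`.
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @param rep_fraction scale factor on repetition counts (1 = protocol
#'   defaults); useful to bound runtime in simulation studies.
#' @return An object of class `ear_session`.
#' @export
simulate_ear_session <- function(params, protocols = PROTOCOL_NAMES,
                                 seed = NULL, rep_fraction = 1) {
  stop_if_not(inherits(params, "ear_sim_params"),
              "params must be an ear_sim_params object")
  bad <- setdiff(protocols, PROTOCOL_NAMES)
  stop_if_not(length(bad) == 0, "unknown protocol '%s'", paste(bad, collapse = ", "))
  with_seed(seed, {
    out <- list(params = params, seed = seed, fs_abr = 20000, fs_aep = 2000,
                protocols = list())
    for (p in protocols) {
      spec <- protocol_conditions(p, rep_fraction)
      conds <- vector("list", nrow(spec))
      for (i in seq_len(nrow(spec))) {
        row <- spec[i, ]
        cond <- list(kind = row$kind, level_db = row$level_db,
                     iti_ms = row$iti_ms, n_reps = row$n_reps)
        if (row$abr) {
          cond$abr <- render_abr_condition(params, row$level_db, row$iti_ms,
                                           row$n_reps, fs = out$fs_abr)
        }
        if (row$aep) {
          ae <- render_aep_condition(params, row$level_db, row$iti_ms,
                                     row$n_reps, fs = out$fs_aep)
          cond$aep_epochs <- ae$epochs
          cond$aep_time_ms <- ae$time_ms
        }
        conds[[i]] <- cond
      }
      out$protocols[[p]] <- conds
    }
    class(out) <- "ear_session"
    out
  })
}

#' Cohort simulation configuration
#'
#' Describes a synthetic cohort: wild-type (WT) ears draw thresholds from a
#' single Gaussian; Df1/+ ears from a two-component (normal-hearing /
#' hearing-impaired) mixture with independent ears by default. Genotype
#' effects are additive offsets applied to every Df1/+ ear's simulation
#' parameters and encode elevated cortical response scale, steeper
#' level-dependent growth, slower recovery from repetition suppression, and
#' delayed late AEP waves.
#'
#' @param n_wt,n_df1 animal counts (>= 0).
#' @param seed integer seed for threshold/metadata draws and derived
#'   per-session seeds.
#' @param wt_threshold `c(mean, sd)` of WT thresholds in dB SPL.
#' @param df1_mixture list with `p_hi` (mixture weight of the impaired
#'   component, in \[0,1\]) and `c(mean, sd)` vectors `nh` and `hi`.
#' @param genotype_effects named additive offsets for Df1/+ ears; any of
#'   `aep_scale`, `aep_level_slope`, `adaptation_tau`, `latency_shift`,
#'   `level_gain`.
#' @param ear_independence if `TRUE` left/right true thresholds are sampled
#'   independently; if `FALSE` both ears share one draw.
#' @param base_params [ear_sim_params()] defaults shared by all ears.
#' @param rep_fraction passed to [simulate_ear_session()].
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_wt = 22, n_df1 = 29, seed = 1,
                              wt_threshold = c(mean = 35.23, sd = 4.64),
                              df1_mixture = list(p_hi = 0.59,
                                                 nh = c(mean = 38, sd = 5),
                                                 hi = c(mean = 65, sd = 9)),
                              genotype_effects = list(aep_scale = 0.3,
                                                      aep_level_slope = 0.015,
                                                      adaptation_tau = 80,
                                                      latency_shift = 3),
                              ear_independence = TRUE,
                              base_params = ear_sim_params(),
                              rep_fraction = 1) {
  stop_if_not(is_number(n_wt) && n_wt >= 0, "n_wt must be >= 0")
  stop_if_not(is_number(n_df1) && n_df1 >= 0, "n_df1 must be >= 0")
  stop_if_not(is_number(df1_mixture$p_hi) && df1_mixture$p_hi >= 0 &&
                df1_mixture$p_hi <= 1, "p_hi must lie in [0, 1]")
  known <- c("aep_scale", "aep_level_slope", "adaptation_tau",
             "latency_shift", "level_gain")
  bad <- setdiff(names(genotype_effects), known)
  stop_if_not(length(bad) == 0, "unknown genotype effect '%s'",
              paste(bad, collapse = ", "))
  out <- list(n_wt = as.integer(n_wt), n_df1 = as.integer(n_df1), seed = seed,
              wt_threshold = wt_threshold, df1_mixture = df1_mixture,
              genotype_effects = genotype_effects,
              ear_independence = isTRUE(ear_independence),
              base_params = base_params, rep_fraction = rep_fraction)
  class(out) <- "cohort_sim_config"
  out
}

draw_threshold <- function(n, mean, sd) {
  # thresholds live on the 5 dB stimulus grid within the tested 20-90 range
  pmin(90, pmax(20, round_to_grid(stats::rnorm(n, mean, sd), 5)))
}

#' Simulate a cohort of animals
#'
#' Draws per-animal metadata and per-ear ground-truth parameters. Sessions are
#' not rendered here (they are large); realize them per ear with
#' [simulate_ear_session()] using the stored `session_seed`, as
#' [run_pipeline()] does.
#'
#' @param config a [cohort_sim_config()].
#' @return An object of class `sim_cohort`: list with `config` and `animals`,
#'   each animal holding `animal_id`, `genotype`, `gender`, `age_weeks` and
#'   per-ear `params` / `session_seed`.
#' @export
simulate_cohort <- function(config) {
  stop_if_not(inherits(config, "cohort_sim_config"),
              "config must be a cohort_sim_config object")
  with_seed(config$seed, {
    n_total <- config$n_wt + config$n_df1
    animals <- vector("list", n_total)
    genotypes <- c(rep("WT", config$n_wt), rep("Df1", config$n_df1))
    for (i in seq_len(n_total)) {
      g <- genotypes[i]
      thr <- if (g == "WT") {
        draw_threshold(2, config$wt_threshold[["mean"]],
                       config$wt_threshold[["sd"]])
      } else {
        hi <- stats::runif(2) < config$df1_mixture$p_hi
        comp <- function(is_hi) {
          d <- if (is_hi) config$df1_mixture$hi else config$df1_mixture$nh
          draw_threshold(1, d[["mean"]], d[["sd"]])
        }
        c(comp(hi[1]), comp(hi[2]))
      }
      if (!config$ear_independence) thr[2] <- thr[1]
      ears <- list()
      for (side in c("left", "right")) {
        p <- config$base_params
        p$true_threshold <- thr[if (side == "left") 1 else 2]
        if (g == "Df1") {
          for (nm in names(config$genotype_effects)) {
            p[[nm]] <- p[[nm]] + config$genotype_effects[[nm]]
          }
        }
        ears[[side]] <- list(
          params = p,
          session_seed = derive_seed(config$seed,
                                     2 * i + (side == "right")))
      }
      animals[[i]] <- list(
        animal_id = sprintf("%s%02d", tolower(g), i),
        genotype = g,
        gender = sample(c("F", "M"), 1),
        age_weeks = round(stats::rnorm(1, 10.2, 1.3), 1),
        ears = ears
      )
    }
    out <- list(config = config, animals = animals)
    class(out) <- "sim_cohort"
    out
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d WT + %d Df1/+ animals (seed %s)\n",
              x$config$n_wt, x$config$n_df1, format(x$config$seed)))
  thr <- true_thresholds(x)
  if (nrow(thr)) {
    cat(sprintf("  true thresholds: %d ears, %g-%g dB SPL\n",
                nrow(thr), min(thr$true_threshold), max(thr$true_threshold)))
  }
  invisible(x)
}

#' Ground-truth threshold table of a simulated cohort
#'
#' @param cohort a `sim_cohort`.
#' @return Data frame with one row per ear: `animal_id`, `genotype`, `ear`,
#'   `true_threshold`.
#' @export
true_thresholds <- function(cohort) {
  if (length(cohort$animals) == 0) {
    return(data.frame(animal_id = character(), genotype = character(),
                      ear = character(), true_threshold = numeric()))
  }
  rows <- lapply(cohort$animals, function(a) {
    data.frame(animal_id = a$animal_id, genotype = a$genotype,
               ear = c("left", "right"),
               true_threshold = c(a$ears$left$params$true_threshold,
                                  a$ears$right$params$true_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
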