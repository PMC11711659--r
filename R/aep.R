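# Cortical AEP analysis: P1/N1/P2 feature extraction, amplitude complexes,
# central auditory gain, and level-/interval-dependent slope statistics.

#' Extract P1, N1 and P2 features from an averaged AEP
#'
#' P1 is the highest deflection between 15 and 30 ms post stimulus onset, N1
#' the lowest between 25 and 60 ms, and P2 the highest between 60 and 120 ms
#' (windows inclusive at both ends; earliest sample on exact ties; no ordering
#' constraint between P1 and N1 latencies). Amplitudes are referenced to the
#' mean of the pre-stimulus baseline. The amplitude complexes
#' `p1n1 = p1_amp - n1_amp` and `n1p2 = p2_amp - n1_amp` are non-negative by
#' construction because the P1 and P2 windows overlap the N1 window.
#'
#' @param avg an [epoched_average()] covering at least 0-120 ms.
#' @param windows list of `c(from, to)` ms windows for `p1`, `n1`, `p2`.
#' @param polarity +1 (default, positive-up convention) or -1 to flip input
#'   polarity for recordings with reversed electrode convention.
#' @return An object of class `aep_features`: amplitudes (uV) and latencies
#'   (ms) of P1/N1/P2 plus the `p1n1` and `n1p2` complexes.
#' @export
extract_aep_features <- function(avg,
                                 windows = list(p1 = c(15, 30),
                                                n1 = c(25, 60),
                                                p2 = c(60, 120)),
                                 polarity = 1) {
  stop_if_not(min(avg$time_ms) <= 0 && max(avg$time_ms) >= 120,
              "epoch must cover 0-120 ms post stimulus onset")
  w <- polarity * avg$mean
  pre <- avg$time_ms < 0
  if (any(pre)) w <- w - mean(w[pre])
  pick <- function(win, find_max) {
    sel <- which(avg$time_ms >= win[1] & avg$time_ms <= win[2])
    i <- if (find_max) sel[which.max(w[sel])] else sel[which.min(w[sel])]
    list(amp = w[i], lat = avg$time_ms[i])
  }
  p1 <- pick(windows$p1, TRUE)
  n1 <- pick(windows$n1, FALSE)
  p2 <- pick(windows$p2, TRUE)
  out <- list(p1_amp = p1$amp, n1_amp = n1$amp, p2_amp = p2$amp,
              p1_lat = p1$lat, n1_lat = n1$lat, p2_lat = p2$lat,
              p1n1 = p1$amp - n1$amp, n1p2 = p2$amp - n1$amp)
  class(out) <- "aep_features"
  out
}

#' @export
print.aep_features <- function(x, ...) {
  cat(sprintf("AEP features: P1 %.2f uV @ %.1f ms; N1 %.2f uV @ %.1f ms; P2 %.2f uV @ %.1f ms\n",
              x$p1_amp, x$p1_lat, x$n1_amp, x$n1_lat, x$p2_amp, x$p2_lat))
  cat(sprintf("  complexes: P1-N1 %.2f uV, N1-P2 %.2f uV\n", x$p1n1, x$n1p2))
  invisible(x)
}

#' Central auditory gain (AEP / ABR wave-1 amplitude ratio)
#'
#' Ratio between the P1-N1 (or N1-P2) AEP amplitude complex and the ABR
#' wave-1 amplitude evoked by the same tone stimulus; quantifies central
#' amplification of peripheral auditory nerve input.
#'
#' @param features an [extract_aep_features()] result.
#' @param wave1 a [wave1_features()] result for the same stimulus condition.
#' @param floor wave-1 amplitude (uV) below which the ratio is flagged
#'   undefined (default 0.01).
#' @return List with `gain_p1n1`, `gain_n1p2` and `undefined` (logical).
#' @export
central_gain <- function(features, wave1, floor = 0.01) {
  if (!is.finite(wave1$amplitude_uv) || wave1$amplitude_uv <= floor) {
    return(list(gain_p1n1 = NA_real_, gain_n1p2 = NA_real_, undefined = TRUE))
  }
  list(gain_p1n1 = features$p1n1 / wave1$amplitude_uv,
       gain_n1p2 = features$n1p2 / wave1$amplitude_uv,
       undefined = FALSE)
}

fit_slope <- function(x, y, predictor) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stop_if_not(n >= 2 && length(unique(x)) >= 2,
              "at least 2 points with distinct predictor values are required")
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  resid <- y - (intercept + slope * x)
  residual_sd <- if (n > 2) sqrt(sum(resid^2) / (n - 2)) else NA_real_
  out <- list(slope = slope, intercept = intercept,
              residual_sd = residual_sd, n_points = n, predictor = predictor)
  class(out) <- "slope_estimate"
  out
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("Slope vs %s: %.4g (intercept %.4g, n = %d)\n",
              x$predictor, x$slope, x$intercept, x$n_points))
  invisible(x)
}

#' Level-dependent AEP slope
#'
#' Ordinary least-squares slope of an AEP feature (amplitude complex in uV,
#' or wave latency in ms) against sound level in dB SPL; quantifies central
#' auditory excitability (loudness dependence of the AEP).
#'
#' @param levels_db sound levels in dB SPL (>= 2 distinct values).
#' @param values feature values at those levels.
#' @return An object of class `slope_estimate`; `slope` is per dB.
#' @export
level_slope <- function(levels_db, values) {
  fit_slope(levels_db, values, predictor = "level_db")
}

#' Interval-dependent AEP slope
#'
#' Ordinary least-squares slope of an AEP feature against the natural
#' logarithm of the inter-tone interval (ITI, in ms). Repetition-suppression
#' recovery is expected to be exponential in ITI, so amplitude is approximately
#' linear in ln(ITI) over the sampled range. Optionally normalizes the feature
#' to its value at the 350 ms ITI before fitting, which removes overall
#' amplitude differences between recordings.
#'
#' @param iti_ms inter-tone intervals in ms (>= 2 distinct values).
#' @param values feature values at those ITIs.
#' @param normalize_to_350 divide values by the 350 ms value before fitting
#'   (requires a nonzero 350 ms condition).
#' @return An object of class `slope_estimate`; `slope` is per unit ln(ms).
#' @export
iti_slope <- function(iti_ms, values, normalize_to_350 = FALSE) {
  stop_if_not(all(iti_ms > 0), "ITIs must be positive")
  if (normalize_to_350) {
    at350 <- which(iti_ms == 350)
    stop_if_not(length(at350) == 1, "normalization requires a 350 ms condition")
    stop_if_not(is.finite(values[at350]) && values[at350] != 0,
                "the 350 ms value must be nonzero for normalization")
    values <- values / values[at350]
  }
  fit_slope(log(iti_ms), values, predictor = "ln_iti")
}
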