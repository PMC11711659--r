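# ABR-level analysis: objective hearing-threshold detection from click level
# series, hearing-impairment classification, and wave-1 feature extraction.

#' Detect the click-evoked ABR hearing threshold
#'
#' The hearing threshold is the lowest click level eliciting a characteristic
#' ABR deflection at least twice as large as the time-dependent SEM of the
#' averaged waveform, with the additional requirement that the criterion also
#' holds at every higher level (suprathreshold consistency).
#'
#' Two detection rules are provided. `"anchored"` (default) operationalizes
#' the "characteristic deflection" judgment: the candidate wave is anchored at
#' the largest deflection of the highest-level average, and lower levels are
#' probed for a same-sign deflection within a short latency window around that
#' anchor (allowing for the latency increase toward threshold). `"pointwise"`
#' accepts any sample in the full analysis window with |mean| >= 2 SEM; it is
#' more permissive and correspondingly more prone to spurious subthreshold
#' detections.
#'
#' @param level_series list of [epoched_average()] objects, one per click
#'   level, each carrying `condition$level_db` (alternatively a named list
#'   with names giving the level in dB).
#' @param analysis_window `c(from, to)` in ms post onset (default 1-6 ms,
#'   covering mouse ABR waves 1-5).
#' @param rule `"anchored"` or `"pointwise"`.
#' @param anchor_window `c(pre, post)` ms around the anchor latency searched
#'   at each level under the anchored rule.
#' @return An object of class `threshold_result` with fields `threshold`
#'   (dB SPL, or `NA` with `none_detected = TRUE`), `detected` (named logical
#'   per level), `criterion` (per-level max deflection / SEM ratio), `rule`.
#' @export
detect_threshold <- function(level_series, analysis_window = c(1, 6),
                             rule = c("anchored", "pointwise"),
                             anchor_window = c(-0.5, 1.5)) {
  rule <- match.arg(rule)
  stop_if_not(length(level_series) >= 1, "at least one level is required")
  levels_db <- vapply(seq_along(level_series), function(i) {
    lv <- level_series[[i]]$condition$level_db
    if (is.null(lv)) as.numeric(names(level_series)[i]) else as.numeric(lv)
  }, numeric(1))
  stop_if_not(!anyNA(levels_db), "could not determine the level of every average")
  ord <- order(levels_db)
  level_series <- level_series[ord]
  levels_db <- levels_db[ord]

  in_window <- function(avg, w) {
    avg$time_ms >= w[1] & avg$time_ms <= w[2] & !is.na(avg$sem) & avg$sem > 0
  }
  top <- level_series[[length(level_series)]]
  sel_top <- in_window(top, analysis_window)
  stop_if_not(any(sel_top), "analysis window contains no valid samples")

  if (rule == "anchored") {
    i_anchor <- which(sel_top)[which.max(abs(top$mean[sel_top]))]
    t_anchor <- top$time_ms[i_anchor]
    sgn <- sign(top$mean[i_anchor])
    if (sgn == 0) sgn <- 1
    probe <- c(t_anchor + anchor_window[1], t_anchor + anchor_window[2])
    probe <- c(max(probe[1], analysis_window[1]),
               min(probe[2], analysis_window[2]))
    crit_fun <- function(avg) {
      sel <- in_window(avg, probe)
      if (!any(sel)) return(0)
      max(sgn * avg$mean[sel] / avg$sem[sel])
    }
  } else {
    crit_fun <- function(avg) {
      sel <- in_window(avg, analysis_window)
      if (!any(sel)) return(0)
      max(abs(avg$mean[sel]) / avg$sem[sel])
    }
  }

  criterion <- vapply(level_series, crit_fun, numeric(1))
  detected <- criterion >= 2
  names(criterion) <- names(detected) <- as.character(levels_db)
  # lowest level such that it and all higher levels are detected
  consistent <- rev(cumprod(rev(detected))) > 0
  threshold <- if (any(consistent)) levels_db[which(consistent)[1]] else NA_real_
  out <- list(threshold = threshold, detected = detected,
              criterion = criterion, levels_db = levels_db, rule = rule,
              none_detected = is.na(threshold))
  class(out) <- "threshold_result"
  out
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$none_detected) {
    cat("ABR threshold: none detected\n")
  } else {
    cat(sprintf("ABR threshold: %g dB SPL (%s rule)\n", x$threshold, x$rule))
  }
  invisible(x)
}

#' Cutoff separating normal hearing from hearing impairment
#'
#' @param wt_mean,wt_sd mean and SD of wild-type thresholds (dB SPL).
#' @param k number of SDs above the WT mean (default 2.5).
#' @return List with the exact `cutoff` and the integer `cutoff_display`
#'   (rounded to the nearest dB, as reported).
#' @export
hi_cutoff <- function(wt_mean, wt_sd, k = 2.5) {
  stop_if_not(is_number(wt_sd) && wt_sd > 0, "wt_sd must be > 0")
  cutoff <- wt_mean + k * wt_sd
  list(cutoff = cutoff, cutoff_display = round(cutoff))
}

#' Classify ears as normal-hearing or hearing-impaired
#'
#' An ear is hearing-impaired (HI) when its threshold is strictly greater
#' than `wt_mean + k * wt_sd`; a threshold exactly at the cutoff is
#' normal-hearing (NH). Undetected thresholds (`NA`) are classified HI and
#' flagged, since no response was found even at the highest level tested.
#'
#' @param threshold numeric vector of thresholds in dB SPL (`NA` = none
#'   detected).
#' @param wt_mean,wt_sd wild-type threshold mean and SD in dB SPL.
#' @param k number of SDs above the WT mean (default 2.5).
#' @return Character vector (`"NH"`/`"HI"`) with attributes `cutoff`,
#'   `cutoff_display` and `flagged` (logical, `TRUE` where the threshold was
#'   undetected).
#' @export
classify_hearing <- function(threshold, wt_mean, wt_sd, k = 2.5) {
  cut <- hi_cutoff(wt_mean, wt_sd, k)
  cls <- ifelse(is.na(threshold) | threshold > cut$cutoff, "HI", "NH")
  attr(cls, "cutoff") <- cut$cutoff
  attr(cls, "cutoff_display") <- cut$cutoff_display
  attr(cls, "flagged") <- is.na(threshold)
  cls
}

#' ABR wave-1 amplitude and latency
#'
#' The wave-1 peak is located as the maximum of the averaged waveform inside
#' the search window (earliest sample on exact ties); its amplitude is taken
#' relative to the waveform value at stimulus onset (t = 0).
#'
#' @param avg an [epoched_average()] of the tone-evoked differential ABR.
#' @param search_window `c(from, to)` in ms (default 0.5-2.5 ms for 80 dB SPL
#'   16 kHz tones).
#' @return An object of class `wave1_features`: list with `amplitude_uv` and
#'   `latency_ms`.
#' @export
wave1_features <- function(avg, search_window = c(0.5, 2.5)) {
  stop_if_not(search_window[1] >= min(avg$time_ms) &&
                search_window[2] <= max(avg$time_ms),
              "search window must lie inside the epoch")
  sel <- which(avg$time_ms >= search_window[1] &
                 avg$time_ms <= search_window[2])
  i_pk <- sel[which.max(avg$mean[sel])]
  i0 <- which.min(abs(avg$time_ms))
  out <- list(amplitude_uv = avg$mean[i_pk] - avg$mean[i0],
              latency_ms = avg$time_ms[i_pk])
  class(out) <- "wave1_features"
  out
}

#' Summarize bilateral hearing categories of a cohort
#'
#' Counts, among animals with both ears classified, those with normal hearing
#' in both ears, unilateral impairment, and bilateral impairment.
#'
#' @param table a cohort table (see [run_pipeline()]) with columns
#'   `animal_id`, `ear`, `hi_class`.
#' @return Data frame with `category`, `n_animals`, `pct` (of both-ear-tested
#'   animals).
#' @export
bilateral_hearing_summary <- function(table) {
  split_by <- split(table$hi_class, table$animal_id)
  both <- Filter(function(x) length(x) == 2 && !anyNA(x), split_by)
  n_hi <- vapply(both, function(x) sum(x == "HI"), numeric(1))
  n <- length(both)
  data.frame(
    category = c("both_NH", "unilateral_HI", "both_HI"),
    n_animals = c(sum(n_hi == 0), sum(n_hi == 1), sum(n_hi == 2)),
    pct = if (n > 0) 100 * c(sum(n_hi == 0), sum(n_hi == 1), sum(n_hi == 2)) / n
          else rep(NA_real_, 3)
  )
}
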