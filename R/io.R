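# Plain-text serialization of averaged waveforms and cohort tables.

#' Write an averaged waveform as delimited text
#'
#' Columns `time_ms`, `mean_uv`, `sem_uv`, plus a JSON sidecar
#' (`<path>.json`) holding the stimulus condition and epoch count.
#'
#' @param avg an [epoched_average()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_average <- function(avg, path) {
  utils::write.table(
    data.frame(time_ms = avg$time_ms, mean_uv = avg$mean, sem_uv = avg$sem),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- c(avg$condition, list(n_epochs = avg$n_epochs))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an averaged waveform written by [write_average()]
#'
#' @param path TSV path.
#' @return An [epoched_average()].
#' @export
read_average <- function(path) {
  d <- utils::read.delim(path)
  cond <- list()
  sidecar <- paste0(path, ".json")
  n <- NA_integer_
  if (file.exists(sidecar)) {
    cond <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    n <- cond$n_epochs
    cond$n_epochs <- NULL
  }
  epoched_average(d$time_ms, d$mean_uv, d$sem_uv, n, cond)
}

#' Write a cohort table as CSV
#'
#' @param table cohort table data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort_table()]
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cohort_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write every condition average of an ear session
#'
#' Preprocesses each condition of the session (ABR and/or AEP) and writes one
#' TSV per averaged waveform into `dir`, named
#' `<protocol>_<level>dB_<iti>ms_<abr|aep>.tsv`.
#'
#' @param session an `ear_session`.
#' @param dir output directory (created if missing).
#' @param k artifact-rejection multiplier.
#' @return Character vector of written paths, invisibly.
#' @export
write_session_averages <- function(session, dir, k = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in names(session$protocols)) {
    for (cond in session$protocols[[p]]) {
      base <- sprintf("%s_%gdB_%gms", p, cond$level_db, cond$iti_ms)
      if (!is.null(cond$abr)) {
        f <- file.path(dir, paste0(base, "_abr.tsv"))
        write_average(preprocess_abr_condition(cond, k = k), f)
        paths <- c(paths, f)
      }
      if (!is.null(cond$aep_epochs)) {
        f <- file.path(dir, paste0(base, "_aep.tsv"))
        write_average(preprocess_aep_condition(cond, k = k), f)
        paths <- c(paths, f)
      }
    }
  }
  invisible(paths)
}
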