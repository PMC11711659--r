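# Waveform templates: the deterministic morphology used by the simulator.
#
# Each deflection is a Gaussian-windowed monophasic bump with analytically
# known peak latency and amplitude, so oracle tests can predict extractor
# output exactly.

#' Construct a waveform template
#'
#' A wave template describes the deterministic morphology of an evoked
#' potential as a sum of Gaussian bumps, one per deflection (ABR waves 1-5,
#' or cortical AEP deflections P1/N1/P2). Peak latency and amplitude of every
#' component are analytically known, which makes templates convenient ground
#' truth for testing feature extractors.
#'
#' @param component character names, e.g. `"wave1"` or `"N1"`.
#' @param polarity +1 or -1 per component.
#' @param latency_ms peak latency in ms after stimulus onset (>= 0; ABR
#'   components must peak before 10 ms, AEP components within 15-120 ms).
#' @param width_ms Gaussian SD of the bump in ms (> 0).
#' @param amplitude_uv unsigned base amplitude in microvolts (scaled at render
#'   time by the level/interval-dependent gain model).
#' @param kind `"abr"` or `"aep"`; decides which gain model applies.
#' @return An object of class `wave_template` (a data frame with one row per
#'   deflection and a `kind` attribute).
#' @export
#' @examples
#' wave_template("P1", +1, 20, 4, 6, kind = "aep")
wave_template <- function(component, polarity, latency_ms, width_ms,
                          amplitude_uv, kind = c("abr", "aep")) {
  kind <- match.arg(kind)
  n <- length(component)
  stop_if_not(length(polarity) == n && length(latency_ms) == n &&
                length(width_ms) == n && length(amplitude_uv) == n,
              "all template fields must have one entry per component")
  stop_if_not(all(polarity %in% c(-1, 1)), "polarity must be +1 or -1")
  stop_if_not(all(width_ms > 0), "component widths must be positive")
  stop_if_not(all(latency_ms >= 0), "component latencies must be >= 0")
  if (kind == "abr") {
    stop_if_not(all(latency_ms < 10), "ABR component latencies must be < 10 ms")
  } else {
    stop_if_not(all(latency_ms >= 15 & latency_ms <= 120),
                "AEP component latencies must lie within [15, 120] ms")
  }
  out <- data.frame(component = component, polarity = polarity,
                    latency_ms = latency_ms, width_ms = width_ms,
                    amplitude_uv = amplitude_uv, stringsAsFactors = FALSE)
  attr(out, "kind") <- kind
  class(out) <- c("wave_template", class(out))
  out
}

#' Default mouse ABR template (waves 1-5)
#'
#' Latencies, widths and relative amplitudes follow the conventional mouse
#' click/tone ABR morphology: five successive positive waves within the first
#' 6 ms, wave 1 being the largest and arising from the auditory nerve.
#'
#' @return A `wave_template` of kind `"abr"`.
#' @export
abr_template <- function() {
  wave_template(
    component    = c("wave1", "wave2", "wave3", "wave4", "wave5"),
    polarity     = c(1, 1, 1, 1, 1),
    latency_ms   = c(1.5, 2.5, 3.4, 4.3, 5.2),
    width_ms     = c(0.15, 0.18, 0.20, 0.22, 0.25),
    amplitude_uv = c(1.2, 0.7, 0.9, 0.5, 0.4),
    kind = "abr"
  )
}

#' Default mouse cortical AEP template (P1, N1, P2)
#'
#' P1 (thalamocortical), N1 (primary auditory cortex) and P2 (higher auditory
#' areas) at latencies inside the standard extraction windows 15-30, 25-60 and
#' 60-120 ms, positive-up polarity convention.
#'
#' @return A `wave_template` of kind `"aep"`.
#' @export
aep_template <- function() {
  wave_template(
    component    = c("P1", "N1", "P2"),
    polarity     = c(1, -1, 1),
    latency_ms   = c(20, 38, 80),
    width_ms     = c(4, 7, 14),
    amplitude_uv = c(6, 8, 4),
    kind = "aep"
  )
}
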