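#' Intensity threshold configuration
#'
#' Fixed, manually determined intensity thresholds applied to per-nucleus
#' mean marker intensities. Defaults follow the published image-analysis
#' settings for 8-bit data: nuclear YAP positivity at 75 and TLE4
#' (podocyte) positivity at 115. `tle4_bins` are two additional cut points
#' used only for the low/medium/high display classification; they never
#' enter any metric.
#'
#' @param yap_threshold nuclear-YAP positivity threshold.
#' @param tle4_threshold TLE4 (podocyte) positivity threshold.
#' @param tle4_bins strictly increasing numeric vector of 2 cut points
#'   delimiting the low/medium/high TLE4 display bins.
#' @param bit_depth maximum intensity of the data the thresholds apply to.
#' @return Object of class `ThresholdConfig`.
#' @export
threshold_config <- function(yap_threshold = 75, tle4_threshold = 115,
                             tle4_bins = c(115, 180), bit_depth = 255) {
  if (yap_threshold < 0 || yap_threshold > bit_depth ||
      tle4_threshold < 0 || tle4_threshold > bit_depth)
    stop("podoquant_bad_threshold: thresholds must lie in [0, bit_depth]")
  if (length(tle4_bins) != 2L || diff(tle4_bins) <= 0)
    stop("podoquant_bad_bins: tle4_bins must be 2 strictly increasing cut points")
  structure(list(yap_threshold = yap_threshold,
                 tle4_threshold = tle4_threshold,
                 tle4_bins = as.numeric(tle4_bins),
                 bit_depth = bit_depth),
            class = "ThresholdConfig")
}

#' Flag podocytes among segmented nuclei
#'
#' A nucleus is a podocyte iff its mean TLE4 intensity is at or above the
#' TLE4 threshold (ties count positive). No records are added or removed.
#'
#' @param nuclei nucleus-record data frame from [segment_nuclei()].
#' @param cfg a [threshold_config()].
#' @return `nuclei` with `is_podocyte` set.
#' @export
classify_podocytes <- function(nuclei, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "ThresholdConfig"))
  if (!"mean_TLE4" %in% names(nuclei))
    stop("podoquant_missing_intensity: nuclei lack mean_TLE4")
  nuclei$is_podocyte <- nuclei$mean_TLE4 >= cfg$tle4_threshold
  nuclei
}

#' Flag nuclear-YAP-positive nuclei
#'
#' Positivity is evaluated on the mean YAP intensity over the nuclear
#' mask only (the nuclear compartment); cytoplasmic YAP never enters.
#'
#' @inheritParams classify_podocytes
#' @return `nuclei` with `is_nuclear_yap_positive` set.
#' @export
classify_nuclear_yap <- function(nuclei, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "ThresholdConfig"))
  if (!"mean_YAP" %in% names(nuclei))
    stop("podoquant_missing_intensity: nuclei lack mean_YAP")
  nuclei$is_nuclear_yap_positive <- nuclei$mean_YAP >= cfg$yap_threshold
  nuclei
}

#' TLE4 expression display bin
#'
#' Maps a TLE4 mean intensity to `"low"`, `"medium"` or `"high"` using
#' the two cut points in `cfg$tle4_bins`. Values equal to a cut point
#' fall in the upper bin (same `>=` tie rule as positivity).
#'
#' @param tle4_intensity numeric vector of mean TLE4 intensities.
#' @param cfg a [threshold_config()].
#' @return Factor with levels low < medium < high.
#' @export
tle4_expression_bin <- function(tle4_intensity, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "ThresholdConfig"))
  cuts <- cfg$tle4_bins
  lev <- c("low", "medium", "high")
  idx <- 1L + (tle4_intensity >= cuts[1]) + (tle4_intensity >= cuts[2])
  factor(lev[idx], levels = lev)
}
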