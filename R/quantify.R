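#' @title Wave metrics, thresholds and dB quantities
#'
#' @description
#' Extraction of eABR wave metrics from evoked traces. Amplitude is the
#' voltage difference between a wave's positive peak and the following
#' trough; latency is the timing of the peak; threshold is the lowest
#' charge level that evokes a wave amplitude strictly above 0.1 µV.
#'
#' @name quantify
NULL

#' Default wave search windows (ms)
#'
#' Peak search windows for waves II, III and IV; unstated in the original
#' protocol, declared here and configurable in every caller.
#' @export
WAVE_WINDOWS <- list(II = c(0.7, 1.4), III = c(1.3, 1.9), IV = c(1.8, 2.6))

#' Locate a wave and measure its amplitude and latency
#'
#' The peak is the maximum sample in the search window; the trough is the
#' minimum sample within `trough_span` ms after the peak; amplitude is
#' peak minus trough. The wave is `present` when the amplitude is positive
#' and the peak is a local maximum.
#'
#' @param trace an `evoked_trace`.
#' @param wave_id `"II"`, `"III"` or `"IV"` (selects the default window).
#' @param search_window optional `c(start, end)` ms overriding the default;
#'   pass an explicit window (e.g. shifted by the second-phase onset) for
#'   monophasic long-gap analyses.
#' @param trough_span how far after the peak to search for the trough, ms.
#' @return list of class `wave_metrics` with `wave_id`, `peak_latency`,
#'   `trough_latency` (ms), `amplitude` (µV), `present`.
#' @export
find_wave <- function(trace, wave_id = "II", search_window = NULL,
                      trough_span = 0.6) {
  if (is.null(search_window)) search_window <- WAVE_WINDOWS[[wave_id]]
  t_ms <- trace_times(trace) / 1000
  win <- which(t_ms >= search_window[1] & t_ms <= search_window[2])
  if (!length(win)) stop("empty search window")
  ipk <- win[which.max(trace$samples[win])]
  peak_t <- t_ms[ipk]
  peak_v <- trace$samples[ipk]
  after <- which(t_ms > peak_t & t_ms <= peak_t + trough_span)
  if (length(after)) {
    itr <- after[which.min(trace$samples[after])]
    trough_t <- t_ms[itr]
    trough_v <- trace$samples[itr]
  } else {
    trough_t <- NA_real_
    trough_v <- peak_v
  }
  amplitude <- peak_v - trough_v
  local_max <- (ipk == 1 || trace$samples[ipk] >= trace$samples[ipk - 1]) &&
    (ipk == length(trace$samples) || trace$samples[ipk] >=
       trace$samples[ipk + 1])
  structure(list(wave_id = wave_id, peak_latency = peak_t,
                 trough_latency = trough_t, amplitude = amplitude,
                 present = amplitude > 0 && local_max),
            class = "wave_metrics")
}

#' Assemble a growth series
#'
#' @param condition condition descriptor (shape, polarity, phase duration,
#'   gap).
#' @param levels data frame with columns `charge` (nC), `current` (µA),
#'   `amplitude` (µV), `latency` (ms) and optionally `above_facial_nerve`;
#'   must be strictly increasing in charge.
#' @return object of class `growth_series`. Levels at/above the facial
#'   nerve onset are retained in the table but flagged and excluded from
#'   all analyses.
#' @export
growth_series <- function(condition, levels) {
  stopifnot(is.data.frame(levels),
            all(c("charge", "amplitude") %in% names(levels)))
  if (is.unsorted(levels$charge, strictly = TRUE)) {
    stop("levels must be strictly increasing in charge")
  }
  if (is.null(levels$above_facial_nerve)) {
    levels$above_facial_nerve <- FALSE
  }
  structure(list(condition = condition, levels = levels),
            class = "growth_series")
}

analysis_levels <- function(series) {
  series$levels[!series$levels$above_facial_nerve, , drop = FALSE]
}

#' Detect the eABR threshold of a growth series
#'
#' Lowest tested charge level whose wave amplitude is strictly above the
#' criterion (0.1 µV); all levels at/above the facial nerve onset are
#' excluded first.
#'
#' @param series a [growth_series()].
#' @param criterion amplitude criterion in µV.
#' @return list of class `threshold_result` with `threshold_charge` (nC),
#'   `threshold_current` (µA), `criterion`, `defined`.
#' @export
detect_threshold <- function(series, criterion = 0.1) {
  lv <- analysis_levels(series)
  hit <- which(lv$amplitude > criterion)
  if (!length(hit)) {
    return(structure(list(threshold_charge = NA_real_,
                          threshold_current = NA_real_,
                          criterion = criterion, defined = FALSE),
                     class = "threshold_result"))
  }
  i <- min(hit)
  structure(list(threshold_charge = lv$charge[i],
                 threshold_current = if (!is.null(lv$current)) lv$current[i]
                                     else NA_real_,
                 criterion = criterion, defined = TRUE),
            class = "threshold_result")
}

#' Convert to decibels (20 log10 convention)
#'
#' The amplitude convention used for all charge and current levels: a
#' doubling corresponds to +6.0206 dB.
#'
#' @param value,reference positive quantities in the same unit.
#' @return `20 * log10(value / reference)` in dB.
#' @export
to_db <- function(value, reference = 1) {
  if (any(value <= 0) || any(reference <= 0)) {
    stop("to_db requires positive inputs")
  }
  20 * log10(value / reference)
}

#' Tested level nearest to a dB offset above threshold
#'
#' The target charge is `threshold * 10^(delta_db/20)`; the tested level
#' closest to the target in dB is returned, ties resolved toward the lower
#' level. Used to read suprathreshold latencies at +3 dB.
#'
#' @param series a [growth_series()].
#' @param delta_db offset above threshold in dB re 1 nC (default 3).
#' @param criterion threshold criterion passed to [detect_threshold()].
#' @return one row of the level table (data frame).
#' @export
level_at_db_above_threshold <- function(series, delta_db = 3,
                                        criterion = 0.1) {
  thr <- detect_threshold(series, criterion)
  if (!thr$defined) stop("no defined threshold for this series")
  lv <- analysis_levels(series)
  target_db <- to_db(thr$threshold_charge) + delta_db
  dev <- abs(to_db(lv$charge) - target_db)
  i <- which(dev == min(dev))[1]          # ties -> lower level
  if (lv$charge[i] == max(lv$charge)) {
    warning("target level at the top of the tested range")
  }
  lv[i, , drop = FALSE]
}

#' Tidy per-condition metrics table
#'
#' Machine twin of a growth-function figure panel: one row per level with
#' charge, current, amplitude, latency and threshold flags.
#'
#' @param series a [growth_series()].
#' @param criterion threshold criterion in µV.
#' @return data frame.
#' @export
metrics_table <- function(series, criterion = 0.1) {
  thr <- detect_threshold(series, criterion)
  lv <- series$levels
  data.frame(
    shape = series$condition$shape,
    polarity = series$condition$polarity,
    phase_duration = series$condition$phase_duration,
    interphase_gap = series$condition$interphase_gap,
    lv,
    at_threshold = thr$defined & lv$charge == thr$threshold_charge,
    suprathreshold = thr$defined & lv$charge >= thr$threshold_charge,
    stringsAsFactors = FALSE)
}
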