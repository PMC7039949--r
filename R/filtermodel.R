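#' @title Lowpass-filter threshold-prediction model
#'
#' @description
#' A simple linear model of electrical detection thresholds: the stimulus
#' waveform is passed through a lowpass "animal" filter, the output is
#' multiplied by a series of sliding Hanning windows spanning one stimulus
#' period, and the threshold is assumed inversely proportional to the
#' maximum windowed RMS. The target magnitude response is flat from 0 to
#' 110 Hz, falls at 6 dB/octave from 110 to 4000 Hz, and at 3 dB/octave
#' above 4000 Hz.
#'
#' A -3 dB/octave (half-order) segment cannot be realized exactly by a
#' rational biquad; [design_model_filter()] therefore least-squares fits a
#' biquad's log magnitude to the piecewise target over 10 Hz - 20 kHz and
#' reports the residual. The fit is deterministic. Predictions are
#' reported on the 20 log10 amplitude dB scale (6.02 dB per doubling);
#' the model is sign-blind (RMS), so polarity has no effect.
#'
#' @name filtermodel
NULL

#' Filter-model specification
#'
#' @param corner1,corner2 target corner frequencies, Hz (110 and 4000).
#' @param mid_slope,high_slope target slopes in dB/octave between/above the
#'   corners (-6 and -3).
#' @param window Hanning window duration, ms (10).
#' @param hop_fraction window hop as a fraction of its length (1/10).
#' @param rate stimulus presentation rate, pulses/s (23.3); the windows
#'   span one period `1/rate`.
#' @param fs_model model sampling rate, Hz; 1 MHz resolves 25 µs features.
#' @param calibration_offset additive dB constant set by [calibrate()].
#' @return object of class `filter_model_spec`.
#' @export
filter_model_spec <- function(corner1 = 110, corner2 = 4000,
                              mid_slope = -6, high_slope = -3,
                              window = 10, hop_fraction = 1 / 10,
                              rate = 23.3, fs_model = 1e6,
                              calibration_offset = NA) {
  stopifnot(corner1 < corner2, corner2 < fs_model / 2, window > 0,
            hop_fraction > 0, hop_fraction <= 1)
  structure(list(corner1 = corner1, corner2 = corner2,
                 mid_slope = mid_slope, high_slope = high_slope,
                 window = window, hop_fraction = hop_fraction, rate = rate,
                 fs_model = fs_model,
                 calibration_offset = calibration_offset),
            class = "filter_model_spec")
}

#' Target magnitude (dB) of the model filter
#'
#' @param spec a [filter_model_spec()].
#' @param f frequencies in Hz.
#' @return target magnitude in dB.
#' @export
model_target_db <- function(spec, f) {
  db <- numeric(length(f))
  mid <- f > spec$corner1 & f <= spec$corner2
  high <- f > spec$corner2
  db[mid] <- spec$mid_slope * log2(f[mid] / spec$corner1)
  at2 <- spec$mid_slope * log2(spec$corner2 / spec$corner1)
  db[high] <- at2 + spec$high_slope * log2(f[high] / spec$corner2)
  db
}

# Magnitude (dB) of a 2-pole / 2-zero analog section with real negative
# poles/zeros at the given corner frequencies (Hz), unity DC gain.
biquad_db <- function(f, p1, z1, p2, z2) {
  10 * (log10(1 + (f / z1)^2) + log10(1 + (f / z2)^2) -
          log10(1 + (f / p1)^2) - log10(1 + (f / p2)^2))
}

#' Design the model filter
#'
#' Deterministic least-squares fit of a biquad (two real poles, two real
#' zeros, unity DC gain) to the piecewise log-linear target over 200
#' log-spaced frequencies in 10 Hz - 20 kHz. The interleaved ordering
#' p1 < z1 < p2 < z2 is enforced by the parameterization, which also
#' guarantees a monotonically non-increasing magnitude above the first
#' pole.
#'
#' @param spec a [filter_model_spec()].
#' @return object of class `model_filter`: digital `b`, `a` at
#'   `spec$fs_model` (bilinear transform), analog corner frequencies
#'   (`poles_hz`, `zeros_hz`), fit report (`fit_freqs`, `fit_db`,
#'   `target_db`, `max_dev_db`) and the spec.
#' @export
design_model_filter <- function(spec = filter_model_spec()) {
  f <- exp(seq(log(10), log(20000), length.out = 200))
  target <- model_target_db(spec, f)
  # theta: log p1 plus log(ratio - 1) for each successive ratio, so the
  # ordering p1 < z1 < p2 < z2 holds for every theta (each multiplier is
  # 1 + exp(theta) > 1); this makes the magnitude non-increasing above p1
  unpack <- function(th) {
    p1 <- exp(th[1]); z1 <- p1 * (1 + exp(th[2]))
    p2 <- z1 * (1 + exp(th[3])); z2 <- p2 * (1 + exp(th[4]))
    c(p1, z1, p2, z2)
  }
  obj <- function(th) {
    q <- unpack(th)
    sum((biquad_db(f, q[1], q[2], q[3], q[4]) - target)^2)
  }
  th0 <- c(log(spec$corner1), log(2000 / 110 - 1), log(2), log(9))
  opt <- stats::optim(th0, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  q <- unpack(opt$par)
  fit_db <- biquad_db(f, q[1], q[2], q[3], q[4])
  # analog transfer function in s (rad/s), unity DC gain, then bilinear
  wz <- 2 * pi * q[c(2, 4)]
  wp <- 2 * pi * q[c(1, 3)]
  num <- c(1 / prod(wz), sum(1 / wz), 1)       # descending powers of s
  den <- c(1 / prod(wp), sum(1 / wp), 1)
  fs2 <- 2 * spec$fs_model
  # s = fs2 (1 - z^-1) / (1 + z^-1); expand polynomials in z^-1
  bilinear2 <- function(cf) {
    c2 <- cf[1] * fs2^2; c1 <- cf[2] * fs2; c0 <- cf[3]
    c(c2 + c1 + c0, -2 * c2 + 2 * c0, c2 - c1 + c0)
  }
  b <- bilinear2(num)
  a <- bilinear2(den)
  b <- b / a[1]
  a <- a / a[1]
  structure(list(b = b, a = a, fs = spec$fs_model,
                 poles_hz = q[c(1, 3)], zeros_hz = q[c(2, 4)],
                 fit_freqs = f, fit_db = fit_db, target_db = target,
                 max_dev_db = max(abs(fit_db - target)), spec = spec),
            class = "model_filter")
}

# One period of the stimulus at the model rate, filtered in steady state
# (two periods are filtered and the second kept, valid because the
# stimulus is periodic at the presentation rate).
filtered_period <- function(waveform, model) {
  spec <- model$spec
  dt_us <- 1e6 / spec$fs_model
  if (abs(waveform$sample_interval - dt_us) > 1e-12) {
    stop("waveform grid (", waveform$sample_interval,
         " us) does not match the model rate (", dt_us, " us)")
  }
  period_n <- round(spec$fs_model / spec$rate)
  x <- waveform$samples
  if (length(x) > period_n) {
    stop("waveform longer than one stimulus period (1/rate)")
  }
  x <- c(x, rep(0, period_n - length(x)))
  y <- iir_filter(model$b, model$a, c(x, x))
  y[(period_n + 1):(2 * period_n)]
}

hanning_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Predict the relative threshold of one stimulus period
#'
#' Filters the period, slides Hanning windows (duration `spec$window` ms,
#' hop `hop_fraction` of the length) across it with periodic wrap-around,
#' computes the RMS of each windowed segment, and returns
#' `-20 log10(max RMS)` plus the calibration offset (if set).
#'
#' @param waveform a `pulse_waveform` (from [make_pulse()] or
#'   [make_train()]) sampled at `spec$fs_model`, spanning at most one
#'   period.
#' @param model a designed [design_model_filter()].
#' @return relative threshold in dB.
#' @export
predict_relative_threshold <- function(waveform, model) {
  spec <- model$spec
  y <- filtered_period(waveform, model)
  if (all(waveform$samples == 0)) {
    stop("zero waveform: threshold undefined (infinite)")
  }
  n <- length(y)
  wlen <- round(spec$window / 1000 * spec$fs_model)
  hop <- max(1L, round(wlen * spec$hop_fraction))
  w <- hanning_window(wlen)
  starts <- seq(0L, n - 1L, by = hop)
  rms <- vapply(starts, function(s0) {
    idx <- ((s0 + seq_len(wlen) - 1L) %% n) + 1L
    sqrt(mean((w * y[idx])^2))
  }, numeric(1))
  rel <- -20 * log10(max(rms))
  if (!is.na(spec$calibration_offset)) rel <- rel + spec$calibration_offset
  rel
}

unit_amplitude_waveform <- function(shape, phase_duration, interphase_gap,
                                    fs_model) {
  g <- 1e6 / fs_model
  make_pulse(pulse_spec(shape, "ANODIC_FIRST", phase_duration,
                        interphase_gap, peak_amplitude = 1,
                        grid_resolution = g))
}

#' Calibrate the model to a measured reference threshold
#'
#' Sets the calibration offset so that the model's calibrated current
#' threshold for the reference condition equals the measured value
#' exactly. The standard reference is a rectangular pulse, 25 µs/phase,
#' 10 µs interphase gap, polarity-averaged. Calibration shifts all
#' predictions by a common additive dB constant; recalibrating with the
#' same reference is idempotent.
#'
#' @param model a `model_filter`.
#' @param reference_threshold_current measured threshold current, µA.
#' @param reference_shape,reference_phase_duration,reference_gap the
#'   reference stimulus.
#' @return the model with `spec$calibration_offset` set.
#' @export
calibrate <- function(model, reference_threshold_current,
                      reference_shape = "REC",
                      reference_phase_duration = 25, reference_gap = 10) {
  spec <- model$spec
  spec$calibration_offset <- NA
  m0 <- model
  m0$spec <- spec
  wf <- unit_amplitude_waveform(reference_shape, reference_phase_duration,
                                reference_gap, spec$fs_model)
  rel_ref <- predict_relative_threshold(wf, m0)
  spec$calibration_offset <-
    20 * log10(reference_threshold_current) - rel_ref
  model$spec <- spec
  model
}

#' Predicted thresholds for a set of stimulus conditions
#'
#' For each condition the relative threshold of the unit-amplitude
#' waveform is computed; with a calibrated model the current threshold is
#' `10^((rel + offset)/20)` µA and the charge threshold follows from
#' [charge_per_phase()] at that current.
#'
#' @param conditions data frame with columns `shape`, `phase_duration`,
#'   `interphase_gap`.
#' @param model a (calibrated) `model_filter`.
#' @return data frame with `relative_db`, `predicted_current` (µA) and
#'   `predicted_charge` (nC; `NA` when uncalibrated).
#' @export
predict_table <- function(conditions, model) {
  spec <- model$spec
  uncal <- model
  uncal$spec$calibration_offset <- NA
  out <- conditions
  out$relative_db <- NA_real_
  out$predicted_current <- NA_real_
  out$predicted_charge <- NA_real_
  for (i in seq_len(nrow(conditions))) {
    cd <- conditions[i, ]
    wf <- unit_amplitude_waveform(cd$shape, cd$phase_duration,
                                  cd$interphase_gap, spec$fs_model)
    rel <- predict_relative_threshold(wf, uncal)
    out$relative_db[i] <- rel
    if (!is.na(spec$calibration_offset)) {
      cur <- 10^((rel + spec$calibration_offset) / 20)
      out$predicted_current[i] <- cur
      out$predicted_charge[i] <- charge_per_phase(
        pulse_spec(cd$shape, "ANODIC_FIRST", cd$phase_duration,
                   cd$interphase_gap, peak_amplitude = cur))
    }
  }
  out
}
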