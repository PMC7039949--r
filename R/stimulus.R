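#' @title Charge-balanced biphasic pulse shapes
#'
#' @description
#' Construction of the four pulse shapes used for cochlear-implant
#' stimulation efficiency experiments: rectangular (`REC`) and three ramped
#' shapes (`RAMP_UP`, `RAMP_DOWN`, `RAMP_LONG`). All pulses are biphasic and
#' charge balanced: two phases of opposite polarity separated by an
#' interphase gap. By convention the anodic phase carries positive current.
#'
#' Shapes are defined by the per-phase current envelope:
#' * `REC`       - both phases flat at the peak amplitude;
#' * `RAMP_UP`   - both phases ramp linearly from 0 to the peak;
#' * `RAMP_DOWN` - both phases ramp linearly from the peak to 0;
#' * `RAMP_LONG` - phase 1 ramps peak -> 0, phase 2 ramps 0 -> peak,
#'   giving the longest possible continuous ramp across the pulse.
#'
#' Hence `RAMP_LONG` shares its first phase with `RAMP_DOWN` and its second
#' phase with `RAMP_UP`.
#'
#' @name stimulus
NULL

#' Pulse shape and polarity levels
#'
#' The four supported pulse shapes and two leading-phase polarities.
#' @export
PULSE_SHAPES <- c("REC", "RAMP_UP", "RAMP_DOWN", "RAMP_LONG")

#' @rdname PULSE_SHAPES
#' @export
POLARITIES <- c("ANODIC_FIRST", "CATHODIC_FIRST")

#' Specify a biphasic pulse
#'
#' @param shape one of `"REC"`, `"RAMP_UP"`, `"RAMP_DOWN"`, `"RAMP_LONG"`.
#' @param polarity `"ANODIC_FIRST"` (positive phase leads) or
#'   `"CATHODIC_FIRST"`.
#' @param phase_duration phase duration in microseconds (25/50/75 in the
#'   standard protocol; any positive value allowed).
#' @param interphase_gap zero-current gap between phases in microseconds
#'   (10 or 2900 in the standard protocol).
#' @param peak_amplitude peak current in microamperes (>= 0).
#' @param quant_step hardware current quantization step in microamperes;
#'   25 reproduces the stimulator's stepwise ramps, 0 gives ideal ramps.
#' @param grid_resolution internal sampling grid in microseconds (default 1).
#' @return object of class `pulse_spec`.
#' @examples
#' pulse_spec("RAMP_UP", peak_amplitude = 200)
#' @export
pulse_spec <- function(shape = "REC", polarity = "ANODIC_FIRST",
                       phase_duration = 25, interphase_gap = 10,
                       peak_amplitude = 100, quant_step = 0,
                       grid_resolution = 1) {
  shape <- match.arg(shape, PULSE_SHAPES)
  polarity <- match.arg(polarity, POLARITIES)
  if (phase_duration <= 0) stop("phase_duration must be positive")
  if (peak_amplitude < 0) stop("peak_amplitude must be >= 0")
  if (interphase_gap < 0) stop("interphase_gap must be >= 0")
  if (quant_step < 0) stop("quant_step must be >= 0")
  if (grid_resolution <= 0) stop("grid_resolution must be positive")
  if (quant_step > 0 && peak_amplitude > 0 && peak_amplitude < quant_step) {
    stop("peak_amplitude below one quant_step: no realizable hardware pulse")
  }
  structure(list(shape = shape, polarity = polarity,
                 phase_duration = phase_duration,
                 interphase_gap = interphase_gap,
                 peak_amplitude = peak_amplitude,
                 quant_step = quant_step,
                 grid_resolution = grid_resolution),
            class = "pulse_spec")
}

# Magnitude envelope of one phase sampled at cell midpoints so the discrete
# integral of an ideal ramp equals A * pw / 2 exactly. `direction` is "flat",
# "up" (0 -> A) or "down" (A -> 0).
phase_envelope <- function(direction, spec) {
  g <- spec$grid_resolution
  n <- max(1L, round(spec$phase_duration / g))
  A <- spec$peak_amplitude
  mid <- (seq_len(n) - 0.5) / n
  env <- switch(direction,
    flat = rep(A, n),
    up = A * mid,
    down = A * rev(mid)
  )
  q <- spec$quant_step
  if (q > 0 && direction != "flat" && A > 0) {
    # stepwise hardware ramp: round(A/q) equal-duration plateaus whose levels
    # are the ideal ramp values rounded to multiples of q
    np <- max(1L, round(A / q))
    lev <- q * round(A * (seq_len(np) - 0.5) / (np * q))
    plateau <- pmin(ceiling(seq_len(n) / (n / np)), np)
    env <- lev[plateau]
    if (direction == "down") env <- rev(env)
  }
  env
}

phase_directions <- function(shape) {
  switch(shape,
    REC = c("flat", "flat"),
    RAMP_UP = c("up", "up"),
    RAMP_DOWN = c("down", "down"),
    RAMP_LONG = c("down", "up")
  )
}

#' Sample a biphasic pulse on a uniform grid
#'
#' The two phases have opposite sign and (for a given shape) mirrored
#' envelope plans, so the net injected charge is zero by construction, also
#' in quantized hardware mode.
#'
#' @param spec a [pulse_spec()].
#' @return object of class `pulse_waveform`: list with `samples` (current,
#'   microamperes, one value per grid cell), `sample_interval` (microseconds)
#'   and `t0 = 0` (stimulus onset at the first sample).
#' @examples
#' wf <- make_pulse(pulse_spec("REC", peak_amplitude = 100))
#' sum(wf$samples) * wf$sample_interval  # zero net charge
#' @export
make_pulse <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  dirs <- phase_directions(spec$shape)
  e1 <- phase_envelope(dirs[1], spec)
  e2 <- phase_envelope(dirs[2], spec)
  g <- spec$grid_resolution
  ngap <- round(spec$interphase_gap / g)
  s <- if (spec$polarity == "ANODIC_FIRST") 1 else -1
  samples <- c(s * e1, rep(0, ngap), -s * e2)
  structure(list(samples = samples, sample_interval = g, t0 = 0),
            class = "pulse_waveform")
}

#' Charge per phase of a pulse
#'
#' Charge injected during one phase, using the protocol's printed
#' convention: `phase_duration * peak_amplitude` for rectangular pulses and
#' `phase_duration * peak_amplitude / 2` for any ramped shape. The ideal
#' (unquantized) ramp is used regardless of `quant_step`.
#'
#' @param spec a [pulse_spec()].
#' @return charge in nanocoulombs (µs * µA = pC; divided by 1000).
#' @examples
#' charge_per_phase(pulse_spec("RAMP_UP", phase_duration = 25,
#'                             peak_amplitude = 200))  # 2.5 nC
#' @export
charge_per_phase <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  q_pc <- if (spec$shape == "REC") {
    spec$phase_duration * spec$peak_amplitude
  } else {
    spec$phase_duration * spec$peak_amplitude / 2
  }
  q_pc / 1000
}

#' Specify a pulse train
#'
#' @param pulse a [pulse_spec()].
#' @param rate presentation rate in pulses per second (default 23.3).
#' @param n_pulses number of pulses (>= 1).
#' @return object of class `train_spec`.
#' @export
train_spec <- function(pulse, rate = 23.3, n_pulses = 1) {
  stopifnot(inherits(pulse, "pulse_spec"))
  if (rate <= 0) stop("rate must be positive")
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  structure(list(pulse = pulse, rate = rate, n_pulses = n_pulses),
            class = "train_spec")
}

#' Sample a pulse train
#'
#' Places `n_pulses` copies of the pulse at an inter-onset interval of
#' `1/rate` seconds, zero elsewhere. The waveform covers exactly
#' `n_pulses` periods, so charge balance is preserved per period.
#'
#' @param train a [train_spec()].
#' @return `pulse_waveform` covering `n_pulses / rate` seconds.
#' @export
make_train <- function(train) {
  stopifnot(inherits(train, "train_spec"))
  p <- make_pulse(train$pulse)
  g <- p$sample_interval
  period_n <- round(1e6 / train$rate / g)
  if (length(p$samples) > period_n) {
    stop("pulse longer than the inter-onset interval 1/rate")
  }
  one <- c(p$samples, rep(0, period_n - length(p$samples)))
  structure(list(samples = rep(one, train$n_pulses), sample_interval = g,
                 t0 = 0),
            class = "pulse_waveform")
}

#' Export a waveform as two-column delimited text
#'
#' Writes `time_us` and `current_uA` columns (tab separated) so waveforms
#' can be inspected or consumed outside R.
#'
#' @param waveform a `pulse_waveform`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(waveform, path) {
  stopifnot(inherits(waveform, "pulse_waveform"))
  d <- data.frame(
    time_us = (seq_along(waveform$samples) - 1) * waveform$sample_interval,
    current_uA = waveform$samples
  )
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
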