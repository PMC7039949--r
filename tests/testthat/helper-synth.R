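# Shared fixtures, all built in code.

# evoked trace on the effective (5.12 us) grid from explicit samples
trace_from <- function(samples, dt = 20.48 / 4, t_start = -5000) {
  pulseabr:::new_evoked_trace(samples, dt, t_start)
}

# trace holding an analytic function of time (ms)
trace_fun <- function(f, dt = 20.48, t_start = -5000, t_end = 10000) {
  t <- seq(t_start, t_end, by = dt)
  pulseabr:::new_evoked_trace(f(t / 1000), dt, t_start)
}

# the generator's wave template (peak +1 at `lat`, trough -1 at
# `lat + width`, ms)
gabor_ref <- function(t_ms, lat, width = 0.25) {
  s <- width / 2
  u <- (t_ms - (lat + s)) / s
  -u * exp(-u^2 / 2) / exp(-0.5)
}

# growth series from charge/amplitude vectors (charge:current factor 25
# nC per 1000 uA, i.e. a 25 us rectangular pulse)
series_from <- function(charge, amplitude, latency = 1.05,
                        shape = "REC", polarity = "ANODIC_FIRST",
                        above_fn = FALSE) {
  growth_series(
    list(shape = shape, polarity = polarity, phase_duration = 25,
         interphase_gap = 10),
    data.frame(charge = charge, current = charge * 40,
               amplitude = amplitude, latency = latency,
               above_facial_nerve = above_fn))
}

# single-wave, artifact-free generator parameters (wave II only)
params_wave_only <- function(noise_sd = 0, seed = 1, ...) {
  gen_params(
    noise_sd = noise_sd, seed = seed,
    wave_templates = list(II = list(base_latency = 1.05, width = 0.25,
                                    rel_amplitude = 1)),
    artifact = list(peak_uv_per_ua = 0, tau_ms = 0.025, exp_tail = NULL),
    ...)
}

# current (uA) injecting charge q (nC) for a shape at 25 us/phase
current_for <- function(shape, q, pw = 25) {
  pulseabr:::current_for_charge(shape, pw, q)
}

# baseline mean of one sweep over the default [-5, -1] ms window
mean_baseline <- function(ss, i) {
  dt <- 1e6 / ss$sampling_rate
  t <- ss$t_start + (seq_len(ncol(ss$sweeps)) - 1) * dt
  mean(ss$sweeps[i, t >= -5000 & t <= -1000])
}

# four delay-tagged sweep sets for one condition
delay_sets <- function(params, cond, seed = 1) {
  lapply(c(0, 5, 10, 15), function(d) {
    simulate_sweepset(params, cond, delay_tag = d,
                      seed = pulseabr:::derive_seed(seed, d + 1))
  })
}
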