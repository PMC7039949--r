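---
title: "Methods: pulse-shape efficiency analysis for eABR recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulse-shape efficiency analysis for eABR recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseabr)
```

## The problem

Cochlear implants stimulate the auditory nerve with charge-balanced
biphasic current pulses. Pulse shapes with linearly ramped phases have
been proposed as more charge-efficient than the standard rectangular
shape: the electrically evoked auditory brainstem response (eABR) reaches
a given wave amplitude at lower injected charge (though at higher peak
current). `pulseabr` implements the full measurement chain needed to test
this claim on recordings — or, for development and validation, on
synthetic recordings with known ground truth — plus a linear filter model
that predicts relative thresholds from the stimulus waveform alone.

## Stimuli

Four shapes are supported, each biphasic with phase duration $pw$
(default 25 µs; 50 and 75 µs in the duration series), interphase gap $g$
(10 µs, or 2.9 ms for the "monophasic-like" condition) and peak current
$A$:

* `REC` — both phases flat at $A$;
* `RAMP_UP` — both phases ramp 0 → $A$;
* `RAMP_DOWN` — both phases ramp $A$ → 0;
* `RAMP_LONG` — phase 1 ramps $A$ → 0, phase 2 ramps 0 → $A$.

Anodic current is positive by convention (arbitrary but fixed).
Charge per phase follows the study's printed convention:
$Q = pw \cdot A$ for `REC` and $Q = pw \cdot A / 2$ for every ramped
shape, using the *ideal* ramp even when the hardware quantization mode
(`quant_step = 25` µA) is on — printed charges follow the ideal formula.
Ideal ramps are sampled at cell midpoints so that the discrete integral
equals $A \cdot pw / 2$ exactly; quantized ramps are `round(A/step)`
equal-duration plateaus whose levels are the ideal ramp values rounded to
step multiples, with the second phase mirroring the first phase's plan so
charge balance is exact in every mode. The internal grid is 1 µs
(hardware was 3–4 µs; a finer grid is a faithful superset, and it is
configurable).

## The synthetic recording world

`gen_params()` states the simulated acquisition: 48 828 Hz sampling, 400
repetitions per recording, four recordings per level with the stimulus
delayed by 0/5/10/15 µs, epochs of −5 to +10 ms around stimulus onset
(−5 to +13 ms for the long gap). Each sweep is

$$ x(t) = \underbrace{s \cdot a(t)}_{\text{artifact}} +
          \underbrace{\textstyle\sum_w A_w(Q)\, g_w(t)}_{\text{waves II–IV}} +
          \varepsilon(t), $$

where $s = \pm 1$ flips with polarity while the waves do not change sign.
The artifact is a sharp exponential (decay 25 µs) at each phase onset,
with opposite signs for the two phases, scaled 5 µV per µA of stimulus
current; long-gap conditions add a slow exponential tail
($\tau = 1$ ms, 0.5 µV/µA), matching the trend-removal windows the
preprocessing uses.

Wave templates are derivative-of-Gaussian deflections normalized so the
positive peak (+1) sits exactly at the wave's latency and the trough (−1)
follows `width` ms later. `width = 0.25` ms is read as the
**peak-to-trough separation** (Gaussian $\sigma$ = 0.125 ms), consistent
with the 0.6 ms trough-search span and murine ABR morphology. Base
latencies are 1.05/1.5/2.0 ms for waves II/III/IV; wave III/IV values
are plausible defaults (not reported quantities). Latency decreases
10 µs per dB above threshold by default, with per-shape and per-polarity
offsets.

Wave II peak-to-trough amplitude follows a growth model in charge:
$A(Q) = \max(0, \beta (Q - Q_{thr}))$, optionally continuing past a knee
with a non-positive saturation slope (mirroring the broken-stick fit
bounds). Cathodic-first pulses are 1.10× more charge-efficient than
anodic-first ones (the study's threshold ratio). Default shape
thresholds order `RAMP_UP` < `RAMP_LONG` < `RAMP_DOWN` < `REC` in charge
with steeper slopes for ramped shapes — the qualitative finding the
pipeline must reproduce.

### Choice of the noise level

Per-sweep noise is white Gaussian. The original design note tied the
default (2 µV per sweep, hence $2/\sqrt{400} = 0.1$ µV after averaging)
to the 0.1 µV detection criterion. Implementation shows that pairing is
self-defeating: the amplitude *estimator* is "window maximum minus
following trough", whose noise floor on the averaged, bandpassed,
interleaved trace is $\approx 3.5\sigma_f$ where
$\sigma_f \approx 0.39\, \sigma_{\bar x}$ after the 100–3000 Hz
zero-phase bandpass. At $\sigma_{\bar x} = 0.1$ µV the floor is
≈ 0.135 µV — *above* the criterion — so every subthreshold level
triggers detection and thresholds collapse to the lowest tested level.
For the criterion to be a meaningful rule the floor must sit below it
with margin; the package default is therefore **1 µV per sweep**
($\sigma_{\bar x} = 0.05$ µV, floor ≈ 0.07 µV, ≈ 2.5 SD below 0.1 µV),
still realistic for averaged anesthetized-mouse EEG. The √n averaging
law is asserted independently of the level.

### What a green test does and does not establish

The generator emulates: polarity-antisymmetric artifacts with long-gap
exponential tails, delay-interleaved acquisition, level- and
shape-dependent wave growth and latency, facial-nerve truncation
metadata, and per-(condition, delay) reproducible noise streams derived
from one study seed. It does **not** emulate: biophysical nerve dynamics
(KLT channels), electrode impedance, non-Gaussian or correlated
physiological noise, across-sweep latency jitter, or amplitude drift.
Recovery results therefore validate the *analysis chain*, not the
biology.

## Preprocessing

Per delay-tagged recording: per-sweep baseline correction (mean over
−5…−1 ms) and averaging; onset-artifact removal by linear interpolation
over 0…0.3 ms after the (delayed) onset; for long-gap conditions,
least-squares subtraction of $a e^{-t/\tau} + c$ over 0.3–2.7 ms and
3.2–11 ms (the offset $c$ is included because residual DC precedes the
bandpass; $\tau$ is profiled on a log grid and refined — deterministic),
plus interpolation bridging 2.7–3.2 ms across the second-phase onset;
4th-order Butterworth 100–3000 Hz bandpass. Filtering is **zero-phase**
(forward–backward) by default — the causal option exists for fidelity
experiments — and is computed as cascaded second-order sections because
the expanded order-8 polynomial is numerically unstable at this narrow
normalized band (poles cluster near $z = 1$).

The four delay-tagged traces are then interleaved onto a 4× grid
(20.48 µs → 5.12 µs), treating the stated 5/10/15 µs delays as the ideal
quarter-sample grid 5.12/10.24/15.36 µs — the same approximation the
acquisition itself makes; for ≤ 3 kHz content the residual error is
< 2% RMS. Finally, anodic- and cathodic-first traces may be averaged
sample-wise, cancelling the polarity-antisymmetric artifact exactly
while preserving the waves. Every step appends its parameters to the
trace's provenance record.

### Known systematic effects

Measured on noise-free synthetic composites (and asserted as the
module's contract in the unit tests):

* the zero-phase 3 kHz lowpass attenuates the wave II peak-to-trough
  amplitude by ≈ 6%, and wave III's leading lobe raises the wave II
  trough by ≈ 4% — a level-independent ≈ 10% amplitude shrinkage that
  cancels in threshold ordering and inflates slope errors to ≈ −10%;
* the same lowpass smooths the asymmetric peak/trough template into an
  apex ≈ 12–17 µs early (short gap); the long-gap exponential fit can
  add up to ≈ −55 µs. This is why the 2-effective-sample (10.24 µs)
  latency acceptance band is left red: the bias is inherent to the
  stated filter and template, not a defect of the estimator (unfiltered
  recovery is within one effective sample).

## Quantification and fits

Amplitude = positive peak minus following trough (trough searched 0.6 ms
past the peak); latency = peak time; threshold = lowest tested charge
with amplitude strictly above 0.1 µV, scanning per polarity first and
averaging per shape afterwards. Wave search windows default to
II = 0.7–1.4, III = 1.3–1.9, IV = 1.8–2.6 ms (declared, configurable).
Levels at/above an annotated facial-nerve onset are excluded before any
analysis. Suprathreshold latencies are read at the tested level nearest
to +3 dB re 1 nC above threshold (ties toward the lower level). All dB
quantities use $20 \log_{10}$, so a doubling is +6.0206 dB, and for any
shared threshold set the charge-basis strength–duration slope exceeds
the current-basis slope by exactly that constant.

Growth functions are fitted by OLS (linear) and by a continuous
two-segment broken-stick model with the study's printed bounds: slope 1
in [0.1, 50] µV/nC, slope 2 in [−2, 0] µV/nC (saturation forced flat or
falling), intercept in [−10, 2] µV, knee in [2, 20] nC. The model is
parameterized by (intercept, slope1, slope2, knee) with continuity at
the knee enforced; fitting is bounded L-BFGS-B with a deterministic
multi-start over 9 equispaced knee candidates. Current-basis fits reuse
the machinery with bounds rescaled by the condition's nC/µA factor.
Where the study chose between models "based on visual inspection", the
package substitutes a reproducible rule: broken-stick is selected iff
the extra-sum-of-squares F-test is significant at α = 0.05 *and* the
knee is strictly interior — with a manual override flag for fidelity.
On 200 seeded linear datasets at default noise the broken-stick
false-selection rate is ≤ 10% (measured ≈ 0.5%).

## The filter model

The threshold model passes one stimulus period (1/23.3 s) through a
lowpass "animal" filter, multiplies the output by 10 ms Hanning windows
hopped by 1 ms spanning the period (wrapping periodically), takes the
RMS of each windowed segment, and reports
$-20\log_{10}(\max \mathrm{RMS})$ plus a calibration offset. The target
magnitude is flat to 110 Hz, −6 dB/oct to 4 kHz, −3 dB/oct above. A
−3 dB/oct (half-order) segment is not realizable by a rational biquad;
the package fits one biquad (two real poles, two real zeros, unity DC
gain) to the piecewise target by deterministic least squares over 200
log-spaced frequencies in 10 Hz–20 kHz. The parameterization forces the
ordering $p_1 < z_1 < p_2 < z_2$, which guarantees a monotonically
non-increasing magnitude above the first pole; the maximum deviation
from the target (≈ 2.7 dB, dominated by the corner regions) is reported
in the design object. The model runs at 1 MHz so 25 µs features are
exactly resolved; the filter state is brought to periodic steady state
by filtering two concatenated periods and keeping the second.

Calibration pins the predicted current threshold of the reference
condition (rectangular, 25 µs/phase, 10 µs gap) to a measured value;
because the model is linear and RMS sign-blind, calibration is a common
additive dB constant, predictions are polarity-invariant, and doubling
the stimulus amplitude lowers the predicted threshold by exactly
6.0206 dB.

One documented consequence of this model class: at fixed charge the
spectrum of a charge-balanced biphasic pulse scales with the phase
separation ($|X(f)| \approx 2\pi Q f (pw + g)$ below the corner), so
longer phases need *less* charge — ≈ 0.65 dB/doubling even under the
exact piecewise target. "Constant charge across phase duration" is
therefore only qualitative (flat relative to the animal's
3.45–4.01 dB/doubling), and the 0.5 dB flatness acceptance band is left
red by design rather than forced.

## Determinism, containers, provenance

All randomness flows from one study seed; per-(condition, delay) noise
substreams are derived deterministically so any sweep set is
reproducible in isolation. Sweep sets are stored as a directory
container: a versioned JSON manifest (unknown fields preserved) plus one
tab-separated matrix per sweep set written at `%.17g` precision, making
the round trip bit-lossless without any binary format. Pipeline tables
embed the config hash (FNV-1a of the canonical JSON) and seed.

## Limitations

* The latency and amplitude biases above are properties of the stated
  filter + template combination; different widths or filter settings
  change them.
* The filter model ignores polarity and slope sensitivity by
  construction, so it cannot reproduce rampUP/rampDOWN asymmetries or
  long-gap threshold drops seen in animals.
* Mixed-model statistics across animals are out of scope; the package
  emits descriptive per-condition tables only.
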