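---
title: "Models and methods in optephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in optephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optephys)
```

`optephys` implements the computational chain of an LED-based optogenetics +
multielectrode electrophysiology platform: dose calibration, stimulation
pattern synthesis, LFP/spike signal conditioning, multitaper spectral
analysis, stimulation-artifact handling, and a closed-loop theta-power
controller, together with a virtual subject that makes the whole chain
testable against exact ground truth. This vignette documents the models, the
tunable parameters and the numerical choices, and states what the simulator
does and does not capture.

## Dose calibration

Each implanted ferrule transmits a different fraction of the LED output, so
doses are standardized in irradiance units rather than command volts. Powers
measured through the ferrule at a set of command voltages are converted to
irradiance by dividing by the fiber core cross-section $\pi (d/2)^2$ (0.0314
mm² for the standard 200 µm core) and regressed on voltage by ordinary least
squares: $I(V) = \beta_0 + \beta_1 V$.

Choices worth noting:

* **The intercept is fitted, not forced to zero.** LEDs have a turn-on
  offset, and an anomalous intercept is a useful ferrule diagnostic. $r^2$ is
  computed on irradiance; because the area conversion is a positive scalar,
  this equals the power-domain $r^2$.
* **Out-of-range targets error rather than clip.** Over-driving the LED
  risks tissue heating, so the calibrated `[v_min, v_max]` range is a hard
  envelope, and a fitted curve predicting more than a configurable safety
  ceiling (default 80 mW/mm², the upper end of the non-damaging window) at
  `v_max` is rejected outright. Waveform renderers additionally floor the
  command at 0 V: "off" is always attainable.
* The calibration CSV holds only `(voltage_v, power_mw)` pairs; fiber
  geometry and wavelength live in configuration, since they are properties of
  the implant rather than of one measurement session.

The driver model is the affine map of the 0–5 V analog command onto 0–300 mA
of LED current.

## Stimulation patterns

All pulse patterns compile to a `pulse_train` — strictly increasing onsets,
per-pulse widths and intensities inside an epoch, with non-overlap enforced
by the constructor — and can be rendered to an analog command waveform whose
pulse edges snap to the command sample grid (default 10 kHz, i.e. 20 samples
across a 2 ms pulse; configurable).

* **Fixed**: onsets at $t_0 + k/f$ while the whole pulse fits the epoch.
* **Jittered**: the *instantaneous frequency* of each interval is drawn from
  a normal distribution centred on $f$, truncated to $f \pm h$ where $h$ is
  the jitter halfwidth. The "±h" bound is interpreted as a hard truncation
  with $\sigma = h/2$ by default (≈2σ truncation); σ is configurable because
  the underlying spread of the published design is not parameterized. Jitter
  is applied in the frequency domain and then inverted to an interval, so the
  stated bound holds exactly on frequency.
* **Poisson**: i.i.d. exponential intervals at the nominal rate, with
  intervals shorter than the pulse width *redrawn* — light pulses cannot
  physically overlap. Redrawing (rather than shifting) keeps accepted
  intervals memoryless; the realized rate of this dead-time-modified process
  is $\lambda/(1+\lambda w)$, which the tests verify. A `dead_time = FALSE`
  mode realizes the nominal rate and drops offenders instead.
* **Burst**: `pulses_per_burst` pulses at the intra-burst frequency nested in
  a cycle at the burst frequency (theta-nested gamma); the burst span
  $(n-1)/f_{intra} + w$ must fit inside one cycle.
* **Sinusoid**: irradiance $I(t) = \tfrac{I_{max}}{2}(1 - \cos 2\pi f t)$,
  which starts from zero at the epoch edge and is non-negative throughout;
  phase and offset conventions of continuous stimulation are otherwise
  unconstrained, so the zero-start form was chosen for command-safety.

Trial protocols follow the platform's standard 20 s background / 20 s
stimulation / 20 s background layout, with the pattern order given by a
seeded permutation. All stochastic generators are bit-reproducible under
their seed.

## Signal chains

The LFP chain mirrors the platform's online path: a 1-pole Butterworth
band-pass at 1–500 Hz followed by downsampling to exactly 2000 Hz. The
25 kHz → 2 kHz ratio is non-integer (12.5), and a 1-pole filter rolls off far
too slowly (~6 dB/octave) to serve as an anti-alias filter, so the default
chain adds a windowed-sinc low-pass guard (cutoff 800 Hz) evaluated only at
the 2 kHz output instants — a two-phase polyphase evaluation that keeps the
per-channel cost linear. `paper_faithful = TRUE` disables the guard and takes
nearest-sample decimation after the 1-pole filter only, reproducing the
platform's plainer behaviour at the cost of aliasing. Filtering is causal by
default (online-style); zero-phase forward–backward filtering is available
for offline analysis. The spike band is 500–5000 Hz (2-pole Butterworth) at
the original rate.

Median referencing subtracts the per-sample median across each named channel
group (e.g. the CA1 and CA3 electrode rows separately), which removes
common-mode movement and stimulation artifacts while sparing events local to
one channel; it requires at least 3 channels per group and is idempotent.

Spike detection applies symmetric thresholds at $k$ times the per-channel SD
(default $k = 5$). The plain SD is the stated scale, but large spikes inflate
it; a robust `median(|x|)/0.6745` estimator is available. Events within a
1 ms dead time of an accepted event are suppressed, and snippets of 0.6 ms
pre / 1.0 ms post peak are extracted — dead time and snippet geometry are
package choices, as detection-stage conventions vary between sorters. On
pure Gaussian noise the false-event rate matches the tail-probability oracle
$2\Phi(-5) f_s \approx 0.014$ events/s/channel.

## Multitaper spectral analysis

Spectra average the squared magnitudes of taper-windowed Fourier transforms
over $K$ discrete prolate spheroidal sequences; with window length $T$ and
half-bandwidth $W$, $K = 2TW - 1$ by default (the standard configuration
$T = 4$ s, $W = 1$ Hz gives 7 tapers). Power is a one-sided density in
µV²/Hz, so the integral of the estimate equals the signal variance (Parseval
convention, verified to 2% on white noise).

Tapers are computed from the standard symmetric tridiagonal form of the
concentration problem. Dense eigendecomposition is used up to length 1024;
longer tapers are solved at 1024, spline-interpolated to the target length
and re-orthonormalized by QR — the tapers are smooth, slowly varying
functions of relative position, so interpolation error (~1e-5 relative) is
far below the 1e-8 orthonormality tolerance, and the exact and interpolated
paths agree to 1e-4 where both are feasible. Concentration eigenvalues are
computed exactly from the sinc-kernel quadratic form via FFT autocorrelation.

Spectrogram windows are left-aligned and advanced by `step_s` (default
0.5 s), with window *centres* reported as the time axis — the alignment
convention is not dictated by anything upstream, and centring makes
stimulation-epoch boundaries read correctly. A 60 s record at $T = 4$,
step 0.5 yields `floor((60-4)/0.5)+1 = 113` windows.

Peristimulus averages use a lag grid inclusive of both endpoints, with event
times snapped to the nearest sample: at 2 kHz the default −5…+40 ms window
has exactly 91 lags.

**Harmonic removal** fits amplitude and phase of a sinusoid at each listed
frequency by least squares over the whole record and subtracts the fit. This
removes exactly one complex-exponential pair per frequency, leaving the
amplitude and phase of everything else untouched (unlike a notch filter),
which is what makes it usable both for line noise and for harmonic
deconstruction of a periodic evoked response. The alternative — significance-
gated spectral interpolation — was deliberately not reproduced: per-record
regression is deterministic, idempotent (re-application changes the output
by < 1e-9 RMS) and testable against an exact projection oracle. Whole-record
fitting is used; per-window operation is an open convention either way.

## Artifact handling

Optical stimulation near the electrodes produces charge/discharge transients
at pulse onset and offset whose amplitude scales with intensity while the
waveform stays stereotyped. Templates are therefore estimated *per intensity
level* (no cross-intensity interpolation by default) by peristimulus
averaging of a recording from tissue assumed response-free, over a window
from 2 ms before onset to 10 ms after offset. Subtraction is sample-aligned
at each event; overlapping windows subtract additively, with a warning,
since single-pulse templates only approximate compound artifacts. The
underlying identical-artifact assumption between the response-free and
target sites is documented, not validated — it is an experimental-design
assumption.

High-pass-filtered artifacts can masquerade as single units. Flagging uses
two statistics per unit: the fraction of spikes inside stimulation epochs and
the vector strength $|{\rm mean}\, e^{2\pi i f t}|$ of in-stimulation spike
times at the stimulation frequency. A unit is `suspect_artifact` only when
*both* exceed their thresholds (defaults 0.99 and 0.8). The published
criteria are qualitative ("only during stimulation", "locked to the
stimulation frequency"); these thresholds are this package's deliberately
conservative operationalization, not an upstream standard, and flagging is
monotone in both statistics by construction.

## Closed-loop controller

The controller slides a monitoring window over the multichannel LFP,
computes each channel's theta-band (6–10 Hz) power as a fraction of total
power over 1 Hz–Nyquist (matching the LFP band's lower edge), and triggers
when the fraction drops below `threshold_fraction` (default 3.4%) on at
least `min_channels` (default 4) channels. On a trigger, a predefined train
(default 35 Hz, 10 ms, 50 mW/mm² for 30 s) is scheduled at the window end
plus the output latency (default 46.9 ms, the measured command-path mean;
optional Gaussian jitter with σ = 3.1 ms). Detections during a train are
logged but suppressed; detection re-arms immediately after the train unless
a refractory is configured.

The monitoring window defaults to 1 s stepping 0.5 s: a 4 s window (the
offline spectrogram standard) resolves theta more finely but reacts far too
slowly for control; 1 s with a time-bandwidth-2 estimate (3 tapers) still
separates 6–10 Hz from neighbours. Both window and normalization band are
configuration-exposed because online implementations vary. The controller is
a pure function of (stream, config, seed) and its log asserts that emitted
trains never overlap.

## The virtual subject

The simulator produces recordings whose decomposition into components is
exact by construction — `recording = noise + theta + evoked + artifact
(+ spike waveforms)` — so analysis stages can be tested against ground truth
rather than against themselves.

* **Background**: Gaussian noise spectrally shaped to $f^{-\beta}$ (flat
  below 1 Hz; default β = 1.5, SD 50 µV) plus a theta sinusoid (default
  8 Hz, 150 µV) with a common phase, per-channel ±20% gain jitter, and a
  piecewise amplitude schedule for suppression scenarios.
* **Evoked responses**: each pulse adds a difference-of-exponentials kernel
  $e^{-t/\tau_d} - e^{-t/\tau_r}$ normalized to unit peak; the decay constant
  is solved so the kernel peaks exactly at the configured latency (default
  11 ms, rise τ 5 ms → decay τ ≈ 32 ms). Per-pulse amplitude is
  `gain × intensity × width(ms) × r`, with the resource $r$ dropping by the
  release fraction $u$ (default 0.3) at each pulse and recovering with
  τ = 200 ms. This minimal single-resource model reproduces the decrease of
  steady-state evoked amplitude with stimulation frequency; the opsin
  photocycle (state accumulation under prolonged illumination) is explicitly
  *not* modeled, and the simulator makes no claim to reproduce
  intensity-dependent biphasic/unipolar waveform morphology quantitatively.
* **Artifacts**: +/− exponential edges (τ = 2 ms) at pulse onset/offset,
  amplitude 2 µV per mW/mm² — linear in intensity and identical across
  channels (common-mode), consistent with electrical-coupling pickup.
* **Spiking**: inhomogeneous Poisson at `baseline × (1 + gain·1[stim])`,
  thinned by a 2 ms refractory, with an optional sustained mode that keeps
  the elevated rate after stimulation; two stereotyped biphasic waveforms are
  inserted into wideband streams — sufficient for detection tests, not for
  sorting studies.

Two simulator-versus-reality caveats matter for interpreting green tests.
First, the closed-loop scenarios use a steeper background (β = 3): with the
generic β = 1.5 background the theta-band fraction of theta-free noise is
~6–10%, which can never fall below a 3.4% threshold, whereas in vivo
hippocampal spectra fall off much faster at these frequencies. Second,
harmonic-origin checks are run on the noise-free evoked component, because
single multitaper bins of the composite fluctuate (χ² spread over 7 tapers)
by more than the peak criterion. Passing tests demonstrate correctness of
the analysis chain on data with the assumed statistical structure; they do
not certify performance on tissue, electrodes or optics the simulator does
not model (conduction delays, movement artifacts, electrode drift,
biophysical circuit dynamics).

## Problem sizes and tolerances

The test suite and the acceptance script use seconds-to-minutes problem
sizes chosen to keep statistical checks well-powered: 10⁴-interval KS tests
for the pattern laws, 500-replicate rate checks for the dead-time Poisson
process, 200-pulse CLT bounds for template recovery, 60 s × 16-channel
streams for the LFP chain, and 45–100 s 16-channel scenarios for the
controller. Numerical tolerances are stated next to each check: 1e-8 for
taper orthonormality, 1e-9 V for calibration round-trips, 2% for Parseval,
5% RMS for artifact closure, and 1e-9 RMS for harmonic-removal idempotence.
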