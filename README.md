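# optephys

Tools for designing, simulating and analysing combined **optogenetic
stimulation and multielectrode electrophysiology** experiments, of the kind
run on low-cost LED-based open-source acquisition platforms: an implanted
optical ferrule drives a genetically targeted population (e.g. ChR2-expressing
medial-septum or hippocampal neurons) while a 16-channel array records local
field potentials (LFP) and spikes, in open loop or under closed-loop control.

The package covers the full computational chain around such an experiment:

* **Calibration** — per-ferrule linear map between LED command voltage *V*
  and emitted irradiance *I* (mW/mm²): *I = β₀ + β₁V* fitted by OLS from a
  voltage/power table, with irradiance computed as power over the fiber core
  cross-section π(d/2)². Inversion gives the command voltage for a target
  dose and refuses to extrapolate above the calibrated maximum.
* **Pattern synthesis** — fixed, frequency-jittered (truncated-normal
  instantaneous frequency), Poisson (exponential intervals with a pulse-width
  dead time), nested-burst (e.g. four 42 Hz pulses per 7 Hz cycle) and
  continuous-sinusoid patterns, realized as pulse trains and rendered analog
  command waveforms; randomized 20 s/20 s/20 s background–stimulation–background
  trial protocols.
* **Signal chains** — online-style LFP isolation (1-pole Butterworth
  1–500 Hz, downsampled to exactly 2000 Hz with an anti-alias guard),
  offline spike band (500–5000 Hz), per-group median referencing, and ±5·SD
  threshold spike detection with snippet extraction.
* **Spectral analysis** — multitaper spectra and spectrograms using DPSS
  (Slepian) tapers with *K* = 2*TW* − 1 (the standard *T* = 4 s, *W* = 1 Hz,
  7-taper configuration), peristimulus averaging (−5…+40 ms), normalized
  band power, autocorrelation, and phase-preserving removal of sinusoidal
  components by least-squares regression (line noise or response harmonics).
* **Artifact handling** — stimulus-locked artifact templates estimated from
  response-free tissue, sample-aligned template subtraction, and flagging of
  putative artifactual "units" by in-stimulation fraction and vector
  strength.
* **Closed-loop control** — a block-wise controller that monitors normalized
  theta power (6–10 Hz fraction of total LFP power) per channel and, when it
  drops below a threshold (default 3.4%) on ≥ 4 channels, emits a predefined
  train (default 35 Hz, 10 ms, 50 mW/mm² for 30 s) after a modeled output
  latency (46.9 ms), with detection lockout during stimulation.
* **Virtual subject** — a seeded simulator producing multichannel recordings
  as an *exact* sum of 1/f background, scheduled theta, pulse-evoked kernels
  with single-resource synaptic-style depression, intensity-scaled edge
  artifacts and stimulus-modulated Poisson spiking — the ground truth that
  every analysis stage is tested against.

## Worked example

```r
library(optephys)

# calibrate a ferrule from a voltage/power table and invert a 50 mW/mm^2 dose
pts <- data.frame(voltage_v = 0:5, power_mw = 0.3141593 * (0:5))
curve <- fit_calibration(pts, fiber_spec(200, 0.37, 465))
curve
#> <calibration_curve> irradiance = -4.997e-15 + 10 * V  (mW/mm^2), V in [0, 5], r^2 = 1.00000
#>   fiber: 200 um core, NA 0.37, 465 nm
voltage_for_irradiance(50, curve)
#> [1] 4.999999

# a 7 Hz, 10 ms, 50 mW/mm^2 train over a 20 s stimulation epoch
train <- fixed_train(pattern_spec("fixed", 50, 7, 0.010), c(0, 20))
nrow(train)
#> [1] 140

# the evoked kernel: peristimulus average around an isolated pulse
cfg <- subject_config(n_channels = 4, sample_rate = 2000, seed = 42)
ev <- evoked_response(cfg, pulse_train(1, 0.010, 50, c(0, 3)), 3)
psa <- peristimulus_average(ev$trace[, 1], 1, sample_rate = 2000)
psa$lag_s[which.max(psa$mean_uv)] * 1000   # evoked peak latency, ms
#> [1] 11

# full simulated session: background / 7 Hz stimulation / background
prot <- assemble_protocol(list(pattern_spec("fixed", 50, 7, 0.010)),
                          trial_protocol(20, 20, 20))
ses <- compose_session(cfg, prot)
psa7 <- peristimulus_average(ses$recording, ses$truth$trains[[1]]$onset_s)
psa7$lag_s[which.max(psa7$mean_uv)] * 1000
#> [1] 9.5
```

The isolated-pulse response peaks 11 ms after pulse onset; in the 7 Hz
session the peristimulus peak sits slightly earlier because each response
rides on the decaying tail of the previous one. A multitaper spectrogram
(`mt_spectrogram`) of the session shows power at 7 Hz and its harmonics
confined to the stimulation epoch, and `remove_harmonics` isolates the
fundamental.

A thin command-line wrapper over the same functions is installed at
`inst/cli/optephys` (subcommands `calibrate`, `genstim`, `simulate`, `psa`,
`loop`).

## Vignette

`vignettes/optephys-methods.Rmd` documents the models, the numerical choices
(taper computation, resampling, depression model, thresholds) and the
simulator's scope and limitations.
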