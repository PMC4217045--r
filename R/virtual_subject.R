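#' Virtual-subject configuration
#'
#' Parameters of the synthetic hippocampal recording generator used to
#' exercise every analysis stage with known ground truth. The simulated LFP is
#' the exact sum of four components: 1/f-shaped broadband noise, a theta
#' (6--10 Hz) sinusoid with a controllable amplitude schedule, pulse-evoked
#' responses with short-term depression, and intensity-scaled edge artifacts.
#' Spiking is an inhomogeneous Poisson process whose rate is elevated during
#' stimulation, rendered into the wideband stream as stereotyped biphasic
#' waveforms.
#'
#' The evoked kernel is a difference of exponentials
#' `k(t) = e^(-t/decay_tau) - e^(-t/rise_tau)` normalized to unit peak; when
#' `decay_tau_s` is `NULL` it is solved so the kernel peaks exactly at
#' `peak_latency_s` (default 11 ms) given the rise time. Per-pulse amplitude
#' is `gain * intensity * width_ms * r`, where the resource `r` drops by the
#' release fraction at each pulse and recovers exponentially -- a minimal
#' single-resource depression model that reproduces the observed decrease of
#' steady-state evoked amplitude with stimulation frequency. The opsin
#' photocycle itself is deliberately not modeled.
#'
#' Channels receive a fixed +/-20% gain jitter (seeded) so that group-wise
#' median referencing sees realistic heterogeneity.
#'
#' @param n_channels Number of channels (default 16; first half CA1, second
#'   half CA3).
#' @param sample_rate Hz; 2000 for LFP-rate sessions, 25000 for wideband.
#' @param one_over_f_exponent Spectral slope of the background noise.
#' @param broadband_sd_uv Background noise SD, microvolts.
#' @param theta_frequency_hz,theta_amplitude_uv Theta sinusoid parameters.
#' @param peak_latency_s Evoked-kernel peak latency, seconds.
#' @param rise_tau_s,decay_tau_s Kernel time constants, seconds
#'   (`decay_tau_s = NULL` solves for the peak latency).
#' @param gain_uv Evoked gain, microvolts per (mW/mm^2 x ms of pulse width).
#' @param release_fraction Depression release fraction u in (0, 1).
#' @param recovery_tau_s Depression recovery time constant, seconds.
#' @param edge_amplitude_uv_per_mw_mm2 Artifact edge amplitude per unit
#'   intensity.
#' @param edge_tau_s Artifact edge decay time constant, seconds.
#' @param baseline_rate_hz,stim_gain,refractory_s Spiking parameters: baseline
#'   rate, multiplicative in-stimulation gain (rate scales by 1 + gain), and
#'   absolute refractory period.
#' @param sustained_spiking If `TRUE` the elevated rate persists after the
#'   stimulation epoch ends.
#' @param gain_jitter Half-width of the per-channel gain jitter.
#' @param seed Master seed; all generators derive from it.
#' @return An object of class `subject_config`.
#' @export
subject_config <- function(n_channels = 16, sample_rate = 2000,
                           one_over_f_exponent = 1.5, broadband_sd_uv = 50,
                           theta_frequency_hz = 8, theta_amplitude_uv = 150,
                           peak_latency_s = 0.011, rise_tau_s = 0.005,
                           decay_tau_s = NULL, gain_uv = 1,
                           release_fraction = 0.3, recovery_tau_s = 0.2,
                           edge_amplitude_uv_per_mw_mm2 = 2, edge_tau_s = 0.002,
                           baseline_rate_hz = 5, stim_gain = 1,
                           refractory_s = 0.002, sustained_spiking = FALSE,
                           gain_jitter = 0.2, seed = 1L) {
  if (release_fraction <= 0 || release_fraction >= 1)
    op_stop("release_fraction must be in (0, 1)", "optephys_parameter_error")
  stopifnot(rise_tau_s > 0, recovery_tau_s > 0, edge_tau_s > 0)
  if (is.null(decay_tau_s)) {
    peak_of <- function(td) log(td / rise_tau_s) * rise_tau_s * td / (td - rise_tau_s)
    decay_tau_s <- stats::uniroot(function(td) peak_of(td) - peak_latency_s,
                                  c(rise_tau_s * 1.0001, 10))$root
  }
  structure(list(n_channels = as.integer(n_channels), sample_rate = sample_rate,
                 one_over_f_exponent = one_over_f_exponent,
                 broadband_sd_uv = broadband_sd_uv,
                 theta_frequency_hz = theta_frequency_hz,
                 theta_amplitude_uv = theta_amplitude_uv,
                 peak_latency_s = peak_latency_s, rise_tau_s = rise_tau_s,
                 decay_tau_s = decay_tau_s, gain_uv = gain_uv,
                 release_fraction = release_fraction,
                 recovery_tau_s = recovery_tau_s,
                 edge_amplitude_uv_per_mw_mm2 = edge_amplitude_uv_per_mw_mm2,
                 edge_tau_s = edge_tau_s,
                 baseline_rate_hz = baseline_rate_hz, stim_gain = stim_gain,
                 refractory_s = refractory_s,
                 sustained_spiking = sustained_spiking,
                 gain_jitter = gain_jitter, seed = as.integer(seed)),
            class = "subject_config")
}

# deterministic per-channel gain factors
channel_gains <- function(cfg) {
  with_seed(cfg$seed + 101L,
            1 + runif(cfg$n_channels, -cfg$gain_jitter, cfg$gain_jitter))
}

# default channel grouping: first half CA1, second half CA3
default_groups <- function(n_channels) {
  half <- floor(n_channels / 2)
  list(CA1 = seq_len(half), CA3 = seq(half + 1, n_channels))
}

# evaluate a piecewise theta amplitude schedule at sample times
schedule_scale <- function(theta_schedule, t) {
  s <- rep(1, length(t))
  if (is.null(theta_schedule)) return(s)
  sched <- as.data.frame(theta_schedule)
  for (r in seq_len(nrow(sched)))
    s[t >= sched$start_s[r] & t < sched$end_s[r]] <- sched$scale[r]
  s
}

#' Simulate the background LFP (1/f noise + scheduled theta)
#'
#' Broadband noise is synthesized by spectral shaping of white Gaussian noise
#' (density proportional to `f^-exponent`, flat below 1 Hz) and rescaled to the
#' configured SD. Theta is an amplitude-modulated sinusoid with a common phase
#' across channels and per-channel gain; `theta_schedule` scales its amplitude
#' piecewise (rows `start_s`, `end_s`, `scale`) to emulate e.g. theta
#' suppression episodes for closed-loop scenarios.
#'
#' @param cfg A [subject_config()].
#' @param duration_s Duration, seconds.
#' @param theta_schedule Optional data frame `start_s,end_s,scale`.
#' @param seed Seed (defaults to the config seed).
#' @return List: `recording` (a [recording()]) and `truth` (list with `noise`
#'   and `theta` component matrices and the schedule).
#' @export
simulate_background <- function(cfg, duration_s, theta_schedule = NULL,
                                seed = cfg$seed) {
  fs <- cfg$sample_rate
  n <- round(duration_s * fs)
  gains <- channel_gains(cfg)
  noise <- with_seed(seed + 1L, {
    out <- matrix(0, n, cfg$n_channels)
    f <- (0:(n - 1)) * fs / n
    f[f > fs / 2] <- fs - f[f > fs / 2]
    H <- pmax(f, 1)^(-cfg$one_over_f_exponent / 2)
    for (ch in seq_len(cfg$n_channels)) {
      w <- rnorm(n)
      x <- Re(fft(fft(w) * H, inverse = TRUE)) / n
      out[, ch] <- x / sd(x) * cfg$broadband_sd_uv
    }
    out
  })
  t <- (0:(n - 1)) / fs
  scale <- schedule_scale(theta_schedule, t)
  base_theta <- sin(2 * pi * cfg$theta_frequency_hz * t) * scale *
    cfg$theta_amplitude_uv
  theta <- outer(base_theta, gains)
  rec <- recording(noise + theta, fs,
                   channel_groups = default_groups(cfg$n_channels))
  list(recording = rec,
       truth = list(noise = noise, theta = theta, schedule = theta_schedule,
                    gains = gains))
}

# per-pulse depression factors for a train
depression_factors <- function(cfg, onsets) {
  n <- length(onsets)
  r <- numeric(n)
  cur <- 1
  last <- -Inf
  for (i in seq_len(n)) {
    if (is.finite(last))
      cur <- 1 - (1 - cur) * exp(-(onsets[i] - last) / cfg$recovery_tau_s)
    r[i] <- cur
    cur <- cur * (1 - cfg$release_fraction)
    last <- onsets[i]
  }
  r
}

# unit-peak difference-of-exponentials kernel sampled at fs
evoked_kernel <- function(cfg, fs) {
  tmax <- cfg$decay_tau_s * 8
  t <- seq(0, tmax, by = 1 / fs)
  k <- exp(-t / cfg$decay_tau_s) - exp(-t / cfg$rise_tau_s)
  k / max(k)
}

#' Pulse-evoked LFP component for a stimulus train
#'
#' Each pulse contributes the unit-peak kernel scaled by
#' `gain * intensity * width_ms * r_i`, where `r_i` follows the single-resource
#' depression model; contributions sum linearly. The per-channel traces are
#' the common trace scaled by the channel gains.
#'
#' @param cfg A [subject_config()].
#' @param train A [pulse_train()] (onsets in session time).
#' @param duration_s Length of the output trace, seconds.
#' @param kernel_shape `"biexponential"` (the physiological kernel) or
#'   `"sinusoid"`: the latter replaces the per-pulse kernel with a pure
#'   sinusoid at the train's fundamental frequency spanning the train, which
#'   by construction contains no harmonics -- the control condition showing
#'   that harmonic peaks in the response spectrum arise solely from the
#'   kernel's non-sinusoidal shape.
#' @return List: `trace` (matrix, samples x channels), `amplitudes` (per-pulse
#'   peak amplitudes, microvolts, ground truth), `kernel` (sampled kernel).
#' @export
evoked_response <- function(cfg, train, duration_s,
                            kernel_shape = c("biexponential", "sinusoid")) {
  kernel_shape <- match.arg(kernel_shape)
  fs <- cfg$sample_rate
  n <- round(duration_s * fs)
  base <- numeric(n)
  amps <- numeric(0)
  k <- evoked_kernel(cfg, fs)
  if (nrow(train) > 0) {
    r <- depression_factors(cfg, train$onset_s)
    amps <- cfg$gain_uv * train$intensity_mw_mm2 * (train$width_s * 1000) * r
    if (kernel_shape == "biexponential") {
      for (p in seq_len(nrow(train))) {
        i0 <- round(train$onset_s[p] * fs) + 1
        ii <- i0:min(i0 + length(k) - 1, n)
        if (ii[1] > n) next
        base[ii] <- base[ii] + amps[p] * k[seq_along(ii)]
      }
    } else {
      f0 <- if (nrow(train) > 1) 1 / median(diff(train$onset_s)) else
        cfg$theta_frequency_hz
      t_first <- train$onset_s[1]
      t_last <- train$onset_s[nrow(train)] + 1 / f0
      i0 <- max(1, round(t_first * fs) + 1)
      i1 <- min(n, round(t_last * fs))
      t <- ((i0:i1) - 1) / fs
      base[i0:i1] <- mean(amps) * sin(2 * pi * f0 * (t - t_first))
    }
  }
  list(trace = outer(base, channel_gains(cfg)), amplitudes = amps, kernel = k)
}

#' Stimulation-artifact component for a stimulus train
#'
#' A positive decaying exponential at each pulse onset and a mirrored negative
#' one at the offset, with amplitude proportional to pulse intensity --
#' the charge/discharge edge transients seen on electrodes near the fiber.
#' The artifact is common-mode (identical across channels).
#'
#' @param cfg A [subject_config()].
#' @param train A [pulse_train()].
#' @param duration_s Output length, seconds.
#' @return List: `trace` (matrix, samples x channels), `edge_kernel`.
#' @export
inject_artifact <- function(cfg, train, duration_s) {
  fs <- cfg$sample_rate
  n <- round(duration_s * fs)
  tker <- seq(0, cfg$edge_tau_s * 8, by = 1 / fs)
  ker <- exp(-tker / cfg$edge_tau_s)
  base <- numeric(n)
  if (nrow(train) > 0) {
    a <- cfg$edge_amplitude_uv_per_mw_mm2 * train$intensity_mw_mm2
    add_edge <- function(base, t_edge, amp) {
      i0 <- round(t_edge * fs) + 1
      if (i0 > n) return(base)
      ii <- i0:min(i0 + length(ker) - 1, n)
      base[ii] <- base[ii] + amp * ker[seq_along(ii)]
      base
    }
    for (p in seq_len(nrow(train))) {
      base <- add_edge(base, train$onset_s[p], a[p])
      base <- add_edge(base, train$onset_s[p] + train$width_s[p], -a[p])
    }
  }
  list(trace = matrix(base, n, cfg$n_channels), edge_kernel = ker)
}

# stereotyped biphasic spike waveform sampled at fs (about 1.6 ms)
spike_waveform <- function(fs, amp_uv = 120, shape = 1) {
  t <- seq(0, 0.0016, by = 1 / fs)
  if (shape == 1)
    w <- -exp(-((t - 4e-4) / 1.2e-4)^2) + 0.45 * exp(-((t - 8e-4) / 2.5e-4)^2)
  else
    w <- -exp(-((t - 5e-4) / 1.8e-4)^2) + 0.3 * exp(-((t - 10e-4) / 3.5e-4)^2)
  amp_uv * w / max(abs(w))
}

#' Simulate stimulus-modulated spiking
#'
#' Each unit fires as an inhomogeneous Poisson process with rate
#' `baseline * (1 + stim_gain)` inside stimulation epochs (and, in sustained
#' mode, ever after the first stimulation onset), thinned by an absolute
#' refractory period. Stereotyped biphasic waveforms are inserted into a
#' wideband contribution matrix on each unit's home channel.
#'
#' @param cfg A [subject_config()] (use a wideband `sample_rate` if the
#'   waveform contribution matters).
#' @param stim_epochs Two-column matrix of stimulation epoch start/end, s.
#' @param duration_s Session duration, seconds.
#' @param units Data frame with columns `channel` and `shape` (1 or 2), one
#'   row per unit; default two units on channels 1 and 2.
#' @param seed Seed (defaults to config seed).
#' @return List: `spike_times` (list per unit), `trace` (samples x channels
#'   waveform contribution), `rate_fun` (the rate function used).
#' @export
simulate_spikes <- function(cfg, stim_epochs, duration_s,
                            units = data.frame(channel = c(1, 2), shape = c(1, 2)),
                            seed = cfg$seed) {
  fs <- cfg$sample_rate
  stim_epochs <- if (is.null(stim_epochs) || length(stim_epochs) == 0)
    matrix(numeric(0), 0, 2) else as.matrix(stim_epochs)
  elevated <- function(t) {
    if (nrow(stim_epochs) == 0) return(rep(FALSE, length(t)))
    if (cfg$sustained_spiking) return(t >= min(stim_epochs[, 1]))
    res <- rep(FALSE, length(t))
    for (r in seq_len(nrow(stim_epochs)))
      res <- res | (t >= stim_epochs[r, 1] & t <= stim_epochs[r, 2])
    res
  }
  rate_fun <- function(t) cfg$baseline_rate_hz * (1 + cfg$stim_gain * elevated(t))
  rmax <- cfg$baseline_rate_hz * (1 + max(0, cfg$stim_gain))
  n <- round(duration_s * fs)
  trace <- matrix(0, n, cfg$n_channels)
  spike_times <- vector("list", nrow(units))
  names(spike_times) <- paste0("unit", seq_len(nrow(units)))
  for (u in seq_len(nrow(units))) {
    cand <- with_seed(seed + 200L + u, {
      m <- rpois(1, rmax * duration_s * 1.1 + 10)
      tt <- sort(runif(m, 0, duration_s))
      keep <- runif(m) < rate_fun(tt) / rmax
      tt[keep]
    })
    # absolute refractory thinning
    if (length(cand) > 1) {
      acc <- cand[1]
      for (tt in cand[-1]) if (tt - acc[length(acc)] >= cfg$refractory_s)
        acc <- c(acc, tt)
      cand <- acc
    }
    spike_times[[u]] <- cand
    if (fs >= 10000 && length(cand) > 0) {
      w <- spike_waveform(fs, shape = units$shape[u])
      ch <- units$channel[u]
      for (tt in cand) {
        i0 <- round(tt * fs) + 1
        ii <- i0:min(i0 + length(w) - 1, n)
        if (ii[1] > n) next
        trace[ii, ch] <- trace[ii, ch] + w[seq_along(ii)]
      }
    }
  }
  list(spike_times = spike_times, trace = trace, rate_fun = rate_fun)
}

#' Compose a full simulated session from a stimulation protocol
#'
#' Sums background, evoked, artifact and (for wideband rates) spike-waveform
#' components along the trial timeline of a [assemble_protocol()] result. The
#' decomposition is exact by construction and returned as ground truth, which
#' is what makes the simulator usable as an oracle for artifact subtraction
#' and peristimulus recovery.
#'
#' @param cfg A [subject_config()].
#' @param protocol A `stim_protocol` from [assemble_protocol()].
#' @param theta_schedule Optional theta amplitude schedule (see
#'   [simulate_background()]).
#' @param include_spikes Insert spiking (default: only at wideband rates).
#' @param kernel_shape Passed to [evoked_response()].
#' @return List: `recording` and `truth` (components `noise`, `theta`,
#'   `evoked`, `artifact`, `spikes` plus `trains`, `stim_epochs`,
#'   `spike_times`, `evoked_amplitudes`).
#' @export
compose_session <- function(cfg, protocol, theta_schedule = NULL,
                            include_spikes = cfg$sample_rate >= 10000,
                            kernel_shape = "biexponential") {
  stopifnot(inherits(protocol, "stim_protocol"))
  trial <- attr(protocol, "trial")
  duration <- length(protocol) * (trial$pre + trial$stim + trial$post)
  bg <- simulate_background(cfg, duration, theta_schedule)
  n <- nrow(bg$recording$samples)
  evoked <- matrix(0, n, cfg$n_channels)
  artif <- matrix(0, n, cfg$n_channels)
  amps <- list()
  trains <- list()
  stim_epochs <- matrix(numeric(0), 0, 2)
  for (tr in protocol) {
    stim_epochs <- rbind(stim_epochs, tr$epoch_stim)
    if (is.null(tr$train) || nrow(tr$train) == 0) next
    trains[[length(trains) + 1L]] <- tr$train
    ev <- evoked_response(cfg, tr$train, duration, kernel_shape = kernel_shape)
    ar <- inject_artifact(cfg, tr$train, duration)
    evoked <- evoked + ev$trace
    artif <- artif + ar$trace
    amps[[length(amps) + 1L]] <- ev$amplitudes
  }
  spikes <- NULL
  spk_trace <- 0
  if (include_spikes) {
    spikes <- simulate_spikes(cfg, stim_epochs, duration)
    spk_trace <- spikes$trace
  }
  samples <- bg$truth$noise + bg$truth$theta + evoked + artif + spk_trace
  rec <- recording(samples, cfg$sample_rate,
                   channel_groups = default_groups(cfg$n_channels))
  list(recording = rec,
       truth = list(noise = bg$truth$noise, theta = bg$truth$theta,
                    evoked = evoked, artifact = artif,
                    spikes = if (include_spikes) spikes$trace else NULL,
                    trains = trains, stim_epochs = stim_epochs,
                    spike_times = if (include_spikes) spikes$spike_times else NULL,
                    evoked_amplitudes = amps, gains = bg$truth$gains))
}
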