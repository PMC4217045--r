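#' Closed-loop controller configuration
#'
#' Parameters of the theta-power-triggered stimulation controller. The
#' controller slides a monitoring window over the multichannel LFP stream,
#' computes the normalized theta-band (6--10 Hz) power fraction per channel,
#' and when the fraction drops below `threshold_fraction` (default 3.4%) on at
#' least `min_channels` channels (default 4) schedules a predefined
#' stimulation train (default 35 Hz, 10 ms pulses at 50 mW/mm^2 for 30 s).
#' While a train is playing, further detections are logged but suppressed
#' (lockout); detection re-arms immediately after the train unless a
#' refractory period is configured.
#'
#' The monitoring window defaults to 1 s stepping 0.5 s: long enough to
#' resolve the 6--10 Hz band with a time-bandwidth-2 multitaper estimate,
#' short enough for responsive control (a 4 s window as used for offline
#' spectrograms would react sluggishly). The normalization denominator is the
#' power integral over 1 Hz..Nyquist, matching the LFP band's lower edge.
#' `output_latency` models the measured command-path latency (mean 46.9 ms);
#' optional Gaussian jitter (`latency_sd`, e.g. 3.1 ms) is available for
#' realism studies.
#'
#' @param theta_band Control band, Hz.
#' @param threshold_fraction Normalized power threshold (0..1), default 0.034.
#' @param min_channels Channels that must drop below threshold, default 4.
#' @param train A [pattern_spec()] for the emitted train.
#' @param train_duration_s Train duration, seconds (default 30).
#' @param monitor_window_s,monitor_step_s Sliding-window geometry, seconds.
#' @param monitor_W_hz Multitaper half-bandwidth for the monitor, Hz.
#' @param output_latency_s Trigger-to-first-sample latency, seconds.
#' @param latency_sd_s SD of optional Gaussian latency jitter (0 = fixed).
#' @param rearm `"immediate"` or a refractory duration in seconds.
#' @param total_band Normalization band, Hz; `NULL` means 1 Hz..Nyquist.
#' @param seed Seed for latency jitter.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(theta_band = c(6, 10), threshold_fraction = 0.034,
                              min_channels = 4,
                              train = pattern_spec("fixed", 50, 35, 0.010),
                              train_duration_s = 30,
                              monitor_window_s = 1, monitor_step_s = 0.5,
                              monitor_W_hz = 2,
                              output_latency_s = 0.0469, latency_sd_s = 0,
                              rearm = "immediate", total_band = NULL,
                              seed = 1L) {
  chk_num(threshold_fraction, "threshold_fraction")
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    op_stop("threshold_fraction must be in (0, 1)", "optephys_parameter_error")
  chk_num(min_channels, "min_channels", lower = 1)
  chk_num(train_duration_s, "train_duration_s")
  if (train_duration_s <= 0)
    op_stop("train_duration_s must be > 0", "optephys_parameter_error")
  refractory <- if (identical(rearm, "immediate")) 0 else chk_num(rearm, "rearm", lower = 0)
  structure(list(theta_band = theta_band,
                 threshold_fraction = threshold_fraction,
                 min_channels = as.integer(min_channels), train = train,
                 train_duration_s = train_duration_s,
                 monitor_window_s = monitor_window_s,
                 monitor_step_s = monitor_step_s,
                 monitor_W_hz = monitor_W_hz,
                 output_latency_s = output_latency_s,
                 latency_sd_s = latency_sd_s,
                 refractory_s = refractory, total_band = total_band,
                 seed = as.integer(seed)),
            class = "controller_config")
}

#' Per-window, per-channel normalized theta power
#'
#' Slides the controller's monitoring window over the LFP stream and computes
#' [band_power_fraction()] in the theta band for every channel. A
#' constant-zero window has undefined normalized power and is reported as 0
#' with a warning.
#'
#' @param rec An LFP-rate [recording()].
#' @param cfg A [controller_config()].
#' @return A list: `window_start_s`, `window_end_s` (vectors) and `fractions`
#'   (matrix, windows x channels).
#' @export
theta_monitor <- function(rec, cfg) {
  stopifnot(inherits(rec, "recording"), inherits(cfg, "controller_config"))
  fs <- rec$sample_rate
  N <- round(cfg$monitor_window_s * fs)
  if (N > nrow(rec$samples))
    op_stop("monitoring window longer than the stream", "optephys_length_error")
  step_n <- round(cfg$monitor_step_s * fs)
  n_win <- floor((nrow(rec$samples) - N) / step_n) + 1
  params <- multitaper_params(cfg$monitor_window_s, cfg$monitor_W_hz,
                              step_s = cfg$monitor_step_s)
  tapers <- dpss_tapers(params, fs)
  total_band <- if (is.null(cfg$total_band)) c(1, fs / 2) else cfg$total_band
  fr <- matrix(0, n_win, ncol(rec$samples))
  zero_warned <- FALSE
  for (wi in seq_len(n_win)) {
    i0 <- (wi - 1) * step_n + 1
    for (ch in seq_len(ncol(rec$samples))) {
      seg <- rec$samples[i0:(i0 + N - 1), ch]
      if (all(seg == 0)) {
        if (!zero_warned) {
          warning("constant-zero window(s): theta fraction reported as 0")
          zero_warned <- TRUE
        }
        fr[wi, ch] <- 0
      } else {
        fr[wi, ch] <- suppressWarnings(
          band_power_fraction(seg, cfg$theta_band, fs, params = params,
                              total_band = total_band, tapers = tapers)$fraction)
      }
    }
  }
  starts <- rec$t0 + ((seq_len(n_win) - 1) * step_n) / fs
  list(window_start_s = starts, window_end_s = starts + cfg$monitor_window_s,
       fractions = fr)
}

#' Trigger decision for one monitoring window
#'
#' `TRUE` iff at least `min_channels` channels have normalized theta power
#' strictly below the threshold. Monotone: lowering any channel's fraction
#' can never turn a detection off.
#'
#' @param fractions Numeric vector, one normalized theta fraction per channel.
#' @param cfg A [controller_config()].
#' @return Logical scalar.
#' @export
theta_detect <- function(fractions, cfg) {
  sum(fractions < cfg$threshold_fraction) >= cfg$min_channels
}

#' Run the closed-loop controller over a recorded stream
#'
#' Iterates monitoring windows in time order. On a detection outside lockout,
#' a train (`cfg$train`, realized over `cfg$train_duration_s`) is scheduled to
#' start at the triggering window's end plus the output latency; the lockout
#' spans the train (plus any refractory), during which further detections are
#' logged as suppressed.
#'
#' The controller is a pure function of the stream, the configuration and the
#' configuration seed: identical inputs give identical logs.
#'
#' @param rec An LFP-rate [recording()].
#' @param cfg A [controller_config()].
#' @return An object of class `trigger_log`: list with `windows` (data frame:
#'   `window_start_s`, `window_end_s`, `n_below`, `triggered`,
#'   `suppressed_by_lockout`), `fractions` (windows x channels), and `trains`
#'   (list of [pulse_train()]s in stream time).
#' @export
run_controller <- function(rec, cfg) {
  mon <- theta_monitor(rec, cfg)
  n_win <- length(mon$window_start_s)
  n_below <- rowSums(mon$fractions < cfg$threshold_fraction)
  detected <- n_below >= cfg$min_channels
  triggered <- logical(n_win)
  suppressed <- logical(n_win)
  trains <- list()
  lockout_until <- -Inf
  lat_jit <- if (cfg$latency_sd_s > 0)
    with_seed(cfg$seed, rnorm(n_win, 0, cfg$latency_sd_s)) else numeric(n_win)
  for (wi in seq_len(n_win)) {
    if (!detected[wi]) next
    t_end <- mon$window_end_s[wi]
    if (t_end < lockout_until) {
      suppressed[wi] <- TRUE
      next
    }
    triggered[wi] <- TRUE
    t_start <- t_end + cfg$output_latency_s + lat_jit[wi]
    epoch <- c(t_start, t_start + cfg$train_duration_s)
    trains[[length(trains) + 1L]] <- realize_pattern(cfg$train, epoch)
    lockout_until <- epoch[2] + cfg$refractory_s
  }
  # invariant: emitted trains never overlap
  if (length(trains) > 1) {
    eps <- t(vapply(trains, attr, numeric(2), "epoch"))
    stopifnot(all(eps[-1, 1] >= eps[-nrow(eps), 2] - 1e-9))
  }
  structure(list(windows = data.frame(window_start_s = mon$window_start_s,
                                      window_end_s = mon$window_end_s,
                                      n_below = n_below,
                                      triggered = triggered,
                                      suppressed_by_lockout = suppressed),
                 fractions = mon$fractions, trains = trains, config = cfg),
            class = "trigger_log")
}

#' @export
print.trigger_log <- function(x, ...) {
  cat(sprintf("<trigger_log> %d windows, %d trigger(s), %d suppressed detection(s)\n",
              nrow(x$windows), sum(x$windows$triggered),
              sum(x$windows$suppressed_by_lockout)))
  invisible(x)
}

#' Write a trigger log (per-window CSV + emitted-train CSVs)
#' @param log A `trigger_log`.
#' @param path Per-window CSV path; train k is written next to it as
#'   `<path>.train<k>.csv` in the pulse-train format.
#' @return `path`, invisibly.
#' @export
write_trigger_log <- function(log, path) {
  write.csv(log$windows, path, row.names = FALSE)
  for (k in seq_along(log$trains))
    write_pulse_train(log$trains[[k]], sprintf("%s.train%d.csv", path, k))
  invisible(path)
}
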