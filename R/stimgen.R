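#' Symbolic stimulation-pattern specification
#'
#' A `pattern_spec` describes a stimulation pattern before it is realized as a
#' concrete pulse train: the pattern family, the dose (irradiance), the timing
#' parameters and, for stochastic families, the seed. Pattern families:
#'
#' * `"fixed"` -- regular pulses at `frequency` Hz.
#' * `"jittered"` -- interpulse frequency drawn from a truncated normal
#'   centred on `frequency` with hard bounds at +/- `jitter_halfwidth` Hz.
#' * `"poisson"` -- interpulse intervals i.i.d. exponential at rate
#'   `frequency`, with a dead time of one pulse width.
#' * `"burst"` -- `pulses_per_burst` pulses at `intra_burst_frequency` Hz
#'   nested in a cycle repeating at `frequency` Hz (e.g. gamma bursts on a
#'   theta cycle).
#' * `"sinusoid"` -- continuous sinusoidal irradiance at `frequency` Hz,
#'   rendered by [sinusoid_command()] rather than as discrete pulses.
#'
#' @param kind One of `"fixed"`, `"jittered"`, `"poisson"`, `"burst"`,
#'   `"sinusoid"`.
#' @param intensity_mw_mm2 Pulse irradiance, mW/mm^2.
#' @param frequency_hz Pulse rate / centre frequency / burst-cycle rate, Hz.
#' @param pulse_width_s Pulse width, seconds (ignored for `"sinusoid"`).
#' @param jitter_halfwidth_hz Hard half-width of the frequency jitter, Hz
#'   (jittered only).
#' @param jitter_sd_hz Standard deviation of the jitter distribution before
#'   truncation; defaults to `jitter_halfwidth_hz / 2`.
#' @param pulses_per_burst,intra_burst_frequency_hz Burst geometry (burst only).
#' @param seed Integer seed for stochastic families.
#' @return An object of class `pattern_spec`.
#' @examples
#' pattern_spec("burst", 50, 7, 0.010, pulses_per_burst = 4,
#'              intra_burst_frequency_hz = 42)
#' @export
pattern_spec <- function(kind = c("fixed", "jittered", "poisson", "burst", "sinusoid"),
                         intensity_mw_mm2 = 50, frequency_hz = 7,
                         pulse_width_s = 0.010,
                         jitter_halfwidth_hz = NULL, jitter_sd_hz = NULL,
                         pulses_per_burst = NULL, intra_burst_frequency_hz = NULL,
                         seed = 1L) {
  kind <- match.arg(kind)
  chk_num(intensity_mw_mm2, "intensity_mw_mm2", lower = 0)
  chk_num(frequency_hz, "frequency_hz")
  if (frequency_hz < 0)
    op_stop("frequency must be >= 0", "optephys_parameter_error")
  if (kind != "sinusoid") {
    chk_num(pulse_width_s, "pulse_width_s")
    if (pulse_width_s <= 0)
      op_stop("pulse width must be > 0", "optephys_parameter_error")
  }
  if (kind %in% c("fixed", "jittered") && frequency_hz > 0 &&
      pulse_width_s >= 1 / frequency_hz)
    op_stop("pulse width must be shorter than the interpulse period",
            "optephys_duty_cycle_error")
  if (kind == "poisson" && frequency_hz * pulse_width_s >= 1)
    op_stop("rate x pulse width >= 1: dead-time-corrected train is infeasible",
            "optephys_duty_cycle_error")
  if (kind == "jittered") {
    chk_num(jitter_halfwidth_hz, "jitter_halfwidth_hz", lower = 0)
    if (jitter_halfwidth_hz >= frequency_hz)
      op_stop("jitter halfwidth must be smaller than the centre frequency",
              "optephys_jitter_error")
    if (is.null(jitter_sd_hz)) jitter_sd_hz <- jitter_halfwidth_hz / 2
    # worst-case (highest-frequency) interval must still fit the pulse
    if (pulse_width_s >= 1 / (frequency_hz + jitter_halfwidth_hz))
      op_stop("pulse width exceeds the shortest jittered period",
              "optephys_duty_cycle_error")
  }
  if (kind == "burst") {
    chk_num(pulses_per_burst, "pulses_per_burst", lower = 1)
    chk_num(intra_burst_frequency_hz, "intra_burst_frequency_hz")
    span <- (pulses_per_burst - 1) / intra_burst_frequency_hz + pulse_width_s
    if (frequency_hz > 0 && span >= 1 / frequency_hz)
      op_stop(sprintf(
        "burst span (%.4g s) does not fit inside the %.4g s burst cycle",
        span, 1 / frequency_hz), "optephys_nesting_error")
  }
  structure(list(kind = kind, intensity_mw_mm2 = intensity_mw_mm2,
                 frequency_hz = frequency_hz, pulse_width_s = pulse_width_s,
                 jitter_halfwidth_hz = jitter_halfwidth_hz,
                 jitter_sd_hz = jitter_sd_hz,
                 pulses_per_burst = pulses_per_burst,
                 intra_burst_frequency_hz = intra_burst_frequency_hz,
                 seed = as.integer(seed)),
            class = "pattern_spec")
}

#' Construct (and validate) a realized pulse train
#'
#' @param onsets Pulse onset times, seconds, strictly increasing.
#' @param widths Pulse widths, seconds (scalar or per pulse).
#' @param intensities Pulse irradiances, mW/mm^2 (scalar or per pulse).
#' @param epoch Two-element numeric `[t_start, t_end]`, seconds.
#' @return An object of class `pulse_train` (a data frame with columns
#'   `onset_s`, `width_s`, `intensity_mw_mm2` and an `epoch` attribute).
#' @export
pulse_train <- function(onsets, widths, intensities, epoch) {
  n <- length(onsets)
  widths <- rep_len(widths, n)
  intensities <- rep_len(intensities, n)
  if (n > 0) {
    if (is.unsorted(onsets, strictly = TRUE))
      op_stop("pulse onsets must be strictly increasing", "optephys_train_error")
    if (any(onsets < epoch[1] - 1e-12) || any(onsets + widths > epoch[2] + 1e-12))
      op_stop("pulses must lie inside the epoch", "optephys_train_error")
    if (n > 1 && any(onsets[-1] - (onsets[-n] + widths[-n]) < -1e-12))
      op_stop("pulses overlap", "optephys_train_error")
  }
  structure(data.frame(onset_s = as.numeric(onsets),
                       width_s = as.numeric(widths),
                       intensity_mw_mm2 = as.numeric(intensities)),
            epoch = as.numeric(epoch),
            class = c("pulse_train", "data.frame"))
}

#' @export
print.pulse_train <- function(x, ...) {
  ep <- attr(x, "epoch")
  cat(sprintf("<pulse_train> %d pulses in [%.3f, %.3f] s\n", nrow(x), ep[1], ep[2]))
  if (nrow(x) > 0) print.data.frame(head(x, 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

# command-voltage map used by the renderers: inverts the calibration line but
# floors at 0 V (LED off) for irradiances below the calibrated minimum, since
# "off" is always attainable; targets above the calibrated maximum still error.
command_voltage <- function(irr, curve) {
  if (curve$slope <= 0)
    op_stop("calibration slope not positive: cannot invert", "optephys_config_error")
  hi <- irradiance_at_voltage(curve$v_max, curve)
  if (any(irr > hi + 1e-9))
    op_stop("pulse irradiance above calibrated maximum", "optephys_range_error")
  pmax(0, (irr - curve$intercept) / curve$slope)
}

# run expr with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Regular (fixed-frequency) pulse train
#'
#' Pulses at `epoch[1] + k / frequency` for k = 0, 1, ... while the whole
#' pulse fits in the epoch.
#'
#' @param spec A [pattern_spec()] with `kind = "fixed"` (other kinds with a
#'   defined rate are accepted and treated as fixed at that rate).
#' @param epoch Two-element `[t_start, t_end]`, seconds.
#' @return A [pulse_train()].
#' @examples
#' tr <- fixed_train(pattern_spec("fixed", 50, 7, 0.010), c(0, 20))
#' nrow(tr)  # 140
#' @export
fixed_train <- function(spec, epoch) {
  f <- spec$frequency_hz; w <- spec$pulse_width_s
  if (f <= 0 || diff(epoch) <= 0)
    return(pulse_train(numeric(0), numeric(0), numeric(0), epoch))
  if (w >= 1 / f)
    op_stop("pulse width >= period", "optephys_duty_cycle_error")
  kmax <- floor((diff(epoch) - w) * f + 1e-9)
  onsets <- epoch[1] + (0:kmax) / f
  pulse_train(onsets, w, spec$intensity_mw_mm2, epoch)
}

# one truncated-normal frequency draw per pulse, by rejection
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0 || hi == lo) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Frequency-jittered pulse train
#'
#' Each interpulse interval is `1 / f_i` with `f_i` drawn from a normal
#' distribution centred on the pattern frequency, truncated to
#' `centre +/- jitter_halfwidth`. Jitter is applied in the frequency domain and
#' then inverted to an interval, so the stated +/- bound holds exactly on the
#' instantaneous frequency. With zero halfwidth the result degenerates to
#' [fixed_train()].
#'
#' @inheritParams fixed_train
#' @return A [pulse_train()].
#' @export
jittered_train <- function(spec, epoch) {
  if (spec$kind != "jittered")
    op_stop("spec$kind must be 'jittered'", "optephys_parameter_error")
  hw <- spec$jitter_halfwidth_hz
  if (is.null(hw) || hw == 0) {
    tr <- fixed_train(spec, epoch)
    return(tr)
  }
  f0 <- spec$frequency_hz; w <- spec$pulse_width_s
  with_seed(spec$seed, {
    onsets <- numeric(0)
    t <- epoch[1]
    repeat {
      if (t + w > epoch[2] + 1e-12) break
      onsets <- c(onsets, t)
      fi <- rtruncnorm1(1, f0, spec$jitter_sd_hz, f0 - hw, f0 + hw)
      t <- t + 1 / fi
    }
    pulse_train(onsets, w, spec$intensity_mw_mm2, epoch)
  })
}

#' Poisson pulse train with pulse-width dead time
#'
#' Interpulse intervals are i.i.d. exponential at the pattern rate; an
#' interval shorter than the pulse width (which would make light pulses
#' overlap) is redrawn. Redrawing, rather than shifting, keeps accepted
#' intervals memoryless. With dead time w the realized rate is
#' `lambda / (1 + lambda * w)`.
#'
#' @inheritParams fixed_train
#' @param dead_time If `FALSE`, overlapping intervals are *not* redrawn and
#'   the nominal rate is realized; overlapping pulses are merged away by
#'   dropping the offender (not the default).
#' @return A [pulse_train()].
#' @export
poisson_train <- function(spec, epoch, dead_time = TRUE) {
  f <- spec$frequency_hz; w <- spec$pulse_width_s
  if (f <= 0 || diff(epoch) <= 0)
    return(pulse_train(numeric(0), numeric(0), numeric(0), epoch))
  with_seed(spec$seed, {
    onsets <- numeric(0)
    t <- epoch[1] + rexp(1, f)
    repeat {
      if (t + w > epoch[2] + 1e-12) break
      onsets <- c(onsets, t)
      repeat {
        gap <- rexp(1, f)
        if (!dead_time || gap >= w) break
      }
      t <- t + gap
    }
    if (!dead_time && length(onsets) > 1) {
      keep <- c(TRUE, diff(onsets) >= w)
      onsets <- onsets[keep]
    }
    pulse_train(onsets, w, spec$intensity_mw_mm2, epoch)
  })
}

#' Nested-burst (cross-frequency) pulse train
#'
#' Burst onsets repeat at the cycle frequency; within each burst,
#' `pulses_per_burst` pulses are spaced at the intra-burst frequency (e.g.
#' four 42 Hz pulses per 7 Hz cycle to emulate theta-nested gamma).
#'
#' @inheritParams fixed_train
#' @return A [pulse_train()].
#' @export
burst_train <- function(spec, epoch) {
  if (spec$kind != "burst")
    op_stop("spec$kind must be 'burst'", "optephys_parameter_error")
  f <- spec$frequency_hz; w <- spec$pulse_width_s
  npb <- spec$pulses_per_burst; fi <- spec$intra_burst_frequency_hz
  span <- (npb - 1) / fi + w
  if (f > 0 && span >= 1 / f)
    op_stop("burst span >= burst cycle", "optephys_nesting_error")
  if (f <= 0 || diff(epoch) <= 0)
    return(pulse_train(numeric(0), numeric(0), numeric(0), epoch))
  kmax <- floor((diff(epoch) - span) * f + 1e-9)
  if (kmax < 0)
    return(pulse_train(numeric(0), numeric(0), numeric(0), epoch))
  burst_starts <- epoch[1] + (0:kmax) / f
  onsets <- as.vector(outer((0:(npb - 1)) / fi, burst_starts, "+"))
  pulse_train(sort(onsets), w, spec$intensity_mw_mm2, epoch)
}

#' Dispatch a pattern_spec to its generator
#' @inheritParams fixed_train
#' @return A [pulse_train()]; errors for `kind = "sinusoid"` (use
#'   [sinusoid_command()]).
#' @export
realize_pattern <- function(spec, epoch) {
  switch(spec$kind,
         fixed = fixed_train(spec, epoch),
         jittered = jittered_train(spec, epoch),
         poisson = poisson_train(spec, epoch),
         burst = burst_train(spec, epoch),
         sinusoid = op_stop("sinusoid patterns are rendered with sinusoid_command()",
                            "optephys_parameter_error"))
}

#' Continuous sinusoidal analog command
#'
#' Renders irradiance `I(t) = (I_max / 2) * (1 - cos(2 pi f t))` over the
#' stimulation epoch -- non-negative, starting from zero irradiance at the
#' epoch start -- and maps it to command volts through a calibration curve.
#'
#' @param spec A [pattern_spec()] with `kind = "sinusoid"`.
#' @param epoch Two-element `[t_start, t_end]`, seconds.
#' @param curve A [fit_calibration()] result.
#' @param sample_rate Command sample rate, Hz; must be at least 10x the
#'   sinusoid frequency.
#' @return An `analog_command`: list of `samples` (volts), `sample_rate`, `t0`.
#' @export
sinusoid_command <- function(spec, epoch, curve, sample_rate = 10000) {
  if (spec$kind != "sinusoid")
    op_stop("spec$kind must be 'sinusoid'", "optephys_parameter_error")
  if (sample_rate < 10 * spec$frequency_hz)
    op_stop("sample rate below 10x the sinusoid frequency", "optephys_undersampling_error")
  n <- round(diff(epoch) * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  irr <- (spec$intensity_mw_mm2 / 2) * (1 - cos(2 * pi * spec$frequency_hz * t))
  v <- command_voltage(irr, curve)
  structure(list(samples = v, sample_rate = sample_rate, t0 = epoch[1],
                 units = "V"),
            class = "analog_command")
}

#' Render a pulse train as an analog command waveform
#'
#' Square pulses at the voltage that delivers each pulse's irradiance, on a 0 V
#' (LED off) baseline. Pulse edges snap to the nearest command sample; with the
#' default 10 kHz command rate a 2 ms pulse spans 20 samples.
#'
#' @param train A [pulse_train()].
#' @param curve A [fit_calibration()] result.
#' @param sample_rate Command sample rate, Hz.
#' @return An `analog_command` spanning the train's epoch.
#' @export
render_command <- function(train, curve, sample_rate = 10000) {
  stopifnot(inherits(train, "pulse_train"))
  epoch <- attr(train, "epoch")
  n <- round(diff(epoch) * sample_rate)
  v <- numeric(n)
  if (nrow(train) > 0) {
    amps <- command_voltage(train$intensity_mw_mm2, curve)
    i0 <- round((train$onset_s - epoch[1]) * sample_rate) + 1
    i1 <- i0 + round(train$width_s * sample_rate) - 1
    for (p in seq_len(nrow(train))) {
      ii <- i0[p]:min(i1[p], n)
      v[ii] <- amps[p]
    }
  }
  structure(list(samples = v, sample_rate = sample_rate, t0 = epoch[1],
                 units = "V"),
            class = "analog_command")
}

#' Trial protocol: background / stimulation / background
#'
#' The standard trial is 20 s of background, 20 s of stimulation and 20 s of
#' additional background (one minute per trial).
#'
#' @param pre,stim,post Epoch durations in seconds.
#' @param order_seed Seed for the random ordering of patterns across trials.
#' @return An object of class `trial_protocol`.
#' @export
trial_protocol <- function(pre = 20, stim = 20, post = 20, order_seed = 1L) {
  if (any(c(pre, stim, post) < 0))
    op_stop("durations must be >= 0", "optephys_parameter_error")
  structure(list(pre = pre, stim = stim, post = post,
                 order_seed = as.integer(order_seed)),
            class = "trial_protocol")
}

#' Assemble a randomized multi-trial stimulation protocol
#'
#' Each pattern is realized inside its trial's stimulation epoch; trials are
#' ordered by a seeded permutation of the supplied patterns and concatenated
#' back-to-back, so trial k occupies
#' `[(k-1) * total, k * total]` with the stimulation epoch at
#' `[(k-1) * total + pre, (k-1) * total + pre + stim]`.
#'
#' @param patterns List of [pattern_spec()] objects (sinusoid patterns are
#'   carried symbolically; pulse patterns are realized).
#' @param trial A [trial_protocol()].
#' @return A list of class `stim_protocol`: one element per trial with fields
#'   `trial_id`, `pattern`, `train` (a [pulse_train()] in absolute session
#'   time, `NULL` for sinusoid patterns), `epoch_pre`, `epoch_stim`,
#'   `epoch_post`.
#' @export
assemble_protocol <- function(patterns, trial = trial_protocol()) {
  stopifnot(inherits(trial, "trial_protocol"))
  total <- trial$pre + trial$stim + trial$post
  ord <- with_seed(trial$order_seed, sample(seq_along(patterns)))
  out <- vector("list", length(patterns))
  for (k in seq_along(ord)) {
    sp <- patterns[[ord[k]]]
    t0 <- (k - 1) * total
    stim_epoch <- c(t0 + trial$pre, t0 + trial$pre + trial$stim)
    tr <- if (sp$kind == "sinusoid") NULL else realize_pattern(sp, stim_epoch)
    out[[k]] <- list(trial_id = k, pattern = sp, train = tr,
                     epoch_pre = c(t0, stim_epoch[1]),
                     epoch_stim = stim_epoch,
                     epoch_post = c(stim_epoch[2], t0 + total))
  }
  structure(out, trial = trial, class = "stim_protocol")
}

#' Write / read a pulse train as CSV (`onset_s,width_s,intensity_mw_mm2`)
#' @param train A [pulse_train()].
#' @param path File path.
#' @param epoch Epoch to attach when reading (defaults to the data range).
#' @return `path` invisibly (write); a [pulse_train()] (read).
#' @export
write_pulse_train <- function(train, path) {
  write.csv(as.data.frame(train), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pulse_train
#' @export
read_pulse_train <- function(path, epoch = NULL) {
  df <- read.csv(path)
  if (is.null(epoch)) {
    epoch <- if (nrow(df) > 0)
      c(min(df$onset_s), max(df$onset_s + df$width_s)) else c(0, 0)
  }
  pulse_train(df$onset_s, df$width_s, df$intensity_mw_mm2, epoch)
}

#' Write an analog command as float32 binary plus JSON sidecar
#' @param cmd An `analog_command`.
#' @param path Binary output path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_analog_command <- function(cmd, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(cmd$samples), con, size = 4, endian = "little")
  jsonlite::write_json(list(sample_rate = cmd$sample_rate, t0 = cmd$t0,
                            units = cmd$units, n_samples = length(cmd$samples)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
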