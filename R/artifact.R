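#' Estimate a stimulation-artifact template
#'
#' Stimulus-locked optical/electrical artifacts appear as charge/discharge
#' transients at pulse onset and offset. Their waveform is stereotyped at a
#' given intensity while the amplitude scales with intensity, so templates are
#' estimated per intensity level by peristimulus averaging of a recording from
#' tissue assumed response-free (e.g. non-expressing cortex). The key
#' assumption -- that the artifact is identical at the response-free and
#' target sites -- is an experimental-design assumption the code documents but
#' cannot validate.
#'
#' @param x Numeric vector or [recording()] from the response-free site.
#' @param events Pulse onset times, seconds.
#' @param intensity_mw_mm2 Intensity level of these pulses.
#' @param sample_rate Sampling rate, Hz (from the recording if given).
#' @param lead_s Template window start before pulse onset, seconds.
#' @param tail_s Template window end after pulse *offset*, seconds.
#' @param pulse_width_s Pulse width (sets the offset position), seconds.
#' @param t0,channel As in [peristimulus_average()].
#' @param min_pulses Minimum number of pulses (default 10).
#' @return An object of class `artifact_template`: data frame `lag_s`,
#'   `mean_uv`, `sd_uv` with attributes `intensity_mw_mm2`, `n_pulses`.
#' @export
estimate_template <- function(x, events, intensity_mw_mm2, sample_rate = NULL,
                              lead_s = 0.002, tail_s = 0.010,
                              pulse_width_s = 0.010, t0 = 0, channel = 1,
                              min_pulses = 10) {
  if (length(events) < min_pulses)
    op_stop(sprintf("need >= %d pulses to estimate a template", min_pulses),
            "optephys_insufficient_data_error")
  psa <- peristimulus_average(x, events, sample_rate,
                              pre_s = lead_s, post_s = pulse_width_s + tail_s,
                              t0 = t0, channel = channel)
  out <- as.data.frame(psa)
  attr(out, "intensity_mw_mm2") <- intensity_mw_mm2
  attr(out, "n_pulses") <- attr(psa, "n_events")
  class(out) <- c("artifact_template", "data.frame")
  out
}

#' Subtract an artifact template at each stimulus time
#'
#' Subtracts the template mean, sample-aligned to each event onset, from the
#' target-site signal. When consecutive pulses are closer than the template
#' window the overlapping contributions subtract additively (a warning is
#' emitted, since overlap means single-pulse templates only approximate the
#' compound artifact).
#'
#' @param x Numeric vector or single-channel [recording()] to clean.
#' @param events Pulse onset times, seconds.
#' @param template An [estimate_template()] result.
#' @param sample_rate,t0,channel As in [peristimulus_average()].
#' @return Cleaned numeric vector (or recording, matching the input type).
#' @export
subtract_template <- function(x, events, template, sample_rate = NULL,
                              t0 = 0, channel = 1) {
  rec_in <- inherits(x, "recording")
  if (rec_in) {
    rec <- x; sample_rate <- rec$sample_rate; t0 <- rec$t0
    x <- rec$samples[, channel]
  }
  if (is.null(sample_rate)) op_stop("sample_rate required", "optephys_parameter_error")
  if (length(events) == 0) {
    return(if (rec_in) rec else x)
  }
  lag_n <- round(template$lag_s * sample_rate)
  win_s <- diff(range(template$lag_s))
  if (length(events) > 1 && min(diff(sort(events))) < win_s)
    warning("template window exceeds inter-event spacing; overlapping templates summed")
  y <- x
  centre <- round((events - t0) * sample_rate) + 1
  for (c0 in centre) {
    ii <- c0 + lag_n
    keep <- ii >= 1 & ii <= length(y)
    y[ii[keep]] <- y[ii[keep]] - template$mean_uv[keep]
  }
  if (rec_in) {
    rec$samples[, channel] <- y
    rec
  } else y
}

#' Flag putative stimulus-locked artifactual units
#'
#' High-pass filtering of the stimulation artifact can masquerade as a single
#' unit. Such false units are (a) detected almost exclusively inside
#' stimulation epochs and (b) tightly locked to the stimulation frequency.
#' Both statistics are computed per unit: the fraction of spikes inside the
#' stimulation epochs, and the vector strength
#' `|mean(exp(2 pi i f t))|` of in-stimulation spike times at the stimulation
#' frequency. A unit is flagged `suspect_artifact` only when *both* exceed
#' their thresholds; the default thresholds (0.99 and 0.8) encode "detected
#' essentially only during stimulation" and "near-perfect locking" and are
#' deliberately conservative.
#'
#' @param spike_times Named list of numeric vectors, spike times per unit (s).
#' @param stim_epochs Two-column matrix (or data frame) of epoch
#'   `[start, end]` times, seconds.
#' @param stim_frequency_hz Stimulation frequency, Hz.
#' @param min_spikes Units with fewer spikes are still scored but flagged with
#'   a warning (statistics unstable below ~20 spikes); zero spikes is an error.
#' @param thresholds Named numeric: `in_stim` and `vector_strength`.
#' @return Data frame of class `unit_flags` with columns `unit_id`,
#'   `n_spikes`, `in_stim_fraction`, `vector_strength`, `verdict`.
#' @export
flag_stimulus_locked_units <- function(spike_times, stim_epochs,
                                       stim_frequency_hz,
                                       min_spikes = 20,
                                       thresholds = c(in_stim = 0.99,
                                                      vector_strength = 0.8)) {
  stim_epochs <- as.matrix(stim_epochs)
  if (is.null(names(spike_times)))
    names(spike_times) <- paste0("unit", seq_along(spike_times))
  in_epoch <- function(t) {
    res <- rep(FALSE, length(t))
    for (r in seq_len(nrow(stim_epochs)))
      res <- res | (t >= stim_epochs[r, 1] & t <= stim_epochs[r, 2])
    res
  }
  rows <- lapply(names(spike_times), function(uid) {
    t <- spike_times[[uid]]
    if (length(t) == 0)
      op_stop(sprintf("unit '%s' has no spikes", uid), "optephys_undefined_unit_error")
    if (length(t) < min_spikes)
      warning(sprintf("unit '%s' has %d < %d spikes; statistics unstable",
                      uid, length(t), min_spikes))
    ins <- in_epoch(t)
    frac <- mean(ins)
    vs <- if (any(ins))
      Mod(mean(exp(2i * pi * stim_frequency_hz * t[ins]))) else 0
    verdict <- if (frac >= thresholds[["in_stim"]] &&
                   vs >= thresholds[["vector_strength"]])
      "suspect_artifact" else "plausible"
    data.frame(unit_id = uid, n_spikes = length(t), in_stim_fraction = frac,
               vector_strength = vs, verdict = verdict)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("unit_flags", "data.frame")
  out
}

#' Write artifact template / unit flags to disk
#' @param template An `artifact_template`.
#' @param path CSV path; a JSON header (`intensity`, `n_pulses`) is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_artifact_template <- function(template, path) {
  write.csv(as.data.frame(template), path, row.names = FALSE)
  jsonlite::write_json(list(intensity_mw_mm2 = attr(template, "intensity_mw_mm2"),
                            n_pulses = attr(template, "n_pulses")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
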