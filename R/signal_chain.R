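#' Butterworth band-pass filter specification
#'
#' @param kind `"lfp_bandpass"` (default band 1--500 Hz, 1 pole, matching the
#'   online LFP chain) or `"spike_bandpass"` (default 500--5000 Hz, 2 poles,
#'   the offline action-potential band).
#' @param band Two-element numeric, Hz.
#' @param order Filter order (poles per band edge).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("lfp_bandpass", "spike_bandpass"),
                        band = NULL, order = NULL) {
  kind <- match.arg(kind)
  if (is.null(band)) band <- if (kind == "lfp_bandpass") c(1, 500) else c(500, 5000)
  if (is.null(order)) order <- if (kind == "lfp_bandpass") 1L else 2L
  if (band[1] <= 0 || band[2] <= band[1])
    op_stop("need 0 < low < high", "optephys_config_error")
  structure(list(kind = kind, band = as.numeric(band), order = as.integer(order),
                 topology = "butterworth"),
            class = "filter_spec")
}

# apply a Butterworth band-pass to every channel; causal by default,
# zero-phase (forward-backward) optionally for offline analysis
apply_bandpass <- function(mat, sample_rate, band, order, zero_phase = FALSE) {
  nyq <- sample_rate / 2
  if (band[2] >= nyq)
    op_stop("band edge at or above Nyquist", "optephys_config_error")
  bf <- signal::butter(order, band / nyq, type = "pass")
  b <- bf$b / bf$a[1]; a <- bf$a / bf$a[1]
  out <- mat
  for (ch in seq_len(ncol(mat))) {
    y <- .iir_filter_cpp(b, a, mat[, ch])
    if (zero_phase) y <- rev(.iir_filter_cpp(b, a, rev(y)))
    out[, ch] <- y
  }
  out
}

# windowed-sinc low-pass taps evaluated at arbitrary lag offsets (in input
# samples); used to evaluate the anti-alias FIR only at output instants
sinc_taps <- function(offsets, cutoff_norm) {
  h <- 2 * cutoff_norm * sinc_fn(2 * cutoff_norm * offsets)
  L <- max(abs(offsets))
  w <- 0.54 + 0.46 * cos(pi * offsets / (L + 1))  # Hamming
  h <- h * w
  h / sum(h)
}
sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Isolate the local field potential stream
#'
#' Mirrors the platform's online LFP chain: a 1-pole Butterworth band-pass at
#' 1--500 Hz followed by downsampling to 2000 Hz. The wideband-to-LFP rate
#' ratio (25 kHz / 2 kHz = 12.5) is non-integer, so resampling is done by
#' evaluating a windowed-sinc anti-alias low-pass (cutoff 800 Hz) directly at
#' the 2 kHz output instants. The 1-pole band-pass alone rolls off far too
#' slowly (~6 dB/octave) to prevent aliasing, hence the guard filter is on by
#' default; `paper_faithful = TRUE` disables it and takes nearest-sample
#' decimation after the 1-pole filter only.
#'
#' @param rec A wideband [recording()] (sample rate at least 1000 Hz).
#' @param target_rate Output rate, Hz (default 2000).
#' @param band,order LFP band and filter order (defaults 1--500 Hz, 1 pole).
#' @param zero_phase Apply the band-pass forward-backward (offline use).
#' @param paper_faithful Disable the anti-alias guard (see above).
#' @param guard_taps Half-width of the windowed-sinc guard, in input samples.
#' @return A [recording()] at exactly `target_rate` Hz.
#' @export
isolate_lfp <- function(rec, target_rate = 2000, band = c(1, 500), order = 1,
                        zero_phase = FALSE, paper_faithful = FALSE,
                        guard_taps = 64) {
  stopifnot(inherits(rec, "recording"))
  if (rec$sample_rate < 2 * band[2])
    op_stop("input rate below twice the LFP band edge", "optephys_config_error")
  n_in <- nrow(rec$samples)
  if (n_in < max(8 * (order + 1), round(0.01 * rec$sample_rate)))
    op_stop("recording shorter than filter warm-up", "optephys_length_error")
  filt <- apply_bandpass(rec$samples, rec$sample_rate, band, order, zero_phase)
  if (rec$sample_rate == target_rate)
    return(recording(filt, target_rate, rec$channel_groups, rec$t0))
  dur <- n_in / rec$sample_rate
  n_out <- floor(dur * target_rate)
  # output instants in input-sample units (0-based position of sample m)
  pos <- (0:(n_out - 1)) * rec$sample_rate / target_rate
  base <- floor(pos)
  frac <- pos - base
  out <- matrix(0, n_out, ncol(filt))
  if (paper_faithful) {
    idx <- pmin(round(pos) + 1L, n_in)
    out <- filt[idx, , drop = FALSE]
  } else {
    cutoff_norm <- 0.4 * target_rate / rec$sample_rate  # 800 Hz at 25 kHz -> 2 kHz
    # group output instants by fractional offset (rational ratio => few phases)
    phase_key <- round(frac, 9)
    for (ph in unique(phase_key)) {
      sel <- which(phase_key == ph)
      offs <- (-guard_taps:guard_taps) + ph
      taps <- sinc_taps(offs, cutoff_norm)
      idx <- as.integer(base[sel] + 1L)
      for (ch in seq_len(ncol(filt)))
        out[sel, ch] <- .fir_at_cpp(filt[, ch], taps, idx, guard_taps + 1L)
    }
  }
  recording(out, target_rate, rec$channel_groups, rec$t0)
}

#' Spike-band filtering
#'
#' Band-passes the wideband stream to the action-potential band (default
#' 500--5000 Hz, 2-pole Butterworth) at the original sample rate.
#'
#' @param rec A wideband [recording()] with Nyquist above the band top.
#' @param band,order Band (Hz) and order.
#' @param zero_phase Forward-backward filtering for offline analysis.
#' @return A [recording()] at the original rate.
#' @export
spike_band <- function(rec, band = c(500, 5000), order = 2, zero_phase = FALSE) {
  stopifnot(inherits(rec, "recording"))
  if (rec$sample_rate / 2 <= band[2])
    op_stop("Nyquist must exceed the spike band top", "optephys_config_error")
  filt <- apply_bandpass(rec$samples, rec$sample_rate, band, order, zero_phase)
  recording(filt, rec$sample_rate, rec$channel_groups, rec$t0)
}

#' Median referencing within channel groups
#'
#' Subtracts the per-sample median across each channel group from that group's
#' channels, removing common-mode components (movement and stimulation
#' artifacts shared across an electrode row) while sparing activity local to
#' single channels.
#'
#' @param rec A [recording()] whose `channel_groups` each contain >= 3
#'   channels. Channels belonging to no group are handled per `ungrouped`.
#' @param ungrouped `"error"` (default) or `"keep"` (pass through unreferenced).
#' @return A [recording()].
#' @export
median_reference <- function(rec, ungrouped = c("error", "keep")) {
  stopifnot(inherits(rec, "recording"))
  ungrouped <- match.arg(ungrouped)
  groups <- rec$channel_groups
  if (length(groups) == 0)
    op_stop("recording has no channel groups", "optephys_grouping_error")
  covered <- sort(unlist(groups))
  missing <- setdiff(seq_len(ncol(rec$samples)), covered)
  if (length(missing) > 0 && ungrouped == "error")
    op_stop("some channels belong to no group (set ungrouped = 'keep' to pass through)",
            "optephys_grouping_error")
  out <- rec$samples
  for (g in groups) {
    if (length(g) < 3)
      op_stop("median referencing needs >= 3 channels per group",
              "optephys_grouping_error")
    med <- apply(rec$samples[, g, drop = FALSE], 1, median)
    out[, g] <- rec$samples[, g, drop = FALSE] - med
  }
  recording(out, rec$sample_rate, groups, rec$t0)
}

#' Threshold spike detection with snippet extraction
#'
#' Applies symmetric positive and negative thresholds at `k` times the
#' per-channel standard deviation of the (spike-band, referenced) signal.
#' Threshold crossings within `dead_time` of an accepted event on the same
#' channel are suppressed; each event is aligned to the extremum of the
#' crossing run and a fixed pre/post snippet is extracted.
#'
#' The plain SD is the stated detection scale; because large spikes inflate
#' the SD and raise the threshold, a robust estimate
#' (`median(|x|) / 0.6745`) is available via `sd_estimator = "mad"`.
#'
#' @param rec A spike-band [recording()].
#' @param k Threshold multiplier (default 5).
#' @param dead_time Per-channel refractory for detection, seconds.
#' @param snippet_pre,snippet_post Snippet extent around the peak, seconds.
#' @param sd_estimator `"sd"` (plain standard deviation) or `"mad"`.
#' @return A data frame of class `spike_events` with columns `channel`,
#'   `time_s`, `polarity` (+1/-1), `peak_uv`, and a `snippets` attribute
#'   (list of matrices, one row per event).
#' @export
detect_spikes <- function(rec, k = 5, dead_time = 0.001,
                          snippet_pre = 0.0006, snippet_post = 0.0010,
                          sd_estimator = c("sd", "mad")) {
  stopifnot(inherits(rec, "recording"))
  if (k <= 0) op_stop("k must be > 0", "optephys_parameter_error")
  sd_estimator <- match.arg(sd_estimator)
  fs <- rec$sample_rate
  n <- nrow(rec$samples)
  dead_n <- max(1L, round(dead_time * fs))
  pre_n <- round(snippet_pre * fs); post_n <- round(snippet_post * fs)
  res <- list(); snips <- list()
  for (ch in seq_len(ncol(rec$samples))) {
    x <- rec$samples[, ch]
    scale <- if (sd_estimator == "sd") sd(x) else median(abs(x)) / 0.6745
    if (scale == 0) next
    thr <- k * scale
    over <- abs(x) >= thr
    if (!any(over)) next
    idx <- which(over)
    # group contiguous / near-contiguous crossings, honour dead time
    events <- integer(0)
    last <- -Inf
    i <- 1
    while (i <= length(idx)) {
      start <- idx[i]
      if (start - last >= dead_n) {
        # peak within the crossing run (bounded by dead window)
        run_end <- min(start + dead_n - 1L, n)
        seg <- start:run_end
        pk <- seg[which.max(abs(x[seg]))]
        if (pk - pre_n >= 1 && pk + post_n <= n) {
          events <- c(events, pk)
          snips[[length(snips) + 1L]] <- x[(pk - pre_n):(pk + post_n)]
          res[[length(res) + 1L]] <- data.frame(
            channel = ch, time_s = rec$t0 + (pk - 1) / fs,
            polarity = sign(x[pk]), peak_uv = x[pk])
        }
        last <- pk
      }
      i <- i + 1
      while (i <= length(idx) && idx[i] - last < dead_n) i <- i + 1
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(channel = integer(0), time_s = numeric(0),
               polarity = numeric(0), peak_uv = numeric(0))
  attr(out, "snippets") <- if (length(snips)) do.call(rbind, snips) else
    matrix(numeric(0), 0, pre_n + post_n + 1)
  attr(out, "snippet_lags_s") <- (-pre_n:post_n) / fs
  class(out) <- c("spike_events", "data.frame")
  out
}

#' Export detected spikes as CSV
#' @param events A `spike_events` data frame from [detect_spikes()].
#' @param path CSV path (`channel,time_s,polarity,peak_uv`); snippets go to a
#'   float32 binary sidecar `paste0(path, ".snippets.bin")`.
#' @return `path`, invisibly.
#' @export
write_spike_events <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  sn <- attr(events, "snippets")
  if (!is.null(sn) && nrow(sn) > 0) {
    con <- file(paste0(path, ".snippets.bin"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(t(sn)), con, size = 4, endian = "little")
  }
  invisible(path)
}
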