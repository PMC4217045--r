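#' Multichannel extracellular recording
#'
#' Container for a uniformly sampled multichannel voltage time series. Samples
#' are stored as a numeric matrix with one column per channel (time runs down
#' the rows), in microvolts. `channel_groups` names disjoint partitions of the
#' channels (e.g. the electrode rows targeting CA1 and CA3) and drives
#' group-wise operations such as median referencing.
#'
#' @param samples Numeric matrix, `n_samples x n_channels`, microvolts. A
#'   vector is treated as a single channel.
#' @param sample_rate Sampling rate, Hz (> 0).
#' @param channel_groups Named list of integer channel-index vectors; groups
#'   must be disjoint. May be empty.
#' @param t0 Time of the first sample, seconds.
#' @return An object of class `recording`.
#' @examples
#' rec <- recording(matrix(rnorm(2000 * 4), ncol = 4), 2000,
#'                  channel_groups = list(CA1 = 1:2, CA3 = 3:4))
#' @export
recording <- function(samples, sample_rate, channel_groups = list(), t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples)) op_stop("samples must be a matrix", "optephys_config_error")
  if (sample_rate <= 0) op_stop("sample_rate must be > 0", "optephys_config_error")
  idx <- unlist(channel_groups)
  if (length(idx) > 0) {
    if (anyDuplicated(idx))
      op_stop("channel groups must be disjoint", "optephys_grouping_error")
    if (any(idx < 1 | idx > ncol(samples)))
      op_stop("channel group index out of range", "optephys_grouping_error")
  }
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate),
                 channel_groups = channel_groups, t0 = as.numeric(t0),
                 units = "uV"),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %.3f s at %g Hz (t0 = %g s)\n",
              ncol(x$samples), nrow(x$samples) / x$sample_rate,
              x$sample_rate, x$t0))
  if (length(x$channel_groups))
    cat("  groups:", paste(sprintf("%s[%d]", names(x$channel_groups),
                                   lengths(x$channel_groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Duration, seconds.
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$sample_rate

#' Write / read a recording as int16 flat binary plus JSON sidecar
#'
#' The on-disk format is channel-interleaved little-endian int16 with a JSON
#' sidecar (`<path>.json`) recording `sample_rate_hz`, `n_channels`,
#' `uv_per_lsb`, `t0_s` and the channel groups. `uv_per_lsb` is chosen on
#' write so the full int16 range covers the data (unless given).
#'
#' @param rec A [recording()].
#' @param path Binary file path; sidecar goes to `paste0(path, ".json")`.
#' @param uv_per_lsb Quantization step; default scales the peak to ~90% of
#'   the int16 range.
#' @return `path` invisibly (write); a [recording()] (read).
#' @export
write_recording <- function(rec, path, uv_per_lsb = NULL) {
  stopifnot(inherits(rec, "recording"))
  peak <- max(abs(rec$samples), 1e-12)
  if (is.null(uv_per_lsb)) uv_per_lsb <- peak / (0.9 * 32767)
  q <- round(t(rec$samples) / uv_per_lsb)  # channel-interleaved
  q <- pmin(pmax(q, -32768), 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2, endian = "little")
  jsonlite::write_json(
    list(sample_rate_hz = rec$sample_rate, n_channels = ncol(rec$samples),
         uv_per_lsb = uv_per_lsb, t0_s = rec$t0,
         groups = rec$channel_groups),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_ch <- meta$n_channels
  raw <- readBin(path, "integer", n = file.info(path)$size / 2, size = 2,
                 endian = "little")
  mat <- t(matrix(raw, nrow = n_ch)) * meta$uv_per_lsb
  groups <- lapply(meta$groups, as.integer)
  recording(mat, meta$sample_rate_hz, channel_groups = groups, t0 = meta$t0_s)
}
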