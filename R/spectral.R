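#' Multitaper analysis parameters
#'
#' Window length `T`, spectral half-bandwidth `W` and taper count `K`
#' parameterize the multitaper estimate. By the Slepian concentration problem
#' at time-bandwidth product `T * W` there are `2 T W - 1` usefully
#' concentrated tapers, which is the default `K`. The standard configuration
#' for hippocampal LFP here is `T = 4` s, `W = 1` Hz, `K = 7`, stepping 0.5 s.
#'
#' @param T_s Window length, seconds.
#' @param W_hz Half-bandwidth, Hz; `T_s * W_hz` must be >= 1.
#' @param K Number of tapers; defaults to `2 * T_s * W_hz - 1`.
#' @param step_s Spectrogram step, seconds (<= `T_s`).
#' @return An object of class `multitaper_params`.
#' @examples
#' multitaper_params(4, 1)  # K = 7
#' @export
multitaper_params <- function(T_s = 4, W_hz = 1, K = NULL, step_s = 0.5) {
  tw <- T_s * W_hz
  if (tw < 1) op_stop("T * W must be >= 1", "optephys_parameter_error")
  kmax <- round(2 * tw - 1)
  if (is.null(K)) K <- kmax
  if (K > kmax)
    op_stop(sprintf("requested %d tapers but only %d are concentrated (2TW-1)",
                    K, kmax), "optephys_taper_error")
  if (K < 1) op_stop("need at least one taper", "optephys_parameter_error")
  if (step_s > T_s) op_stop("step must be <= window length", "optephys_parameter_error")
  structure(list(T_s = T_s, W_hz = W_hz, K = as.integer(K), step_s = step_s),
            class = "multitaper_params")
}

# dense tridiagonal solve of the Slepian concentration problem at length N
dpss_exact <- function(N, NW, K) {
  W <- NW / N
  i <- 0:(N - 1)
  d <- ((N - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  e <- (1:(N - 1)) * (N - (1:(N - 1))) / 2
  M <- matrix(0, N, N)
  diag(M) <- d
  M[cbind(1:(N - 1), 2:N)] <- e
  M[cbind(2:N, 1:(N - 1))] <- e
  eigen(M, symmetric = TRUE)$vectors[, seq_len(K), drop = FALSE]
}

dpss_sign_fix <- function(V) {
  for (k in seq_len(ncol(V))) {
    v <- V[, k]
    flip <- if (k %% 2 == 1) sum(v) < 0 else (v[2] - v[1]) < 0
    if (flip) V[, k] <- -v
  }
  V
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `K` DPSS tapers of length `N = T_s * sample_rate` for
#' half-bandwidth `W_hz`, as the leading eigenvectors of the standard
#' tridiagonal form of the concentration problem. For long windows
#' (`N > interp_from`) the eigenproblem is solved at a shorter length and the
#' tapers are spline-interpolated to `N` and re-orthonormalized (QR); the
#' interpolation error is far below the orthonormality tolerance because the
#' tapers are smooth, slowly varying functions of relative position.
#'
#' @param params A [multitaper_params()].
#' @param sample_rate Sampling rate, Hz.
#' @param interp_from Length above which interpolation is used.
#' @return An `N x K` matrix; columns orthonormal, ordered by in-band energy
#'   concentration, with concentration eigenvalues in attribute
#'   `"concentration"` (computed from the zero-padded FFT of each taper).
#' @export
dpss_tapers <- function(params, sample_rate, interp_from = 1024) {
  stopifnot(inherits(params, "multitaper_params"))
  N <- round(params$T_s * sample_rate)
  NW <- params$T_s * params$W_hz
  K <- params$K
  if (N <= interp_from) {
    V <- dpss_exact(N, NW, K)
  } else {
    V0 <- dpss_exact(interp_from, NW, K)
    x0 <- (seq_len(interp_from) - 0.5) / interp_from
    x1 <- (seq_len(N) - 0.5) / N
    V <- vapply(seq_len(K), function(k) spline(x0, V0[, k], xout = x1)$y,
                numeric(N))
    V <- qr.Q(qr(V))
  }
  V <- dpss_sign_fix(V)
  # exact in-band concentration: lambda = sum_d K(d) * acf_v(d) with
  # K(d) = sin(2 pi W d) / (pi d), evaluated via FFT autocorrelation
  Wn <- NW / N
  d <- 1:(N - 1)
  Kd <- sin(2 * pi * Wn * d) / (pi * d)
  nfft <- 2^ceiling(log2(2 * N))
  conc <- vapply(seq_len(K), function(k) {
    A <- fft(c(V[, k], rep(0, nfft - N)))
    r <- Re(fft(Mod(A)^2, inverse = TRUE)) / nfft
    2 * Wn * r[1] + 2 * sum(Kd * r[2:N])
  }, numeric(1))
  attr(V, "concentration") <- conc
  V
}

#' Multitaper power spectrum of one segment
#'
#' Averages the squared magnitudes of the taper-windowed Fourier transforms
#' over `K` orthonormal DPSS tapers. Power is reported as a one-sided density
#' in signal-units^2 per Hz, so the integral of the estimate over frequency
#' equals the segment variance in expectation (Parseval convention).
#'
#' @param segment Numeric vector of length `round(T_s * sample_rate)`.
#' @param params A [multitaper_params()].
#' @param sample_rate Sampling rate, Hz.
#' @param tapers Optional precomputed taper matrix (from [dpss_tapers()]).
#' @return An object of class `spectral_estimate`: list with `frequencies`
#'   (Hz, 0..Nyquist), `power` (density), `params`.
#' @export
multitaper_spectrum <- function(segment, params, sample_rate, tapers = NULL) {
  N <- round(params$T_s * sample_rate)
  if (length(segment) != N)
    op_stop(sprintf("segment must have exactly %d samples (T * rate)", N),
            "optephys_length_error")
  if (is.null(tapers)) tapers <- dpss_tapers(params, sample_rate)
  X <- mvfft(tapers * segment)      # N x K
  P <- rowMeans(abs(X)^2) / sample_rate
  half <- floor(N / 2) + 1
  pow <- P[seq_len(half)]
  # one-sided: double interior bins (not DC; not Nyquist when N is even)
  dbl <- 2:(half - if (N %% 2 == 0) 1 else 0)
  pow[dbl] <- 2 * pow[dbl]
  structure(list(frequencies = (seq_len(half) - 1) * sample_rate / N,
                 power = pow, params = params, sample_rate = sample_rate),
            class = "spectral_estimate")
}

#' Moving-window multitaper spectrogram
#'
#' Applies [multitaper_spectrum()] to left-aligned windows of length `T_s`
#' advanced by `step_s`; the number of windows is
#' `floor((L - T) / step) + 1` and window centres (window midpoints) are
#' reported as the time axis.
#'
#' @param x Numeric vector (one channel).
#' @param params A [multitaper_params()].
#' @param sample_rate Sampling rate, Hz.
#' @param t0 Time of the first sample, seconds.
#' @return A `spectral_estimate` with `times` (window centres, seconds) and
#'   `power` as a `frequencies x times` matrix.
#' @export
mt_spectrogram <- function(x, params, sample_rate, t0 = 0) {
  N <- round(params$T_s * sample_rate)
  if (length(x) < N)
    op_stop("signal shorter than one analysis window", "optephys_length_error")
  step_n <- round(params$step_s * sample_rate)
  n_win <- floor((length(x) - N) / step_n) + 1
  tapers <- dpss_tapers(params, sample_rate)
  pow <- NULL
  times <- numeric(n_win)
  for (wi in seq_len(n_win)) {
    i0 <- (wi - 1) * step_n + 1
    est <- multitaper_spectrum(x[i0:(i0 + N - 1)], params, sample_rate, tapers)
    if (is.null(pow)) pow <- matrix(0, length(est$power), n_win)
    pow[, wi] <- est$power
    times[wi] <- t0 + (i0 - 1) / sample_rate + params$T_s / 2
  }
  structure(list(frequencies = (seq_len(nrow(pow)) - 1) * sample_rate / N,
                 times = times, power = pow, params = params,
                 sample_rate = sample_rate),
            class = "spectral_estimate")
}

#' Peristimulus average of an LFP around stimulus onsets
#'
#' Computes the per-lag mean and SD of the signal in a window from `pre_s`
#' before to `post_s` after each event onset (defaults 5 ms and 40 ms). Event
#' times snap to the nearest sample; the lag grid includes both endpoints, so
#' at 2 kHz with defaults there are 91 lag samples. Events whose window falls
#' outside the recording are dropped with a warning.
#'
#' @param x Numeric vector (one LFP channel) or a [recording()] (first
#'   channel used unless `channel` given).
#' @param events Event onset times, seconds (same time base as the signal).
#' @param sample_rate Sampling rate, Hz (taken from the recording if given).
#' @param pre_s,post_s Window extent, seconds.
#' @param t0 Time of first sample (taken from the recording if given).
#' @param channel Channel to use when `x` is a recording.
#' @return An object of class `peristimulus_average`: data frame with columns
#'   `lag_s`, `mean_uv`, `sd_uv`, and attribute `n_events`.
#' @export
peristimulus_average <- function(x, events, sample_rate = NULL,
                                 pre_s = 0.005, post_s = 0.040, t0 = 0,
                                 channel = 1) {
  if (inherits(x, "recording")) {
    sample_rate <- x$sample_rate; t0 <- x$t0; x <- x$samples[, channel]
  }
  if (is.null(sample_rate)) op_stop("sample_rate required", "optephys_parameter_error")
  n_pre <- round(pre_s * sample_rate); n_post <- round(post_s * sample_rate)
  lags <- (-n_pre:n_post)
  centre <- round((events - t0) * sample_rate) + 1
  ok <- centre - n_pre >= 1 & centre + n_post <= length(x)
  if (any(!ok))
    warning(sprintf("%d event(s) too close to the record edge dropped", sum(!ok)))
  centre <- centre[ok]
  if (length(centre) == 0)
    op_stop("no usable events for the peristimulus average",
            "optephys_empty_average_error")
  M <- vapply(centre, function(c0) x[c0 + lags], numeric(length(lags)))
  mu <- rowMeans(M)
  sdv <- if (length(centre) > 1) apply(M, 1, sd) else rep(0, length(lags))
  out <- data.frame(lag_s = lags / sample_rate, mean_uv = mu, sd_uv = sdv)
  attr(out, "n_events") <- length(centre)
  class(out) <- c("peristimulus_average", "data.frame")
  out
}

#' Normalized (biased) autocorrelation
#'
#' Mean-removed, biased autocorrelation normalized to 1 at lag zero; during
#' periodic stimulation the LFP becomes highly correlated at multiples of the
#' stimulation period.
#'
#' @param x Numeric vector.
#' @param max_lag_s Maximum lag, seconds.
#' @param sample_rate Sampling rate, Hz.
#' @return Data frame with columns `lag_s`, `r`.
#' @export
autocorrelation <- function(x, max_lag_s, sample_rate) {
  if (sd(x) == 0)
    op_stop("autocorrelation of a constant signal is undefined",
            "optephys_degenerate_signal_error")
  max_lag <- round(max_lag_s * sample_rate)
  if (max_lag >= length(x))
    op_stop("max lag must be shorter than the signal", "optephys_length_error")
  r <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  data.frame(lag_s = (0:max_lag) / sample_rate, r = r)
}

#' Remove sinusoidal components at listed frequencies
#'
#' For each listed frequency, fits amplitude and phase of a sinusoid to the
#' whole record by least squares and subtracts the fit. Unlike a notch
#' filter this removes exactly one complex exponential pair per frequency and
#' leaves the amplitude and phase of all other components untouched, which is
#' what makes it suitable both for line-noise removal and for harmonic
#' deconstruction of a periodic evoked response (removing 14, 21, 28, ... Hz
#' components of a 7 Hz response to isolate the fundamental).
#'
#' @param x Numeric vector.
#' @param freqs_hz Frequencies to remove, Hz (duplicates collapsed with a
#'   warning; must be below Nyquist).
#' @param sample_rate Sampling rate, Hz.
#' @return The cleaned signal, same length as `x`.
#' @export
remove_harmonics <- function(x, freqs_hz, sample_rate) {
  if (any(freqs_hz >= sample_rate / 2))
    op_stop("frequencies must be below Nyquist", "optephys_parameter_error")
  if (anyDuplicated(freqs_hz)) {
    warning("duplicate frequencies collapsed")
    freqs_hz <- unique(freqs_hz)
  }
  n <- length(x)
  t <- (0:(n - 1)) / sample_rate
  D <- do.call(cbind, lapply(freqs_hz, function(f)
    cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))))
  fit <- lm.fit(D, x)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  as.numeric(x - D %*% cf)
}

#' Fraction of spectral power in a band
#'
#' Multitaper estimate of the segment's power spectral density, integrated
#' over `band` and divided by the integral over `total_band` (default: the
#' full one-sided axis). This normalized band power is the closed-loop
#' control signal (theta band 6--10 Hz relative to total power).
#'
#' @param segment Numeric vector.
#' @param band Two-element numeric, Hz.
#' @param sample_rate Sampling rate, Hz.
#' @param params Optional [multitaper_params()]; by default the whole segment
#'   is one window (`T = length / rate`) with `W` chosen to give at least
#'   time-bandwidth 2.
#' @param total_band Denominator band, Hz; `NULL` means 0..Nyquist.
#' @param tapers Optional precomputed tapers.
#' @return An object of class `band_power`: list with `band`, `fraction`,
#'   `absolute` (integrated density over `band`), `total`.
#' @export
band_power_fraction <- function(segment, band, sample_rate, params = NULL,
                                total_band = NULL, tapers = NULL) {
  if (length(band) != 2 || band[2] <= band[1])
    op_stop("band must be an increasing pair", "optephys_parameter_error")
  if (band[2] > sample_rate / 2)
    op_stop("band must lie inside [0, Nyquist]", "optephys_parameter_error")
  if (is.null(params)) {
    T_s <- length(segment) / sample_rate
    params <- multitaper_params(T_s, max(2 / T_s, 1 / T_s), step_s = T_s)
  }
  est <- multitaper_spectrum(segment, params, sample_rate, tapers)
  df <- est$frequencies[2] - est$frequencies[1]
  in_band <- est$frequencies >= band[1] & est$frequencies <= band[2]
  if (is.null(total_band)) total_band <- c(0, sample_rate / 2)
  in_tot <- est$frequencies >= total_band[1] & est$frequencies <= total_band[2]
  tot <- sum(est$power[in_tot]) * df
  absr <- sum(est$power[in_band]) * df
  frac <- if (tot > 0) absr / tot else {
    warning("zero total power; band fraction reported as 0")
    0
  }
  structure(list(band = band, fraction = frac, absolute = absr, total = tot),
            class = "band_power")
}

#' Write a peristimulus average as CSV (`lag_s,mean_uv,sd_uv`)
#' @param psa A [peristimulus_average()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_peristimulus <- function(psa, path) {
  write.csv(as.data.frame(psa), path, row.names = FALSE)
  invisible(path)
}
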