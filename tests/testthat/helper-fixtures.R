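# shared fixtures: exact linear calibration and small subject configs

# calibration curve with irradiance = intercept + slope * V over [0, 5] V,
# built from noiseless points through the full fitting path
make_linear_curve <- function(slope = 10, intercept = 0) {
  v <- seq(0, 5, by = 1)
  irr <- intercept + slope * v
  fib <- fiber_spec(200, 0.37, 465)
  area <- pi * (fib$core_diameter_um / 2000)^2
  fit_calibration(data.frame(voltage_v = v, power_mw = irr * area), fib)
}

# small, fast virtual subject
small_cfg <- function(...) {
  subject_config(n_channels = 4, sample_rate = 2000, seed = 42L, ...)
}

# steep-spectrum subject whose theta-free normalized theta power sits below
# the controller threshold (in vivo hippocampal LFP decays much faster than
# the generic 1/f^1.5 default; exponent 3 emulates that regime)
loop_cfg <- function(seed = 7L, ...) {
  subject_config(n_channels = 16, sample_rate = 2000,
                 one_over_f_exponent = 3, theta_amplitude_uv = 150,
                 seed = seed, ...)
}

# analytic gain of a digital filter given (b, a) at frequency f_hz
digital_gain <- function(b, a, f_hz, fs) {
  z <- exp(-1i * 2 * pi * f_hz / fs)
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}

# steady-state amplitude of a sine in a filtered trace (skip transient)
sine_amplitude <- function(x, f_hz, fs, skip_s = 1) {
  x <- x[-(1:round(skip_s * fs))]
  t <- (0:(length(x) - 1)) / fs
  D <- cbind(cos(2 * pi * f_hz * t), sin(2 * pi * f_hz * t))
  cf <- qr.solve(D, x)
  sqrt(sum(cf^2))
}
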