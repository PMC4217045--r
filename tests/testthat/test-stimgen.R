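test_that("fixed trains enumerate onsets while pulses fit the epoch", {
  tr <- fixed_train(pattern_spec("fixed", 50, 7, 0.010), c(0, 20))
  # enumeration oracle
  expected <- (0:1000) / 7
  expected <- expected[expected + 0.010 <= 20]
  expect_equal(nrow(tr), 140)
  expect_equal(tr$onset_s, expected)
  expect_lt(max(abs(diff(tr$onset_s) - 1 / 7)), 1e-10)
  expect_equal(nrow(fixed_train(pattern_spec("fixed", 50, 7, 0.010), c(5, 5))), 0)
  expect_error(pattern_spec("fixed", 50, 100, 0.010),
               class = "optephys_duty_cycle_error")
})

test_that("fixed-train count matches the enumeration oracle across parameters", {
  for (f in c(3, 7, 11, 23)) {
    for (dur in c(5, 10, 17.3)) {
      w <- 1e-4
      tr <- fixed_train(pattern_spec("fixed", 10, f, w), c(0, dur))
      oracle <- sum((0:ceiling(dur * f)) / f + w <= dur)
      expect_equal(nrow(tr), oracle, info = sprintf("f=%g dur=%g", f, dur))
      # with an integer cycle count the last pulse no longer fits,
      # giving exactly duration x frequency pulses
      if (abs(dur * f - round(dur * f)) < 1e-9)
        expect_equal(nrow(tr), round(dur * f))
    }
  }
})

test_that("jittered trains bound instantaneous frequency and centre on the mean", {
  sp <- pattern_spec("jittered", 50, 23, 0.010, jitter_halfwidth_hz = 5, seed = 8)
  tr <- jittered_train(sp, c(0, 20))
  fi <- 1 / diff(tr$onset_s)
  expect_true(all(fi >= 18 - 1e-9 & fi <= 28 + 1e-9))
  # degenerate jitter reduces to the fixed train
  sp0 <- pattern_spec("jittered", 50, 23, 0.010, jitter_halfwidth_hz = 0, seed = 8)
  expect_equal(jittered_train(sp0, c(0, 20))$onset_s,
               fixed_train(sp0, c(0, 20))$onset_s)
  expect_error(pattern_spec("jittered", 50, 23, 0.010, jitter_halfwidth_hz = 23),
               class = "optephys_jitter_error")
})

test_that("jittered instantaneous frequencies follow the truncated normal law", {
  # long epoch to accumulate ~10,000 intervals
  sp <- pattern_spec("jittered", 50, 23, 0.010, jitter_halfwidth_hz = 5, seed = 13)
  tr <- jittered_train(sp, c(0, 10001 / 23))
  fi <- 1 / diff(tr$onset_s)
  expect_gte(length(fi), 9000)
  expect_lt(abs(mean(fi) - 23), 0.2)
  # KS against the truncated normal CDF (sigma = halfwidth / 2)
  ptrunc <- function(x, mu = 23, s = 2.5, lo = 18, hi = 28) {
    (pnorm((x - mu) / s) - pnorm((lo - mu) / s)) /
      (pnorm((hi - mu) / s) - pnorm((lo - mu) / s))
  }
  ks <- suppressWarnings(ks.test(fi, ptrunc))
  expect_gt(ks$p.value, 0.01)
})

test_that("poisson trains realize the dead-time-corrected rate", {
  expect_equal(nrow(poisson_train(pattern_spec("poisson", 50, 1e-12, 0.01), c(0, 20))),
               0)
  # oracle: dead-time-modified Poisson process rate lambda / (1 + lambda w)
  lambda <- 23; w <- 0.010; dur <- 20
  expected <- lambda / (1 + lambda * w) * dur
  counts <- vapply(1:500, function(r) {
    nrow(poisson_train(pattern_spec("poisson", 50, lambda, w, seed = r), c(0, dur)))
  }, numeric(1))
  se <- sd(counts) / sqrt(500)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1)
})

test_that("poisson interval law: CV near 1 for vanishing width, exponential KS", {
  sp <- pattern_spec("poisson", 50, 23, 1e-5, seed = 3)
  tr <- poisson_train(sp, c(0, 10200 / 23))
  iv <- diff(tr$onset_s)
  expect_gte(length(iv), 9000)
  expect_lt(abs(sd(iv) / mean(iv) - 1), 0.1)
  # accepted intervals are w + Exp(lambda) by memorylessness
  w <- 1e-5
  ks <- suppressWarnings(ks.test(iv - w, stats::pexp, rate = 23))
  expect_gt(ks$p.value, 0.01)
  expect_error(pattern_spec("poisson", 50, 120, 0.010),
               class = "optephys_duty_cycle_error")
})

test_that("burst trains nest pulses at the intra-burst rate", {
  sp <- pattern_spec("burst", 50, 7, 0.010, pulses_per_burst = 4,
                     intra_burst_frequency_hz = 42)
  tr <- burst_train(sp, c(0, 1))
  # enumeration oracle: 7 bursts of 4
  expect_equal(nrow(tr), 28)
  onsets <- matrix(tr$onset_s, nrow = 4)
  expect_equal(unique(round(diff(onsets[, 1]), 12)), round(1 / 42, 12))
  expect_equal(onsets[1, ], (0:6) / 7)
  # degenerate burst of one pulse equals the fixed train at the cycle rate
  sp1 <- pattern_spec("burst", 50, 7, 0.010, pulses_per_burst = 1,
                      intra_burst_frequency_hz = 42)
  expect_equal(burst_train(sp1, c(0, 1))$onset_s,
               fixed_train(pattern_spec("fixed", 50, 7, 0.010), c(0, 1))$onset_s)
  # 7 pulses at 42 Hz span 152.9 ms > the 142.9 ms cycle
  expect_error(pattern_spec("burst", 50, 7, 0.010, pulses_per_burst = 7,
                            intra_burst_frequency_hz = 42),
               class = "optephys_nesting_error")
})

test_that("sinusoid command spans 0..I_max with mean I_max/2 and peaks at f", {
  cc <- make_linear_curve(10, 0)
  sp <- pattern_spec("sinusoid", 50, 23, seed = 1)
  cmd <- sinusoid_command(sp, c(0, 2), cc, sample_rate = 10000)
  irr <- irradiance_at_voltage(cmd$samples, cc)  # back to irradiance
  expect_equal(min(irr), 0, tolerance = 1e-9)
  expect_equal(max(irr), 50, tolerance = 1e-6)
  expect_equal(mean(irr), 25, tolerance = 1e-6)  # whole periods in 2 s
  # FFT oracle: dominant non-DC bin at 23 Hz
  sp_fft <- abs(fft(irr - mean(irr)))[2:10000]
  fgrid <- (1:9999) * 10000 / 20000
  expect_equal(fgrid[which.max(sp_fft)], 23)
  expect_error(sinusoid_command(sp, c(0, 2), cc, sample_rate = 100),
               class = "optephys_undersampling_error")
})

test_that("rendered commands are square pulses on a 0 V baseline", {
  cc <- make_linear_curve(10, 0)
  empty <- pulse_train(numeric(0), numeric(0), numeric(0), c(0, 1))
  expect_true(all(render_command(empty, cc, 10000)$samples == 0))
  one <- pulse_train(0.1, 0.010, 50, c(0, 1))
  cmd <- render_command(one, cc, 10000)
  expect_equal(sum(cmd$samples == 5), 100)  # 10 ms at 10 kHz
  expect_equal(sum(cmd$samples != 0), 100)
  # duty-cycle counting oracle on a full train
  tr <- fixed_train(pattern_spec("fixed", 50, 7, 0.010), c(0, 20))
  cmd2 <- render_command(tr, cc, 10000)
  duty <- mean(cmd2$samples > 0)
  expect_lt(abs(duty - 7 * 0.010), 1 / 10000 * 7 + 1e-6)
  expect_error(render_command(pulse_train(0.1, 0.01, 80, c(0, 1)), cc, 10000),
               class = "optephys_range_error")
})

test_that("protocol assembly brackets stimulation with silence and is seeded", {
  pats <- list(pattern_spec("fixed", 50, 7, 0.010, seed = 1),
               pattern_spec("fixed", 50, 23, 0.010, seed = 2),
               pattern_spec("poisson", 50, 23, 0.010, seed = 3))
  pr <- assemble_protocol(pats, trial_protocol(20, 20, 20, order_seed = 5))
  expect_length(pr, 3)
  for (tr in pr) {
    expect_equal(diff(tr$epoch_pre) + diff(tr$epoch_stim) + diff(tr$epoch_post), 60)
    on <- tr$train$onset_s
    expect_true(all(on >= tr$epoch_stim[1] & on <= tr$epoch_stim[2]))
  }
  pr2 <- assemble_protocol(pats, trial_protocol(order_seed = 5))
  expect_identical(vapply(pr, function(t) t$pattern$frequency_hz, numeric(1)),
                   vapply(pr2, function(t) t$pattern$frequency_hz, numeric(1)))
})

test_that("all generators respect non-overlap and seed determinism", {
  set.seed(99)
  for (rep in 1:12) {
    kind <- sample(c("fixed", "jittered", "poisson", "burst"), 1)
    f <- runif(1, 4, 40)
    w <- runif(1, 0.001, 0.8 / (f + 6))
    sp <- switch(kind,
      fixed = pattern_spec("fixed", 30, f, w, seed = rep),
      jittered = pattern_spec("jittered", 30, f, min(w, 0.8 / (f + f / 4)),
                              jitter_halfwidth_hz = f / 4, seed = rep),
      poisson = pattern_spec("poisson", 30, f, w, seed = rep),
      burst = pattern_spec("burst", 30, 5, 0.002, pulses_per_burst = 3,
                           intra_burst_frequency_hz = 60, seed = rep))
    tr <- realize_pattern(sp, c(0, 12))
    tr2 <- realize_pattern(sp, c(0, 12))
    expect_identical(tr$onset_s, tr2$onset_s)
    if (nrow(tr) > 1)
      expect_true(all(diff(tr$onset_s) >= tr$width_s[-nrow(tr)] - 1e-12))
  }
})

test_that("pulse-train CSV and analog binary round-trips preserve data", {
  tr <- fixed_train(pattern_spec("fixed", 50, 11, 0.005), c(0, 3))
  path <- tempfile(fileext = ".csv")
  write_pulse_train(tr, path)
  tr2 <- read_pulse_train(path, epoch = c(0, 3))
  expect_equal(tr2$onset_s, tr$onset_s)
  expect_equal(tr2$intensity_mw_mm2, tr$intensity_mw_mm2)
  cc <- make_linear_curve(10, 0)
  cmd <- render_command(tr, cc, 5000)
  bin <- tempfile(fileext = ".bin")
  write_analog_command(cmd, bin)
  meta <- jsonlite::read_json(paste0(bin, ".json"), simplifyVector = TRUE)
  expect_equal(meta$sample_rate, 5000)
  raw <- readBin(bin, "numeric", n = meta$n_samples, size = 4, endian = "little")
  expect_equal(raw, cmd$samples, tolerance = 1e-6)
  unlink(c(path, bin, paste0(bin, ".json")))
})
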