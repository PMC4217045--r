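# build a synthetic "non-expressing site" record: known biphasic artifact at
# each pulse onset plus white noise
make_artifact_record <- function(n_pulses, fs = 2000, noise_sd = 5, amp = 40,
                                 seed = 1) {
  set.seed(seed)
  dur <- n_pulses * 0.1 + 1
  n <- round(dur * fs)
  tker <- seq(0, 0.004, by = 1 / fs)
  ker <- amp * (exp(-tker / 0.002) - 0.5 * exp(-tker / 0.0005))
  events <- seq(0.5, by = 0.1, length.out = n_pulses)
  x <- rnorm(n, sd = noise_sd)
  clean <- numeric(n)
  for (e in events) {
    i0 <- round(e * fs) + 1
    ii <- i0:(i0 + length(ker) - 1)
    clean[ii] <- clean[ii] + ker
  }
  list(x = x + clean, clean = clean, ker = ker, events = events, fs = fs,
       noise_sd = noise_sd)
}

test_that("template estimation recovers an injected artifact within CLT bounds", {
  rec <- make_artifact_record(200)
  tmpl <- estimate_template(rec$x, rec$events, intensity_mw_mm2 = 50,
                            sample_rate = rec$fs, pulse_width_s = 0.010)
  se <- rec$noise_sd / sqrt(200)
  truth <- numeric(nrow(tmpl))
  pos <- tmpl$lag_s >= 0 & tmpl$lag_s <= max(0.004, 0)
  truth[pos] <- rec$ker[seq_len(sum(pos))]
  expect_true(all(abs(tmpl$mean_uv - truth) < 4 * se))
  expect_equal(attr(tmpl, "n_pulses"), 200L)
  expect_equal(attr(tmpl, "intensity_mw_mm2"), 50)
  expect_error(estimate_template(rec$x, rec$events[1:5], 50, rec$fs),
               class = "optephys_insufficient_data_error")
})

test_that("a response-free recording yields a null template", {
  set.seed(3)
  fs <- 2000
  x <- rnorm(fs * 30, sd = 5)
  ev <- seq(0.5, 29, by = 0.15)
  tmpl <- estimate_template(x, ev, 10, fs)
  se <- 5 / sqrt(length(ev))
  expect_lt(max(abs(tmpl$mean_uv)), 4 * se)
})

test_that("template amplitude increases with stimulation intensity", {
  cfg <- small_cfg()
  peaks <- vapply(c(10, 30, 50), function(inten) {
    tr <- fixed_train(pattern_spec("fixed", inten, 7, 0.010), c(1, 19))
    art <- inject_artifact(cfg, tr, 20)
    tmpl <- estimate_template(art$trace[, 1], tr$onset_s, inten,
                              cfg$sample_rate)
    max(abs(tmpl$mean_uv))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("template subtraction recovers the underlying response", {
  rec <- make_artifact_record(150, noise_sd = 0.5)
  fs <- rec$fs
  # underlying "response": slow evoked wave at each event
  t_resp <- seq(0, 0.03, by = 1 / fs)
  resp_ker <- 100 * (exp(-t_resp / 0.012) - exp(-t_resp / 0.004))
  resp <- numeric(length(rec$x))
  for (e in rec$events) {
    i0 <- round(e * fs) + 1
    ii <- i0:(i0 + length(resp_ker) - 1)
    resp[ii] <- resp[ii] + resp_ker
  }
  lfp <- resp + rec$clean  # response + artifact, no noise for exactness
  tmpl <- estimate_template(rec$clean, rec$events, 50, fs, pulse_width_s = 0.010)
  cleaned <- subtract_template(lfp, rec$events, tmpl, fs)
  resid <- cleaned - resp
  expect_lt(sqrt(mean(resid^2)), 0.05 * sqrt(mean(rec$clean^2)))
  # no events: identity
  expect_identical(subtract_template(lfp, numeric(0), tmpl, fs), lfp)
  # dense events: overlap warning
  expect_warning(subtract_template(lfp, c(1, 1.002), tmpl, fs), "overlap")
})

test_that("subtraction then re-estimation closes to a null template", {
  rec <- make_artifact_record(200, noise_sd = 2)
  fs <- rec$fs
  tmpl <- estimate_template(rec$x, rec$events, 50, fs, pulse_width_s = 0.010)
  cleaned <- subtract_template(rec$x, rec$events, tmpl, fs)
  tmpl2 <- estimate_template(cleaned, rec$events, 50, fs, pulse_width_s = 0.010)
  expect_lt(sqrt(mean(tmpl2$mean_uv^2)), 0.05 * sqrt(mean(tmpl$mean_uv^2)))
})

test_that("when the response dwarfs the artifact, band power barely changes", {
  cfg <- small_cfg()
  tr <- fixed_train(pattern_spec("fixed", 50, 7, 0.010), c(1, 19))
  ev <- evoked_response(cfg, tr, 20)   # ~400 uV response
  art <- inject_artifact(cfg, tr, 20)  # ~100 uV edges, few-ms decay
  lfp <- ev$trace[, 1] + art$trace[, 1]
  tmpl <- estimate_template(art$trace[, 1], tr$onset_s, 50, cfg$sample_rate,
                            pulse_width_s = 0.010)
  cleaned <- subtract_template(lfp, tr$onset_s, tmpl, cfg$sample_rate)
  seg <- (4 * cfg$sample_rate + 1):(12 * cfg$sample_rate)
  p <- multitaper_params(8, 0.5)
  before <- multitaper_spectrum(lfp[seg], p, cfg$sample_rate)
  after <- multitaper_spectrum(cleaned[seg], p, cfg$sample_rate)
  bin7 <- which.min(abs(before$frequencies - 7))
  expect_lt(abs(after$power[bin7] - before$power[bin7]) / before$power[bin7],
            0.05)
})

test_that("template estimation error variance scales as 1/n_pulses", {
  sds <- vapply(c(25, 100, 400), function(np) {
    rec <- make_artifact_record(np, noise_sd = 5, seed = np)
    tmpl <- estimate_template(rec$x, rec$events, 50, rec$fs,
                              pulse_width_s = 0.010)
    truth <- numeric(nrow(tmpl))
    pos <- which(tmpl$lag_s >= 0)
    truth[pos[seq_along(rec$ker)]] <- rec$ker
    sd(tmpl$mean_uv - truth)
  }, numeric(1))
  # each 4x increase in pulses should halve the error SD (within 2x slack)
  expect_lt(sds[2] / sds[1], 1)
  expect_lt(sds[3] / sds[2], 1)
  expect_lt(sds[3] / sds[1], 0.5)
})

test_that("stimulus-locked unit flagging separates artifacts from real units", {
  epochs <- rbind(c(20, 40), c(80, 100))
  f <- 23
  # unit firing at fixed 4 ms latency after each pulse, silent otherwise
  pulses <- c(seq(20, 40 - 1 / f, by = 1 / f), seq(80, 100 - 1 / f, by = 1 / f))
  locked <- pulses + 0.004
  # tonic 5 Hz unit
  tonic <- seq(0.05, 120, by = 0.2)
  # unit whose rate doubles during stimulation and persists after
  set.seed(31)
  persistent <- sort(c(runif(200, 0, 20), runif(400, 20, 40), runif(400, 40, 120)))
  flags <- flag_stimulus_locked_units(
    list(locked = locked, tonic = tonic, persistent = persistent),
    epochs, f)
  expect_equal(flags$verdict[flags$unit_id == "locked"], "suspect_artifact")
  expect_equal(flags$verdict[flags$unit_id == "tonic"], "plausible")
  expect_equal(flags$verdict[flags$unit_id == "persistent"], "plausible")
  expect_gt(flags$vector_strength[flags$unit_id == "locked"], 0.99)
  expect_equal(flags$in_stim_fraction[flags$unit_id == "locked"], 1)
  expect_error(flag_stimulus_locked_units(list(u = numeric(0)), epochs, f),
               class = "optephys_undefined_unit_error")
  expect_warning(flag_stimulus_locked_units(list(u = c(25, 26, 27)), epochs, f),
                 "unstable")
})

test_that("flagging is monotone in both statistics", {
  epochs <- rbind(c(10, 20))
  f <- 23
  base <- seq(10, 20 - 1 / f, by = 1 / f) + 0.004
  # adding out-of-epoch spikes lowers in_stim_fraction -> can only weaken the flag
  flags_pure <- flag_stimulus_locked_units(list(u = base), epochs, f)
  diluted <- sort(c(base, seq(1, 9, by = 0.5)))
  flags_dil <- flag_stimulus_locked_units(list(u = diluted), epochs, f)
  expect_equal(flags_pure$verdict, "suspect_artifact")
  expect_lt(flags_dil$in_stim_fraction, flags_pure$in_stim_fraction)
  expect_equal(flags_dil$verdict, "plausible")
  # jittering in-stim spikes lowers vector strength -> weakens the flag
  set.seed(40)
  jittered <- base + runif(length(base), 0, 1 / f)
  flags_jit <- flag_stimulus_locked_units(list(u = jittered), epochs, f)
  expect_lt(flags_jit$vector_strength, flags_pure$vector_strength)
  expect_equal(flags_jit$verdict, "plausible")
})

test_that("artifact template artifact writes CSV plus JSON header", {
  rec <- make_artifact_record(50)
  tmpl <- estimate_template(rec$x, rec$events, 30, rec$fs, pulse_width_s = 0.010)
  path <- tempfile(fileext = ".csv")
  write_artifact_template(tmpl, path)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(hdr$intensity_mw_mm2, 30)
  expect_equal(hdr$n_pulses, 50)
  back <- read.csv(path)
  expect_equal(back$mean_uv, tmpl$mean_uv)
  unlink(c(path, paste0(path, ".json")))
})
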