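# Patch-clamp feature extraction.

test_that("input resistance follows Ohm's law and survives offsets", {
  t <- seq(0, 800, 0.1)
  i <- ifelse(t >= 100 & t < 600, 100, 0)
  sw <- sweep_record(t, i, mode = "vclamp", step_window = c(100, 600))
  expect_equal(input_resistance(sw, step_mv = 5), 50)
  # additive baseline offset cancels
  sw2 <- sweep_record(t, i - 37, mode = "vclamp", step_window = c(100, 600))
  expect_equal(input_resistance(sw2, step_mv = 5), 50)
  # unresolvable change
  flat <- sweep_record(t, rep(2, length(t)), mode = "vclamp",
                       step_window = c(100, 600))
  expect_error(input_resistance(flat, 5), "unresolvable")
})

test_that("input resistance recovers the generating RC membrane", {
  sw <- gen_passive_sweep(200, 20, step = 5, mode = "vclamp")
  expect_equal(input_resistance(sw, 5), 200, tolerance = 0.01)
  errs <- vapply(1:20, function(s) {
    R <- 30 + 250 * (s - 1) / 19
    swn <- gen_passive_sweep(R, 20, step = 5, mode = "vclamp",
                             noise_sd = 5, seed = s)
    abs(input_resistance(swn, 5) - R) / R
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("IV curve slope conductance and input resistance", {
  sws <- lapply(seq(-40, 40, 20), function(v)
    gen_passive_sweep(100, 20, step = v, mode = "vclamp"))
  iv <- iv_curve(sws)
  expect_equal(iv$slope_conductance, 10, tolerance = 0.005)
  expect_equal(iv$r_input, 100, tolerance = 0.005)
  swsn <- lapply(seq(-40, 40, 20), function(v)
    gen_passive_sweep(50, 20, step = v, mode = "vclamp", noise_sd = 10,
                      seed = round(v) + 50))
  expect_equal(iv_curve(swsn)$r_input, 50, tolerance = 0.05)
  expect_error(iv_curve(sws[1]), "insufficient")
})

test_that("spike detection: flat and subthreshold traces yield none", {
  t <- seq(0, 500, 0.05)
  flat <- sweep_record(t, rep(-70, length(t)), mode = "cclamp",
                       step_window = c(100, 400))
  expect_equal(nrow(detect_spikes(flat)), 0)
  # 5 mV bump rising at 2 mV/ms stays under the 10 mV/ms criterion
  v <- rep(-70, length(t))
  ramp <- t >= 200 & t < 202.5
  v[ramp] <- -70 + 2 * (t[ramp] - 200)
  v[t >= 202.5] <- -65
  bump <- sweep_record(t, v, mode = "cclamp", step_window = c(100, 400))
  expect_equal(nrow(detect_spikes(bump)), 0)
})

test_that("spike detection finds generated template trains at known times", {
  tr <- gen_ap_train(7, 10, 20)
  sp <- detect_spikes(tr)
  expect_equal(nrow(sp), 7)
  expect_lte(max(abs(sp$peak_t - attr(tr, "ground_truth")$peak_times)),
             tr$dt)
})

test_that("AP features follow the study conventions", {
  amps <- seq(0, 440, 40)
  sws <- lapply(amps, function(a) {
    if (a < 240) gen_ap_train(0, step_pa = a)
    else gen_ap_train(3 + (a - 240) / 40, 10, 20, step_pa = a)
  })
  f <- ap_features(sws, amps)
  expect_equal(f$rheobase, 200)               # step before first spiking
  expect_equal(f$rheobase_first_spiking, 240)
  expect_equal(f$adaptation, 2.0)             # 20 ms / 10 ms at the top step
  expect_equal(f$overshoot, 20)
  expect_equal(f$half_width, 1.5, tolerance = 1e-6)
  expect_equal(f$ahp, 5, tolerance = 0.01)
  expect_equal(f$max_frequency, 8 / 0.5)      # 8 spikes in the 500 ms step

  # 30 spikes in 500 ms at the top step = 60 Hz
  sws30 <- lapply(amps, function(a) {
    if (a < 240) gen_ap_train(0, step_pa = a)
    else gen_ap_train(30, 15, 15, step_pa = a)
  })
  expect_equal(ap_features(sws30, amps)$max_frequency, 60)

  # no spiking step: spike features are NA, not errors
  quiet <- lapply(amps, function(a) gen_ap_train(0, step_pa = a))
  fq <- ap_features(quiet, amps)
  expect_true(is.na(fq$rheobase) && is.na(fq$half_width) &&
                is.na(fq$adaptation))
  expect_equal(fq$max_frequency, 0)
})

test_that("AP features are invariant to a uniform time shift", {
  amps <- c(0, 40, 80)
  mk <- function(shift) lapply(amps, function(a) {
    sw <- if (a < 40) gen_ap_train(0, step_pa = a)
          else gen_ap_train(4, 10, 16, step_pa = a)
    sweep_record(sw$time + shift, sw$primary, sw$command, mode = "cclamp",
                 step_window = sw$step_window + shift)
  })
  f0 <- ap_features(mk(0), amps)
  f1 <- ap_features(mk(250), amps)
  for (k in c("rheobase", "adaptation", "overshoot", "half_width",
              "max_frequency"))
    expect_equal(f0[[k]], f1[[k]])
})

test_that("rheobase is monotone when an earlier step gains spikes", {
  amps <- seq(0, 440, 40)
  mk <- function(first_spiking) lapply(amps, function(a) {
    if (a < first_spiking) gen_ap_train(0, step_pa = a)
    else gen_ap_train(4, 10, 20, step_pa = a)
  })
  f_late <- ap_features(mk(280), amps)
  f_early <- ap_features(mk(160), amps)
  expect_lt(f_early$rheobase, f_late$rheobase)
})

test_that("the triangle half-width matches the analytic crossing times", {
  # rise 1 ms, fall 2 ms, threshold -40, peak +20: half level -10 mV is
  # crossed 0.5 ms into the rise and 1 ms into the fall
  tr <- gen_ap_train(1, 10, 10, threshold_mv = -40, peak_mv = 20,
                     rise_ms = 1, fall_ms = 2)
  sp <- detect_spikes(tr)
  hw <- gliaquant:::.spike_half_width(tr, sp$onset_idx[1], sp$peak_idx[1])
  expect_equal(hw, 1.5, tolerance = 1e-9)
})

test_that("sIPSC detection rejects flat noise and recovers generated trains", {
  fp <- vapply(1:20, function(s) {
    tw <- gen_sipsc_trace(0, noise_sd = 2, duration_s = 10, seed = s)
    nrow(detect_sipscs(tw, amp_threshold = 10))
  }, numeric(1))
  expect_gte(sum(fp == 0), 19)

  tr <- gen_sipsc_trace(2, 50, 10, 60, noise_sd = 2, seed = 7)  # SNR 25
  ev <- detect_sipscs(tr)
  st <- event_stats(ev)
  gt <- attr(tr, "ground_truth")
  expect_lt(abs(st$frequency - gt$n_events / 60) / (gt$n_events / 60), 0.10)
  expect_lt(abs(st$mean_amplitude - 50) / 50, 0.10)
  expect_lt(abs(st$mean_decay - 10) / 10, 0.15)
})

test_that("an ideal exponential event is fitted to its true tau", {
  base <- gen_sipsc_trace(0, duration_s = 2, seed = 1)
  x <- base$primary
  t <- base$time
  x[t >= 500] <- x[t >= 500] - 50 * exp(-(t[t >= 500] - 500) / 10)
  sw <- sweep_record(t, x, mode = "vclamp")
  ev <- detect_sipscs(sw)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$decay_tau, 10, tolerance = 0.01)
  expect_equal(ev$amplitude, 50, tolerance = 0.01)
})

test_that("event statistics average per sweep then across sweeps", {
  mk_events <- function(n, amp, dur) {
    e <- data.frame(onset_t = seq_len(n), peak_t = seq_len(n),
                    amplitude = rep(amp, n), decay_tau = rep(10, n))
    attr(e, "duration_s") <- dur
    class(e) <- c("event_list", class(e))
    e
  }
  one <- event_stats(mk_events(120, 50, 60))
  expect_equal(one$frequency, 2)
  grand <- event_stats(list(mk_events(10, 40, 60), mk_events(30, 60, 60)))
  expect_equal(grand$mean_amplitude, 50)       # per-sweep means 40 and 60
  empty <- event_stats(mk_events(0, 0, 60))
  expect_equal(empty$frequency, 0)
  expect_true(is.na(empty$mean_amplitude))
})
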