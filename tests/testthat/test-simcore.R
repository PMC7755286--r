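test_that("trial schedule places cues on the sample clock with exact spacing", {
  cfg <- sim_config(n_trials = 90, seed = 5)
  sch <- build_trial_schedule(cfg, 5)
  fs <- attr(sch, "sampling_rate")

  expect_equal(nrow(sch), 90)
  expect_true(all(sch$condition %in% c("Free", "Instructed", "Control")))
  expect_true(all(sch$delay_ms %in% c(3750, 5750, 7750)))
  # cue2 - cue1 is exactly (cue duration + delay) converted to samples
  expect_identical(sch$cue2_onset - sch$cue1_onset,
                   ms_to_samples(250 + sch$delay_ms, fs))
  # counts within the binomial 99% band around n/3
  band <- qbinom(c(0.005, 0.995), 90, 1/3)
  expect_true(all(table(sch$condition) >= band[1] & table(sch$condition) <= band[2]))

  expect_identical(build_trial_schedule(cfg, 5), sch)       # seeded determinism
  empty <- build_trial_schedule(sim_config(n_trials = 0), 1)
  expect_equal(nrow(empty), 0)
  expect_error(sim_config(condition_probs = c(Free = 0.5, Instructed = 0.5,
                                              Control = 0.5)), "sum to 1")
  expect_error(sim_config(delays_ms = numeric(0)), "delay set")
})

test_that("condition and delay frequencies converge to configured probabilities", {
  cfg <- sim_config(n_trials = 900)
  ok_cond <- ok_delay <- logical(20)
  for (i in 1:20) {
    sch <- build_trial_schedule(cfg, 100 + i)
    ok_cond[i] <- chisq.test(table(sch$condition))$p.value > 0.01
    ok_delay[i] <- chisq.test(table(sch$delay_ms))$p.value > 0.01
  }
  expect_gte(sum(ok_cond), 19)
  expect_gte(sum(ok_delay), 19)
})

test_that("recording synthesis is bit-reproducible and honours degenerate configs", {
  cfg <- quiet_cfg(n_trials = 6, seed = 9)
  sim1 <- simulate_participant(cfg, 9)
  sim2 <- simulate_participant(cfg, 9)
  expect_identical(sim1$recording$signal, sim2$recording$signal)
  expect_identical(sim1$trials, sim2$trials)
  expect_identical(sim1$ground_truth, sim2$ground_truth)

  silent <- quiet_cfg(n_trials = 4, seed = 2,
                      noise = noise_spec(broadband_scale = 0, oscillations = list()),
                      effects = list())
  sch <- build_trial_schedule(silent, 2)
  out <- synthesize_recording(sch, silent, 2)
  expect_true(all(out$recording$signal == 0))

  # ground-truth effect map keys are exactly the configured effect channels
  eff_ch <- sort(unique(vapply(cfg$effects, function(e) e$channel, numeric(1))))
  expect_setequal(names(sim1$ground_truth$effect_map), paste0("site", eff_ch))
})

test_that("effect specification invariants are enforced", {
  expect_error(effect_spec("Free", "sustained", rel_amplitude = -1.2,
                           duration_ms = 100), "-1")
  expect_error(effect_spec("Free", "sustained", rel_amplitude = 0.2,
                           duration_ms = 0), "positive")
  expect_error(effect_spec("Free", "transient", rel_amplitude = 0.2,
                           duration_ms = 100), "peak_latency")
  expect_error(sim_config(n_channels = 2,
                          effects = list(list(channel = 7,
                                              spec = effect_spec("Free", "sustained",
                                                                 0.2, 100)))),
               "out of range")
})

test_that("EOG deflections encode direction, follow RT distributions and spare the delay", {
  cfg <- quiet_cfg(n_channels = 1, n_trials = 60, seed = 31, effects = list(),
                   exclusion_fraction = 0)
  sim <- simulate_participant(cfg, 31)
  fs <- sim$eog$sampling_rate
  h <- sim$eog$signal[1, ]
  tr <- sim$trials

  # latencies written back, truncated at zero, near the configured means
  expect_false(anyNA(tr$saccade_latency_ms))
  expect_true(all(tr$saccade_latency_ms > 0))
  free_rt <- tr$saccade_latency_ms[tr$condition == "Free"]
  expect_lt(abs(mean(free_rt) - 334), 3 * 36 / sqrt(length(free_rt)) + 10)

  for (i in seq_len(nrow(tr))) {
    post <- h[(tr$cue2_onset[i] + ms_to_samples(tr$saccade_latency_ms[i] + 100, fs)):
                (tr$cue2_onset[i] + ms_to_samples(tr$saccade_latency_ms[i] + 300, fs))]
    expected_sign <- if (tr$direction[i] == "L") -1 else 1
    expect_gt(expected_sign * mean(post), 100)     # deflection in the right direction
    delay_seg <- h[(tr$cue1_onset[i] + ms_to_samples(300, fs)):
                     (tr$cue2_onset[i] - ms_to_samples(100, fs))]
    expect_lt(max(abs(delay_seg)), cfg$eog_amplitude_au / 2)  # quiet delay period
  }
})

test_that("trial table and recording round-trip through plain-text writers", {
  cfg <- quiet_cfg(n_channels = 2, n_trials = 5, seed = 4)
  sim <- simulate_participant(cfg, 4)
  td <- withr::local_tempdir()

  p <- write_trial_table(sim$trials, file.path(td, "trials.tsv"))
  back <- read_trial_table(p, cfg$sampling_rate)
  expect_equal(back$cue1_onset, sim$trials$cue1_onset)
  expect_equal(back$cue2_onset, sim$trials$cue2_onset)
  expect_equal(back$saccade_latency_ms, sim$trials$saccade_latency_ms)
  expect_equal(back$condition, sim$trials$condition)

  short <- new_recording(sim$recording$signal[, 1:200, drop = FALSE],
                         cfg$sampling_rate, sim$recording$channel_labels)
  pre <- write_recording(short, file.path(td, "rec"))
  rec2 <- read_recording(pre)
  expect_equal(rec2$signal, short$signal, tolerance = 1e-6)
  expect_identical(rec2$channel_labels, short$channel_labels)

  gt_path <- write_ground_truth(sim$ground_truth, file.path(td, "gt.json"))
  gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  expect_equal(gt$saccade_latency_ms, sim$ground_truth$saccade_latency_ms,
               tolerance = 1e-9)
})
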