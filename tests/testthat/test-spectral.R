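test_that("bipolar re-referencing derives adjacent-contact differences", {
  set.seed(1)
  sig <- matrix(rnorm(4 * 1000), 4, 1000)
  rec <- new_recording(sig, 512, c("c1", "c2", "c3", "c4"))
  bp <- bipolar_rereference(rec, list(shaft = c("c1", "c2", "c3", "c4")))
  expect_equal(nrow(bp$signal), 3)                     # k contacts -> k-1 derivations
  expect_identical(bp$channel_labels, c("c2-c1", "c3-c2", "c4-c3"))
  expect_equal(bp$signal["c2-c1", ], sig[2, ] - sig[1, ])

  # common-mode signal cancels exactly
  common <- sin(seq_len(1000) / 10)
  rec2 <- new_recording(sweep(sig, 2, common, `+`), 512, rec$channel_labels)
  bp2 <- bipolar_rereference(rec2, list(shaft = c("c1", "c2", "c3", "c4")))
  expect_equal(bp2$signal, bp$signal)

  expect_error(bipolar_rereference(rec, list(shaft = c("c1", "cX"))), "missing")
  expect_error(bipolar_rereference(rec, list(shaft = "c1")), "2 contacts")
})

test_that("band envelopes recover amplitudes and reject stop-band energy", {
  fs <- 1024
  t <- seq(0, 3, by = 1 / fs)
  inner <- function(env) {
    e <- attr(env, "edge_samples")
    env[(e + 1):(length(env) - e)]
  }

  env <- band_envelope(2 * sin(2 * pi * 100 * t), c(60, 140), fs)
  expect_lt(max(abs(inner(env) - 2) / 2), 0.05)        # pass band within 5%

  leak <- band_envelope(sin(2 * pi * 5 * t), c(60, 140), fs)
  expect_lt(max(inner(leak)), 0.02)                    # stop band < 2%

  # superposition: 6 Hz amp 1 + 100 Hz amp 3 separates into theta and HG
  x <- sin(2 * pi * 6 * t) + 3 * sin(2 * pi * 100 * t)
  th <- band_envelope(x, c(4, 8), fs)
  hgv <- band_envelope(x, c(60, 140), fs)
  expect_lt(max(abs(inner(th) - 1)), 0.1)
  expect_lt(max(abs(inner(hgv) - 3) / 3), 0.05)

  # homogeneity: envelope of a*x equals a*envelope(x)
  e1 <- band_envelope(x, c(60, 140), fs)
  e3 <- band_envelope(3 * x, c(60, 140), fs)
  expect_equal(as.numeric(e3), 3 * as.numeric(e1), tolerance = 1e-9)

  expect_error(band_envelope(x, c(400, 600), fs), "Nyquist")
})

test_that("windowed power follows the floor((span-window)/step)+1 grid", {
  fs <- 1000
  env <- rep(2, 5000)
  wp <- windowed_power(env, fs, 400, 50, c(0, 3000), ref_sample = 1)
  expect_length(wp, 53)
  expect_true(all(abs(wp - 2) < 1e-12))
  expect_equal(attr(wp, "centers_ms")[1:3], c(200, 250, 300))

  # step = window -> disjoint block means
  env2 <- rep(c(1, 3), each = 500)
  bp <- windowed_power(env2, fs, 500, 500, c(0, 1000))
  expect_equal(as.numeric(bp), c(1, 3))

  # commutes with constant scaling
  set.seed(3)
  env3 <- abs(rnorm(5000))
  expect_equal(as.numeric(windowed_power(5 * env3, fs, 400, 100, c(0, 2000))),
               5 * as.numeric(windowed_power(env3, fs, 400, 100, c(0, 2000))))

  expect_error(windowed_power(env, fs, 400, 0, c(0, 3000)), "positive")
  expect_error(windowed_power(env, fs, 400, 50, c(0, 300)), "span")
})

test_that("baseline normalization yields relative change and flags degenerate baselines", {
  v <- array(10, c(2, 1, 3, 12))
  v[1, 1, 1, 9:12] <- 15
  v[2, 1, 2, ] <- 0                              # degenerate baseline trial
  centers <- seq(-300, by = 50, length.out = 12)  # windows [-500,-100) ... on a 400/50 grid
  tens <- power_tensor(v, centers, 400, 50, "cue1")
  norm <- baseline_normalize(tens, c(-500, -100))
  expect_equal(norm$values[1, 1, 1, 9], 0.5)     # (15 - 10) / 10
  expect_equal(norm$values[1, 1, 1, 1], 0)       # value equal to baseline -> 0
  expect_true(all(is.na(norm$values[2, 1, 2, ])))
  flagged <- attr(norm, "flagged")
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$trial, 2)
  expect_true(norm$normalized)

  no_base <- power_tensor(v, centers + 1000, 400, 50, "cue1")
  expect_error(baseline_normalize(no_base, c(-500, -100)), "baseline windows")
})

test_that("epoching aligns trials on both cues with a common grid", {
  cfg <- quiet_cfg(n_channels = 2, n_trials = 12, seed = 13)
  sim <- simulate_participant(cfg, 13)
  hg <- default_bands()[5, ]

  tens <- epoch_features(sim$recording, sim$trials, default_bands()[c(1, 5), ],
                         "cue1", c(-500, 2500), 400, 50)
  expect_equal(dim(tens$values), c(2, 2, 12, 53))
  expect_equal(tens$window_centers_ms[1], -300)

  # cue2 alignment with a negative span: identical grid across mixed delays
  late <- epoch_features(sim$recording, sim$trials, hg, "cue2", c(-2000, 0), 400, 50)
  expect_equal(dim(late$values)[4], 33)
  expect_true(length(unique(sim$trials$delay_ms)) > 1)
  expect_equal(late$window_centers_ms, seq(-1800, -200, by = 50))

  # the 60/10 ms single-trial display grid is served by the same operation
  fine <- epoch_features(sim$recording, sim$trials, hg, "cue1", c(0, 600), 60, 10)
  expect_equal(dim(fine$values)[4], 55)

  # excluded trials are dropped from the tensor
  tr2 <- sim$trials
  tr2$included[1:2] <- FALSE
  t2 <- epoch_features(sim$recording, tr2, hg, "cue1", c(-500, 2500))
  expect_equal(dim(t2$values)[3], 10)
  expect_identical(t2$trial_index, tr2$trial[tr2$included])

  bad <- sim$trials
  bad$cue1_onset[1] <- ncol(sim$recording$signal)
  expect_error(epoch_features(sim$recording, bad, hg, "cue1", c(-500, 2500)),
               "bounds")
})

test_that("injected relative amplitude is recovered through the spectral chain", {
  # high SNR: broadband background nearly off; Instructed transient +39% @ 475 ms
  eff <- list()
  for (ch in 1:4) eff <- c(eff, list(list(
    channel = ch, spec = effect_spec("Instructed", "transient", 0.39, 600,
                                     onset_ms = 150, peak_latency_ms = 475))))
  cfg <- quiet_cfg(n_channels = 4, n_trials = 60, seed = 17,
                   noise = noise_spec(broadband_scale = 0.02, oscillations = list()),
                   effects = eff, exclusion_fraction = 0)
  sim <- simulate_participant(cfg, 17)
  hg <- default_bands()[5, ]
  tens <- epoch_features(sim$recording, sim$trials, hg, "cue1",
                         c(-500, 2500), 160, 20)
  norm <- baseline_normalize(tens, c(-500, -100))
  instr <- sim$trials$condition == "Instructed"
  expect_gt(sum(instr), 10)
  avg <- apply(norm$values[, 1, instr, , drop = FALSE], 4, mean)
  pk <- peak_metrics(avg, tens$window_centers_ms, c(0, 1500))
  expect_lt(abs(pk$peak_rel_amplitude - 0.39), 0.039)   # within 10%
  expect_lt(abs(pk$peak_latency_ms - 475), 60)
  # control trials carry no delay-period modulation
  ctrl_avg <- apply(norm$values[, 1, sim$trials$condition == "Control", ,
                                drop = FALSE], 4, mean)
  expect_lt(max(abs(ctrl_avg[tens$window_centers_ms > 0 &
                               tens$window_centers_ms < 1500])), 0.1)
})
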