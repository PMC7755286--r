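# Domain types and the seeded synthetic-data generator.
#
# The generator emulates a delayed oculomotor decision task: three interleaved
# trial types (Free, Instructed, Control) at equal probability, a 250 ms
# directional/choice cue (Cue 1), a variable delay of 3750/5750/7750 ms, a go
# signal (Cue 2), and a saccade whose latency depends on the condition.
# Condition- and site-specific band-envelope effects (transient, sustained,
# persistent, execution-locked) are injected multiplicatively on band-limited
# carriers riding on a 1/f background, and every injected parameter is
# recorded in a ground-truth object so downstream modules can be tested by
# parameter recovery.

# ---- Recording ------------------------------------------------------------

#' Construct a multichannel recording
#'
#' A recording is a channels x samples signal matrix with channel labels and a
#' sampling rate. Sample indices are 1-based; all timing columns of the trial
#' table refer to this clock.
#'
#' @param signal numeric matrix, channels x samples (amplitude, a.u.)
#' @param sampling_rate sampling rate in Hz (default 1024)
#' @param channel_labels character vector, one per channel
#' @param participant_id participant label
#' @return an object of class `fs_recording`
#' @export
new_recording <- function(signal, sampling_rate = 1024, channel_labels = NULL,
                          participant_id = "P01") {
  .assert(is.matrix(signal) && is.numeric(signal), "`signal` must be a numeric matrix")
  .assert(sampling_rate > 0, "`sampling_rate` must be positive")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(signal)))
  .assert(length(channel_labels) == nrow(signal),
          "one channel label per signal row is required")
  rownames(signal) <- channel_labels
  structure(list(participant_id = participant_id,
                 channel_labels = channel_labels,
                 signal = signal,
                 sampling_rate = sampling_rate),
            class = "fs_recording")
}

#' @export
print.fs_recording <- function(x, ...) {
  cat(sprintf("<fs_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate))
  invisible(x)
}

# ---- Effect and noise specifications --------------------------------------

#' Specify a condition-specific band-envelope effect
#'
#' Shapes: `"transient"` is a Gaussian bump (sd = duration/4) centred at
#' `peak_latency_ms`; `"sustained"` is a smoothed plateau from `onset_ms`
#' lasting `duration_ms`; `"persistent"` is a plateau from `onset_ms` up to the
#' go signal, whatever the delay; `"execution"` is a ramp-then-plateau locked,
#' per trial, to the saccade latency (plus `onset_ms` offset and Gaussian
#' jitter with sd `onset_jitter_sd_ms`).
#'
#' @param conditions character vector of target conditions
#'   (subset of Free/Instructed/Control)
#' @param shape one of "transient", "sustained", "persistent", "execution"
#' @param rel_amplitude peak envelope modulation as a fraction of baseline
#'   (e.g. 0.39 for +39%); must exceed -1
#' @param duration_ms effect duration in ms (> 0)
#' @param onset_ms effect onset in ms relative to the alignment event
#' @param peak_latency_ms transient peak latency in ms (transient shape only)
#' @param band frequency band carrying the effect, c(f_low, f_high) in Hz
#' @param align alignment event, "cue1" or "cue2" ("execution" implies cue2)
#' @param onset_jitter_sd_ms per-trial onset jitter sd (execution shape)
#' @return an object of class `fs_effect`
#' @export
effect_spec <- function(conditions, shape, rel_amplitude, duration_ms,
                        onset_ms = 0, peak_latency_ms = NULL,
                        band = c(60, 140), align = c("cue1", "cue2"),
                        onset_jitter_sd_ms = 0) {
  shape <- match.arg(shape, c("transient", "sustained", "persistent", "execution"))
  align <- if (shape == "execution") "cue2" else match.arg(align)
  .assert(all(conditions %in% c("Free", "Instructed", "Control")),
          "conditions must be among Free/Instructed/Control")
  .assert(duration_ms > 0, "`duration_ms` must be positive")
  .assert(rel_amplitude > -1, "`rel_amplitude` must be > -1")
  if (shape == "transient")
    .assert(!is.null(peak_latency_ms), "transient effects need `peak_latency_ms`")
  structure(list(conditions = conditions, shape = shape,
                 rel_amplitude = rel_amplitude, duration_ms = duration_ms,
                 onset_ms = onset_ms, peak_latency_ms = peak_latency_ms,
                 band = band, align = align,
                 onset_jitter_sd_ms = onset_jitter_sd_ms),
            class = "fs_effect")
}

#' Specify the background noise model
#'
#' The background model is not constrained by any published value; the
#' defaults (1/f exponent 1, broadband scale 0.3 relative to the unit-RMS
#' effect carriers, a weak alpha oscillation) are stated assumptions, all
#' exposed here.
#'
#' @param one_over_f_exponent spectral exponent of the broadband background
#' @param broadband_scale sd of the broadband background (a.u.)
#' @param oscillations list of `list(band = c(lo, hi), amplitude = a)` entries;
#'   each contributes a sinusoid at the band centre with random phase
#' @param carrier_scale RMS of the band-limited carriers on effect channels
#' @return an object of class `fs_noise`
#' @export
noise_spec <- function(one_over_f_exponent = 1, broadband_scale = 0.3,
                       oscillations = list(list(band = c(8, 15), amplitude = 0.2)),
                       carrier_scale = 1) {
  .assert(broadband_scale >= 0, "`broadband_scale` must be >= 0")
  for (o in oscillations) .assert(o$amplitude >= 0, "oscillation amplitudes must be >= 0")
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 broadband_scale = broadband_scale,
                 oscillations = oscillations,
                 carrier_scale = carrier_scale),
            class = "fs_noise")
}

#' Default effect map calibrated to the study's printed dynamics
#'
#' Channels 1-4 carry an Instructed transient (+39% peaking at 475 ms) and a
#' Free sustained effect (+24%, onset 465 ms, 1200 ms duration, so the plateau
#' covers the 812 ms peak); channel 5 carries a persistent Free effect lasting
#' until the go cue; remaining channels are null during the delay. Every
#' channel receives an execution-locked response tied to the saccade latency.
#'
#' @param n_channels number of channels in the recording
#' @return list of `list(channel = i, spec = fs_effect)` entries
#' @export
default_effects <- function(n_channels = 8) {
  eff <- list()
  for (ch in seq_len(min(4, n_channels))) {
    eff <- c(eff, list(
      list(channel = ch,
           spec = effect_spec("Instructed", "transient", rel_amplitude = 0.39,
                              duration_ms = 600, onset_ms = 150,
                              peak_latency_ms = 475)),
      list(channel = ch,
           spec = effect_spec("Free", "sustained", rel_amplitude = 0.24,
                              duration_ms = 1200, onset_ms = 465))))
  }
  if (n_channels >= 5) {
    eff <- c(eff, list(
      list(channel = 5,
           spec = effect_spec("Free", "persistent", rel_amplitude = 0.24,
                              duration_ms = 1000, onset_ms = 465))))
  }
  for (ch in seq_len(n_channels)) {
    eff <- c(eff, list(
      list(channel = ch,
           spec = effect_spec(c("Free", "Instructed", "Control"), "execution",
                              rel_amplitude = 1, duration_ms = 400,
                              onset_ms = 0, onset_jitter_sd_ms = 30))))
  }
  eff
}

#' Simulation configuration
#'
#' Defaults echo the task parameters: three conditions at 33.3% each, delays
#' of 3750/5750/7750 ms drawn with equal probability, a 250 ms cue, a 1500 ms
#' intertrial interval, condition-specific saccade-latency distributions
#' (Control 466 +- 66 ms, Free 334 +- 36 ms, Instructed 321 +- 33 ms) and an
#' exclusion fraction calibrated so that roughly 75% of trials survive
#' behavioral filtering.
#'
#' @param n_participants number of simulated participants
#' @param n_channels number of recording sites per participant
#' @param n_trials number of trials per participant
#' @param condition_probs named probabilities for Free/Instructed/Control
#' @param delays_ms the set of delay durations in ms
#' @param cue_duration_ms cue presentation time in ms
#' @param response_window_ms time allotted after the go cue in ms
#' @param intertrial_ms blank intertrial gap in ms
#' @param pre_cue_ms lead time before each Cue 1 (covers the baseline window)
#' @param sampling_rate sampling rate in Hz
#' @param noise an [noise_spec()] object
#' @param effects effect map as produced by [default_effects()]
#' @param rt_params per-condition saccade latency mean/sd in ms
#' @param exclusion_fraction probability that a trial carries a spontaneous
#'   delay-period eye movement (and is hence excluded downstream)
#' @param eog_amplitude_au horizontal EOG deflection amplitude (a.u.)
#' @param eog_noise_sd EOG additive noise sd (a.u.)
#' @param seed default seed used when generator calls omit one
#' @return an object of class `fs_config`
#' @export
sim_config <- function(n_participants = 4,
                       n_channels = 8,
                       n_trials = 90,
                       condition_probs = c(Free = 1/3, Instructed = 1/3, Control = 1/3),
                       delays_ms = c(3750, 5750, 7750),
                       cue_duration_ms = 250,
                       response_window_ms = 1500,
                       intertrial_ms = 1500,
                       pre_cue_ms = 1000,
                       sampling_rate = 1024,
                       noise = noise_spec(),
                       effects = default_effects(n_channels),
                       rt_params = list(Control = c(mean = 466, sd = 66),
                                        Free = c(mean = 334, sd = 36),
                                        Instructed = c(mean = 321, sd = 33)),
                       exclusion_fraction = 0.25,
                       eog_amplitude_au = 150,
                       eog_noise_sd = 2,
                       seed = 1L) {
  .assert(abs(sum(condition_probs) - 1) < 1e-8, "condition probabilities must sum to 1")
  .assert(length(delays_ms) >= 1, "the delay set must not be empty")
  .assert(all(names(condition_probs) %in% c("Free", "Instructed", "Control")),
          "condition_probs must be named Free/Instructed/Control")
  for (p in rt_params) .assert(p[["mean"]] >= 0, "RT means must be non-negative")
  for (e in effects) .assert(e$channel >= 1 && e$channel <= n_channels,
                             "effect channel index out of range")
  structure(list(n_participants = n_participants, n_channels = n_channels,
                 n_trials = n_trials, condition_probs = condition_probs,
                 delays_ms = delays_ms, cue_duration_ms = cue_duration_ms,
                 response_window_ms = response_window_ms,
                 intertrial_ms = intertrial_ms, pre_cue_ms = pre_cue_ms,
                 sampling_rate = sampling_rate, noise = noise,
                 effects = effects, rt_params = rt_params,
                 exclusion_fraction = exclusion_fraction,
                 eog_amplitude_au = eog_amplitude_au,
                 eog_noise_sd = eog_noise_sd, seed = seed),
            class = "fs_config")
}

# ---- trial schedule -------------------------------------------------------

#' Lay trials out on the sample clock
#'
#' Conditions and delays are drawn with the configured probabilities, saccade
#' directions are fair coin flips, and each trial occupies
#' pre-cue + cue + delay + response window + fixation + intertrial gap. The
#' Cue 2 onset is exactly `cue_duration_ms + delay` after Cue 1 in samples.
#'
#' @param config an [sim_config()] object
#' @param seed integer seed (defaults to `config$seed`)
#' @return a tibble with one row per trial (class `fs_trials`); attributes
#'   carry the sampling rate and total recording length in samples
#' @export
build_trial_schedule <- function(config, seed = config$seed) {
  .assert(config$n_trials >= 0, "`n_trials` must be >= 0")
  fs <- config$sampling_rate
  n <- config$n_trials
  if (!is.null(seed)) set.seed(seed)
  conds <- names(config$condition_probs)
  condition <- if (n > 0) sample(conds, n, replace = TRUE, prob = config$condition_probs) else character(0)
  direction <- if (n > 0) sample(c("L", "R"), n, replace = TRUE) else character(0)
  delay_ms <- if (n > 0) sample(config$delays_ms, n, replace = TRUE) else numeric(0)

  cue1 <- integer(n); cue2 <- integer(n)
  cursor_ms <- 0
  for (i in seq_len(n)) {
    c1_ms <- cursor_ms + config$pre_cue_ms
    cue1[i] <- ms_to_samples(c1_ms, fs) + 1L
    cue2[i] <- cue1[i] + ms_to_samples(config$cue_duration_ms + delay_ms[i], fs)
    c2_ms <- c1_ms + config$cue_duration_ms + delay_ms[i]
    cursor_ms <- c2_ms + config$response_window_ms + 500 + config$intertrial_ms
  }
  dur <- ms_to_samples(cursor_ms + config$pre_cue_ms, fs) + 1L

  out <- tibble::tibble(trial = seq_len(n),
                        condition = condition,
                        direction = direction,
                        cue1_onset = cue1,
                        delay_ms = delay_ms,
                        cue2_onset = cue2,
                        saccade_latency_ms = rep(NA_real_, n),
                        included = rep(TRUE, n))
  attr(out, "sampling_rate") <- fs
  attr(out, "duration_samples") <- dur
  class(out) <- c("fs_trials", class(out))
  out
}

# ---- noise / carrier primitives -------------------------------------------

# 1/f^a shaped Gaussian noise, unit sd, length n
.colored_noise <- function(n, exponent) {
  if (n == 0) return(numeric(0))
  nf <- nextn(max(n, 2), 2)
  w <- rnorm(nf)
  if (exponent == 0) return(w[seq_len(n)])
  spec <- fft(w)
  idx <- 0:(nf - 1)
  f <- pmin(idx, nf - idx)                      # |frequency| per bin, DC guarded below
  f[1] <- 1
  spec <- spec * f^(-exponent / 2)
  spec[1] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / nf
  x <- x / sd(x)
  x[seq_len(n)]
}

# band-limited Gaussian noise, unit RMS
.bandlimited_noise <- function(n, band, fs) {
  x <- .filter_zerophase(rnorm(n), .fir_bandpass(band, fs))
  x / sqrt(mean(x^2))
}

# raised-cosine edged plateau on [a, b] with ramp length `ramp` (ms units)
.smooth_plateau <- function(t, a, b, ramp = 100) {
  s <- numeric(length(t))
  up <- t >= a & t < a + ramp
  s[up] <- 0.5 * (1 - cos(pi * (t[up] - a) / ramp))
  s[t >= a + ramp & t < b] <- 1
  dn <- t >= b & t < b + ramp
  s[dn] <- 0.5 * (1 + cos(pi * (t[dn] - b) / ramp))
  s
}

# shape profile s(t) in [0,1]; t_ms relative to the alignment event
.shape_profile <- function(t_ms, spec, go_ms = NULL, onset_override = NULL) {
  switch(spec$shape,
    transient  = exp(-((t_ms - spec$peak_latency_ms)^2) / (2 * (spec$duration_ms / 4)^2)),
    sustained  = .smooth_plateau(t_ms, spec$onset_ms, spec$onset_ms + spec$duration_ms),
    persistent = .smooth_plateau(t_ms, spec$onset_ms, go_ms),
    execution  = .smooth_plateau(t_ms, onset_override, onset_override + spec$duration_ms,
                                 ramp = 40))
}

# ---- recording synthesis --------------------------------------------------

#' Synthesize a multichannel LFP-like recording with injected effects
#'
#' Background is 1/f-shaped broadband noise plus configured oscillations.
#' Channels listed in the effect map additionally receive a band-limited
#' unit-RMS carrier whose envelope is modulated multiplicatively,
#' `carrier * (1 + sum_j a_j s_j(t))`, time-locked to Cue 1 or Cue 2 of each
#' trial of the targeted conditions. The returned ground truth records the
#' effect map, the per-trial true execution HG onset (saccade latency + offset
#' + jitter), and the latencies used.
#'
#' @param schedule trial table from [build_trial_schedule()]; execution-locked
#'   effects use its `saccade_latency_ms` (condition means are substituted for
#'   missing latencies)
#' @param config an [sim_config()] object
#' @param seed integer seed
#' @return `list(recording, ground_truth)`
#' @export
synthesize_recording <- function(schedule, config, seed = config$seed) {
  fs <- config$sampling_rate
  n_samp <- attr(schedule, "duration_samples")
  .assert(!is.null(n_samp), "schedule lacks a duration attribute")
  if (nrow(schedule) > 0)
    .assert(max(schedule$cue2_onset) + ms_to_samples(config$response_window_ms, fs) <= n_samp,
            "schedule does not fit within the synthesized duration")
  if (!is.null(seed)) set.seed(seed)

  lat <- schedule$saccade_latency_ms
  if (nrow(schedule) > 0 && anyNA(lat)) {
    for (cond in names(config$rt_params))
      lat[is.na(lat) & schedule$condition == cond] <- config$rt_params[[cond]][["mean"]]
  }

  # one execution-onset truth per trial, shared by all channels
  exec_specs <- Filter(function(e) e$spec$shape == "execution", config$effects)
  hg_onset <- rep(NA_real_, nrow(schedule))
  if (length(exec_specs) > 0 && nrow(schedule) > 0) {
    sp <- exec_specs[[1]]$spec
    hg_onset <- lat + sp$onset_ms + rnorm(nrow(schedule), 0, sp$onset_jitter_sd_ms)
    hg_onset <- pmax(hg_onset, 0)
  }

  sig <- matrix(0, config$n_channels, n_samp)
  for (ch in seq_len(config$n_channels)) {
    x <- numeric(n_samp)
    if (config$noise$broadband_scale > 0)
      x <- config$noise$broadband_scale *
        .colored_noise(n_samp, config$noise$one_over_f_exponent)
    for (o in config$noise$oscillations) {
      if (o$amplitude <= 0) next
      fc <- mean(o$band)
      x <- x + o$amplitude * sin(2 * pi * fc * seq_len(n_samp) / fs + runif(1, 0, 2 * pi))
    }
    sig[ch, ] <- x
  }

  # group effect specs by (channel, band) so each group shares one carrier
  eff <- config$effects
  if (length(eff) > 0 && nrow(schedule) > 0) {
    keys <- vapply(eff, function(e) paste(e$channel, paste(e$spec$band, collapse = "-")),
                   character(1))
    for (key in unique(keys)) {
      grp <- eff[keys == key]
      ch <- grp[[1]]$channel
      band <- grp[[1]]$spec$band
      gain <- rep(1, n_samp)
      for (e in grp) {
        sp <- e$spec
        for (i in seq_len(nrow(schedule))) {
          if (!(schedule$condition[i] %in% sp$conditions)) next
          align <- if (sp$align == "cue1") schedule$cue1_onset[i] else schedule$cue2_onset[i]
          go_ms <- config$cue_duration_ms + schedule$delay_ms[i]
          span_ms <- if (sp$align == "cue1") c(0, go_ms + 200) else
            c(0, config$response_window_ms + 200)
          i0 <- align + ms_to_samples(span_ms[1], fs)
          i1 <- min(align + ms_to_samples(span_ms[2], fs), n_samp)
          idx <- i0:i1
          t_ms <- (idx - align) * 1000 / fs
          gain[idx] <- gain[idx] + sp$rel_amplitude *
            .shape_profile(t_ms, sp, go_ms = go_ms, onset_override = hg_onset[i])
        }
      }
      carrier <- config$noise$carrier_scale * .bandlimited_noise(n_samp, band, fs)
      sig[ch, ] <- sig[ch, ] + carrier * gain
    }
  }

  rec <- new_recording(sig, fs, paste0("site", seq_len(config$n_channels)))
  gt <- structure(list(
    effect_map = split(lapply(eff, `[[`, "spec"),
                       vapply(eff, function(e) paste0("site", e$channel), character(1))),
    hg_onset_ms = hg_onset,
    saccade_latency_ms = schedule$saccade_latency_ms,
    delay_artifact = attr(schedule, "delay_artifact") %||% rep(FALSE, nrow(schedule))),
    class = "fs_ground_truth")
  list(recording = rec, ground_truth = gt)
}

# ---- EOG synthesis --------------------------------------------------------

#' Synthesize the EOG channel pair and draw saccade latencies
#'
#' Latencies are drawn per condition from truncated-at-zero normals and
#' written back into the trial table. Each trial receives a ramp-then-plateau
#' horizontal deflection starting at Cue 2 + latency, with sign encoding
#' direction (L negative, R positive). A configured fraction of trials
#' additionally receives a spontaneous deflection during the delay period,
#' emulating the trials that behavioral screening later rejects.
#'
#' @param schedule trial table from [build_trial_schedule()]
#' @param config an [sim_config()] object
#' @param seed integer seed
#' @return `list(eog, trials, delay_artifact)`: the 2-channel EOG recording,
#'   the trial table with `saccade_latency_ms` filled in (and the artifact
#'   flags attached as the `delay_artifact` attribute), and the flags
#' @export
synthesize_eog <- function(schedule, config, seed = config$seed) {
  fs <- config$sampling_rate
  n_samp <- attr(schedule, "duration_samples")
  n <- nrow(schedule)
  if (!is.null(seed)) set.seed(seed)

  lat <- schedule$saccade_latency_ms
  for (cond in names(config$rt_params)) {
    idx <- which(is.na(lat) & schedule$condition == cond)
    if (!length(idx)) next
    p <- config$rt_params[[cond]]
    .assert(p[["mean"]] >= 0, "negative RT mean")
    draw <- rnorm(length(idx), p[["mean"]], p[["sd"]])
    while (any(draw <= 0)) draw[draw <= 0] <- rnorm(sum(draw <= 0), p[["mean"]], p[["sd"]])
    lat[idx] <- draw
  }
  artifact <- runif(n) < config$exclusion_fraction

  amp <- config$eog_amplitude_au
  heog <- rnorm(n_samp, 0, config$eog_noise_sd)
  veog <- rnorm(n_samp, 0, config$eog_noise_sd)
  ramp_n <- ms_to_samples(40, fs)
  for (i in seq_len(n)) {
    sgn <- if (schedule$direction[i] == "L") -1 else 1
    on <- schedule$cue2_onset[i] + ms_to_samples(lat[i], fs)
    hold_n <- ms_to_samples(500, fs)
    seg <- on:min(on + ramp_n + hold_n, n_samp)
    prof <- c(seq(0, 1, length.out = ramp_n), rep(1, max(0, length(seg) - ramp_n)))
    heog[seg] <- heog[seg] + sgn * amp * prof[seq_along(seg)]
    if (artifact[i]) {
      lo <- schedule$cue1_onset[i] + ms_to_samples(600, fs)
      hi <- schedule$cue2_onset[i] - ms_to_samples(800, fs)
      a_on <- round(runif(1, lo, hi))
      a_len <- ms_to_samples(300, fs)
      aseg <- a_on:min(a_on + a_len, n_samp)
      aprof <- c(seq(0, 1, length.out = ramp_n),
                 rep(1, max(0, length(aseg) - 2 * ramp_n)),
                 seq(1, 0, length.out = ramp_n))
      heog[aseg] <- heog[aseg] + sample(c(-1, 1), 1) * amp * aprof[seq_along(aseg)]
    }
  }

  trials <- schedule
  trials$saccade_latency_ms <- lat
  attr(trials, "delay_artifact") <- artifact
  eog <- new_recording(rbind(heog, veog), fs, c("HEOG", "VEOG"),
                       participant_id = "EOG")
  list(eog = eog, trials = trials, delay_artifact = artifact)
}

# ---- participant / experiment wrappers ------------------------------------

#' Simulate one participant (schedule, EOG, recording, ground truth)
#'
#' @param config an [sim_config()] object
#' @param seed integer seed; sub-seeds for the schedule, EOG and recording are
#'   derived deterministically from it
#' @return `list(trials, eog, recording, ground_truth)`
#' @export
simulate_participant <- function(config, seed = config$seed) {
  sched <- build_trial_schedule(config, seed)
  eo <- synthesize_eog(sched, config, seed + 1L)
  rg <- synthesize_recording(eo$trials, config, seed + 2L)
  rg$ground_truth$saccade_latency_ms <- eo$trials$saccade_latency_ms
  rg$ground_truth$delay_artifact <- eo$delay_artifact
  list(trials = eo$trials, eog = eo$eog, recording = rg$recording,
       ground_truth = rg$ground_truth)
}

#' Simulate a cohort of participants
#'
#' @param config an [sim_config()] object
#' @param seed integer base seed; participant p uses `seed + 10 * (p - 1)`
#' @return list of [simulate_participant()] results
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  lapply(seq_len(config$n_participants), function(p)
    simulate_participant(config, seed + 10L * (p - 1L)))
}
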