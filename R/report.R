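# Contrast direction masks, conjunction analyses, early/late partition, and
# end-to-end pipeline orchestration.

#' Significance-and-direction mask for one contrast
#'
#' A site is flagged when any of its cells in the chosen band is significant
#' anywhere within the window; its direction is the sign of the mean power
#' difference (condition A - condition B) over the window across trials.
#'
#' @param result a `decoding_result` carrying a significance mask, computed on
#'   the same tensor grid
#' @param tensor the `fs_power` tensor the contrast was decoded on
#' @param labels per-trial condition labels aligned with the tensor
#' @param cond_a,cond_b the two conditions (direction is sign of A - B)
#' @param window_ms `c(start, stop)` ms interval (half-open) on the grid
#' @param band band name or index
#' @return a tibble (site, significant, sign) with contrast metadata in
#'   attributes; sign is "+", "-" or "0" and only meaningful for significant
#'   sites
#' @export
contrast_mask <- function(result, tensor, labels, cond_a, cond_b,
                          window_ms, band = "highgamma") {
  .assert(length(result$window_centers_ms) == length(tensor$window_centers_ms) &&
            all(result$window_centers_ms == tensor$window_centers_ms),
          "result and tensor are on different window grids")
  centers <- tensor$window_centers_ms
  win <- centers >= window_ms[1] & centers < window_ms[2]
  .assert(any(win), "window outside the tensor grid")
  sites <- dimnames(tensor$values)[[1]]
  sig <- vapply(seq_along(sites), function(s)
    any(result$sig_mask[s, band, win]), logical(1))
  va <- tensor$values[, band, labels == cond_a, win, drop = FALSE]
  vb <- tensor$values[, band, labels == cond_b, win, drop = FALSE]
  dmean <- apply(va, 1, mean) - apply(vb, 1, mean)
  sgn <- ifelse(dmean > 0, "+", ifelse(dmean < 0, "-", "0"))
  out <- tibble::tibble(site = sites, significant = sig, sign = sgn)
  attr(out, "contrast") <- paste(cond_a, "vs", cond_b)
  attr(out, "window_ms") <- window_ms
  attr(out, "alignment") <- tensor$alignment
  out
}

#' Conjunction of two contrast masks
#'
#' Sites significant in both masks with the required effect directions.
#'
#' @param mask_a,mask_b contrast masks over the same site universe
#' @param required_signs length-2 character, required sign in each mask
#' @return character vector of site labels
#' @export
conjunction_sites <- function(mask_a, mask_b, required_signs = c("+", "+")) {
  .assert(identical(mask_a$site, mask_b$site), "mismatched site universes")
  keep <- mask_a$significant & mask_a$sign == required_signs[1] &
    mask_b$significant & mask_b$sign == required_signs[2]
  mask_a$site[keep]
}

#' Partition conjunction sites into early-only, late-only and both
#'
#' @param conj_early sites from the early-window conjunction
#' @param conj_late sites from the late-window conjunction
#' @return `list(early_only, late_only, both)`; the three sets are disjoint
#'   and their union is the union of the inputs
#' @export
early_late_partition <- function(conj_early, conj_late) {
  list(early_only = setdiff(conj_early, conj_late),
       late_only = setdiff(conj_late, conj_early),
       both = intersect(conj_early, conj_late))
}

# ---- per-participant analysis ---------------------------------------------

# condition label per tensor trial
.tensor_conditions <- function(tensor, trials) {
  trials$condition[match(tensor$trial_index, trials$trial)]
}

#' Run the full analysis chain for one simulated participant
#'
#' EOG saccade detection and exclusions, reaction-time statistics, trial
#' history, delay- and execution-period feature extraction, Free/Instructed/
#' Control decoding with max-statistics, temporal generalization, dynamics
#' metrics, per-trial HG onsets and the early/late conjunction.
#'
#' @param sim output of [simulate_participant()]
#' @param n_perm,alpha permutation settings for the max-statistics
#' @param n_folds CV folds
#' @param seed integer seed for folds/permutations
#' @param rt_max_ms behavioral latency ceiling
#' @return a list of per-participant results (see the pipeline vignette)
#' @export
analyze_participant <- function(sim, n_perm = 100, alpha = 0.01, n_folds = 10,
                                seed = 1L, rt_max_ms = 750) {
  fs <- sim$recording$sampling_rate
  heog <- sim$eog$signal[1, ]

  trials <- sim$trials
  trials$saccade_latency_ms <- vapply(seq_len(nrow(trials)), function(i)
    detect_saccade_onset(heog, fs, trials$cue2_onset[i]), numeric(1))
  artifacts <- detect_delay_artifacts(sim$eog, trials)
  trials <- apply_trial_exclusions(trials, rt_max_ms, artifacts)

  rt <- compare_reaction_times(trials)
  free_dirs <- trials$direction[trials$included & trials$condition == "Free"]
  history <- if (length(free_dirs) >= 3) trial_history_test(free_dirs, seed = seed) else NULL

  bands <- default_bands()
  hg <- bands[bands$name == "highgamma", ]
  delay <- epoch_features(sim$recording, trials, bands, "cue1", c(-500, 2500), 400, 50)
  late <- epoch_features(sim$recording, trials, hg, "cue2", c(-2000, 0), 400, 50)
  exec_bins <- epoch_features(sim$recording, trials, hg, "cue2", c(-500, 1500), 60, 60)
  base_bins <- epoch_features(sim$recording, trials, hg, "cue1", c(-500, -80), 60, 60)

  conds <- .tensor_conditions(delay, trials)
  pick <- function(tensor, a, b) {
    keep <- which(conds %in% c(a, b))
    list(tensor = tensor_subset(tensor, trials = keep),
         labels = factor(conds[keep], levels = c(b, a)))
  }

  fi <- pick(delay, "Free", "Instructed")
  res_fi <- permutation_maxstat(fi$tensor, fi$labels, n_perm, alpha, n_folds, seed)
  delay_hg <- tensor_subset(delay, bands = "highgamma")
  fc <- pick(delay_hg, "Free", "Control")
  res_fc <- permutation_maxstat(fc$tensor, fc$labels, n_perm, alpha, n_folds, seed)
  ic <- pick(delay_hg, "Instructed", "Control")
  res_ic <- permutation_maxstat(ic$tensor, ic$labels, n_perm, alpha, n_folds, seed)

  fi_hg <- pick(delay_hg, "Free", "Instructed")
  ms_da <- multisite_decoding(fi_hg$tensor, fi_hg$labels, n_folds, seed)

  span <- c(0, 2500)
  win_in <- delay$window_centers_ms >= span[1] & delay$window_centers_ms < span[2]
  hg_i <- which(bands$name == "highgamma")
  sig_sites_fi <- which(apply(res_fi$sig_mask[, hg_i, win_in, drop = FALSE], 1, any))
  sig_sites_fc <- which(apply(res_fc$sig_mask[, 1, win_in, drop = FALSE], 1, any))
  sig_sites_ic <- which(apply(res_ic$sig_mask[, 1, win_in, drop = FALSE], 1, any))

  da_fi_hg <- res_fi$da[, hg_i, win_in, drop = FALSE]
  max_da <- if (length(sig_sites_fi)) max(da_fi_hg[sig_sites_fi, , ]) else NA_real_
  mean_da <- if (length(sig_sites_fi)) mean(apply(
    da_fi_hg[sig_sites_fi, 1, , drop = FALSE], 1, max)) else NA_real_

  # HG temporal dynamics: baseline-normalized averages over significant sites
  norm_hg <- baseline_normalize(delay_hg)
  peaks <- list(Instructed = NULL, Free = NULL)
  if (length(sig_sites_fi)) {
    for (cond in c("Instructed", "Free")) {
      avg <- apply(norm_hg$values[sig_sites_fi, 1, conds == cond, , drop = FALSE],
                   4, mean, na.rm = TRUE)
      peaks[[cond]] <- peak_metrics(avg, delay$window_centers_ms, span)
    }
  }

  onset_dur <- function(res, sites) {
    if (!length(sites)) return(list(onset = NA_real_, duration = NA_real_, peak = NA_real_))
    per <- lapply(sites, function(s) decoding_onset_duration(res, s, 1, span))
    list(onset = mean(vapply(per, `[[`, numeric(1), "decoding_onset_ms"), na.rm = TRUE),
         duration = mean(vapply(per, `[[`, numeric(1), "decoding_duration_ms")),
         peak = mean(vapply(per, `[[`, numeric(1), "peak_da_latency_ms")))
  }
  dyn_free <- onset_dur(res_fc, sig_sites_fc)
  dyn_instr <- onset_dur(res_ic, sig_sites_ic)

  tg <- if (length(sig_sites_fc))
    temporal_generalization(fc$tensor, fc$labels,
                            sites = sig_sites_fc[seq_len(min(6, length(sig_sites_fc)))],
                            band = 1, n_folds = n_folds, alpha = alpha, seed = seed)
  else NULL

  # per-trial execution HG onsets vs saccade latency, averaged across sites;
  # baseline statistics are pooled across trials (a 7-bin per-trial SD is too
  # unstable for the 2-SD rule) and the search is restricted to post-go bins
  exec_avg <- apply(exec_bins$values[, 1, , , drop = FALSE], c(3, 4), mean)
  base_avg <- apply(base_bins$values[, 1, , , drop = FALSE], c(3, 4), mean)
  bin_starts <- exec_bins$window_centers_ms - exec_bins$window_length_ms / 2
  post <- bin_starts >= 0
  onsets <- vapply(seq_len(nrow(exec_avg)), function(j)
    detect_hg_onset_trial(exec_avg[j, post], bin_starts[post],
                          mean(base_avg), sd(base_avg)), numeric(1))
  lat_inc <- trials$saccade_latency_ms[trials$included]
  onset_rt <- if (sum(complete.cases(onsets, lat_inc)) >= 3)
    correlate_hg_saccade_onsets(onsets, lat_inc) else NULL

  # conjunction: early [0, 2000) after cue1, late [-2000, 0) before cue2
  late_conds <- .tensor_conditions(late, trials)
  lfc <- pick(late, "Free", "Control")
  res_lfc <- permutation_maxstat(lfc$tensor, lfc$labels, n_perm, alpha, n_folds, seed)
  lfi <- pick(late, "Free", "Instructed")
  res_lfi <- permutation_maxstat(lfi$tensor, lfi$labels, n_perm, alpha, n_folds, seed)

  m_early_fc <- contrast_mask(res_fc, fc$tensor, as.character(fc$labels),
                              "Free", "Control", c(0, 2000), 1)
  m_early_fi <- contrast_mask(res_fi, fi$tensor, as.character(fi$labels),
                              "Free", "Instructed", c(0, 2000), "highgamma")
  m_late_fc <- contrast_mask(res_lfc, lfc$tensor, as.character(lfc$labels),
                             "Free", "Control", c(-2000, 0), 1)
  m_late_fi <- contrast_mask(res_lfi, lfi$tensor, as.character(lfi$labels),
                             "Free", "Instructed", c(-2000, 0), 1)
  conj_early <- conjunction_sites(m_early_fc, m_early_fi)
  conj_late <- conjunction_sites(m_late_fc, m_late_fi)
  partition <- early_late_partition(conj_early, conj_late)

  list(trials = trials, rt = rt, history = history,
       decoding = list(free_vs_instructed = res_fi, free_vs_control = res_fc,
                       instructed_vs_control = res_ic),
       multisite_da = ms_da,
       sig_sites = list(free_vs_instructed = sig_sites_fi,
                        free_vs_control = sig_sites_fc,
                        instructed_vs_control = sig_sites_ic),
       max_da = max_da, mean_da = mean_da,
       peaks = peaks, dyn_free = dyn_free, dyn_instructed = dyn_instr,
       generalization = tg, hg_onsets = onsets, onset_rt = onset_rt,
       conjunction = list(early = conj_early, late = conj_late,
                          partition = partition),
       window_centers_ms = delay$window_centers_ms)
}

# ---- pipeline --------------------------------------------------------------

.config_from_yaml <- function(path) {
  .assert(file.exists(path), paste("config file not found:", path))
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(sim_config)), c("noise", "effects", "rt_params"))
  extra <- setdiff(names(raw), c(allowed, "n_perm", "alpha"))
  .assert(length(extra) == 0,
          paste("unknown config field:", paste(extra, collapse = ", ")))
  args <- raw[names(raw) %in% allowed]
  if (!is.null(args$condition_probs)) args$condition_probs <- unlist(args$condition_probs)
  if (!is.null(args$delays_ms)) args$delays_ms <- unlist(args$delays_ms)
  list(config = do.call(sim_config, args),
       n_perm = raw$n_perm %||% 100, alpha = raw$alpha %||% 0.01)
}

#' Run the end-to-end pipeline and write a report directory
#'
#' Simulates the configured cohort, runs the per-participant analysis chain
#' ([analyze_participant()]), aggregates group-level paired t statistics
#' (reaction times, HG peak amplitude/latency, decoding onset and duration),
#' and writes TSV/JSON outputs plus a run log. Fully deterministic under the
#' seed; on error, partial outputs are removed.
#'
#' @param config an [sim_config()] object, or the path to a YAML file with
#'   scalar `sim_config` fields (plus optional `n_perm`, `alpha`)
#' @param seed integer master seed
#' @param out_dir output directory (created; must not be an existing
#'   non-empty directory unless `overwrite = TRUE`)
#' @param n_perm,alpha permutation settings (overridden by a YAML config)
#' @param overwrite allow writing into an existing directory
#' @return invisibly, the list of results (`participants`, `group`, paths)
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, out_dir = "freesacc-run",
                         n_perm = 100, alpha = 0.01, overwrite = FALSE) {
  if (is.character(config)) {
    cfg <- .config_from_yaml(config)
    n_perm <- cfg$n_perm; alpha <- cfg$alpha; config <- cfg$config
  }
  .assert(inherits(config, "fs_config"), "`config` must be an fs_config or a YAML path")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("`out_dir` exists and is not empty; set overwrite = TRUE", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- TRUE
  on.exit(if (created) unlink(out_dir, recursive = TRUE), add = TRUE)

  sims <- simulate_experiment(config, seed)
  results <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    res <- analyze_participant(sims[[p]], n_perm = n_perm, alpha = alpha,
                               seed = seed + 1000L * p)
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    write_trial_table(res$trials, file.path(pdir, "trials.tsv"))
    write.table(as.data.frame(res$rt$per_condition), file.path(pdir, "rt_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(res$rt$pairwise), file.path(pdir, "rt_pairwise.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .write_decoding_tsv(res$decoding$free_vs_instructed,
                        file.path(pdir, "decoding_free_vs_instructed.tsv"))
    .write_decoding_tsv(res$decoding$free_vs_control,
                        file.path(pdir, "decoding_free_vs_control.tsv"))
    .write_decoding_tsv(res$decoding$instructed_vs_control,
                        file.path(pdir, "decoding_instructed_vs_control.tsv"))
    if (!is.null(res$history))
      jsonlite::write_json(lapply(unclass(res$history), function(x)
        if (is.numeric(x) || is.logical(x)) as.list(x) else x),
        file.path(pdir, "history.json"), auto_unbox = TRUE, digits = NA,
        force = TRUE)
    conj <- res$conjunction$partition
    write.table(data.frame(site = unlist(conj, use.names = FALSE),
                           set = rep(names(conj), lengths(conj))),
                file.path(pdir, "conjunction.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results[[p]] <- res
  }

  group <- .group_stats(results)
  jsonlite::write_json(group, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(list(seed = seed, n_perm = n_perm, alpha = alpha,
                            n_participants = config$n_participants,
                            n_channels = config$n_channels,
                            n_trials = config$n_trials,
                            sampling_rate = config$sampling_rate,
                            package_version = as.character(utils::packageVersion("freesacc")),
                            r_version = R.version.string),
                       file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  created <- FALSE
  invisible(list(participants = results, group = group, out_dir = out_dir))
}

.write_decoding_tsv <- function(result, path) {
  d <- dim(result$da)
  grid <- expand.grid(site = dimnames(result$da)[[1]],
                      band = dimnames(result$da)[[2]],
                      window_center_ms = result$window_centers_ms,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$da <- as.vector(result$da)
  grid$significant <- as.vector(result$sig_mask)
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# group-level aggregation across participants: per-participant means compared
# with paired t tests in the directions reported for the task
.group_stats <- function(results) {
  g <- function(f) vapply(results, f, numeric(1))
  safe_mean <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  safe_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  rt_of <- function(cond) g(function(r) {
    pc <- r$rt$per_condition
    if (cond %in% pc$condition) pc$mean_ms[pc$condition == cond] else NA_real_
  })
  rt_c <- rt_of("Control"); rt_f <- rt_of("Free"); rt_i <- rt_of("Instructed")
  peak_lat_i <- g(function(r) r$peaks$Instructed$peak_latency_ms %||% NA_real_)
  peak_lat_f <- g(function(r) r$peaks$Free$peak_latency_ms %||% NA_real_)
  peak_amp_i <- g(function(r) r$peaks$Instructed$peak_rel_amplitude %||% NA_real_)
  peak_amp_f <- g(function(r) r$peaks$Free$peak_rel_amplitude %||% NA_real_)
  onset_i <- g(function(r) r$dyn_instructed$onset)
  onset_f <- g(function(r) r$dyn_free$onset)
  dur_i <- g(function(r) r$dyn_instructed$duration)
  dur_f <- g(function(r) r$dyn_free$duration)

  paired_or_null <- function(a, b) {
    ok <- complete.cases(a, b)
    if (sum(ok) >= 2) as.list(group_compare(a[ok], b[ok], paired = TRUE)) else NULL
  }
  list(
    n_participants = length(results),
    rt_mean_ms = list(Control = safe_mean(rt_c),
                      Free = safe_mean(rt_f),
                      Instructed = safe_mean(rt_i)),
    rt_tests = list(control_vs_free = paired_or_null(rt_c, rt_f),
                    control_vs_instructed = paired_or_null(rt_c, rt_i),
                    free_vs_instructed = paired_or_null(rt_f, rt_i)),
    retained_fraction = mean(g(function(r) mean(r$trials$included))),
    n_sig_sites_hg = sum(g(function(r) length(r$sig_sites$free_vs_instructed))),
    max_da = safe_max(g(function(r) r$max_da %||% NA_real_)),
    mean_da = safe_mean(g(function(r) r$mean_da %||% NA_real_)),
    multisite_max_da = safe_mean(g(function(r) max(r$multisite_da))),
    peak_latency_ms = list(Instructed = safe_mean(peak_lat_i),
                           Free = safe_mean(peak_lat_f),
                           test = paired_or_null(peak_lat_i, peak_lat_f)),
    peak_amplitude_rel = list(Instructed = safe_mean(peak_amp_i),
                              Free = safe_mean(peak_amp_f),
                              test = paired_or_null(peak_amp_i, peak_amp_f)),
    decoding_onset_ms = list(Instructed = safe_mean(onset_i),
                             Free = safe_mean(onset_f),
                             test = paired_or_null(onset_i, onset_f)),
    decoding_duration_ms = list(Instructed = safe_mean(dur_i),
                                Free = safe_mean(dur_f),
                                test = paired_or_null(dur_i, dur_f)),
    conjunction = list(
      early_only = sum(g(function(r) length(r$conjunction$partition$early_only))),
      late_only = sum(g(function(r) length(r$conjunction$partition$late_only))),
      both = sum(g(function(r) length(r$conjunction$partition$both)))),
    onset_rt_correlation = list(
      r = safe_mean(g(function(r) r$onset_rt$r %||% NA_real_)),
      p = safe_mean(g(function(r) r$onset_rt$p %||% NA_real_))))
}
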