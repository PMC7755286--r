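# EOG saccade-onset detection, trial exclusion, reaction-time statistics and
# the trial-history (n-1) conditional-probability test.

#' Detect saccade onset from an EOG trace
#'
#' Fully automatic slope detection: the trace is smoothed with a short moving
#' average, differentiated, and the onset is the first time after the go
#' signal at which the derivative magnitude exceeds `k_sd` times the standard
#' deviation of the pre-go derivative for at least `min_run_ms`.
#'
#' @param trace numeric EOG segment (must cover the search window after go)
#' @param fs sampling rate in Hz
#' @param go_sample sample index of the go signal within `trace`
#' @param search_ms how far after go to search (default 1000 ms)
#' @param smooth_ms moving-average length (default 10 ms)
#' @param k_sd slope threshold in pre-go derivative SDs (default 3)
#' @param min_run_ms minimum supra-threshold run (default 5 ms)
#' @param baseline_ms pre-go interval used to estimate the derivative SD
#' @return saccade latency in ms after go, or NA if no slope is found
#' @export
detect_saccade_onset <- function(trace, fs, go_sample, search_ms = 1000,
                                 smooth_ms = 10, k_sd = 3, min_run_ms = 5,
                                 baseline_ms = c(-400, -50)) {
  .assert(length(trace) > 0, "empty trace")
  n_sm <- max(1L, ms_to_samples(smooth_ms, fs))
  sm <- as.numeric(stats::filter(trace, rep(1 / n_sm, n_sm), sides = 2))
  dv <- c(NA, diff(sm))
  b0 <- max(1L, go_sample + ms_to_samples(baseline_ms[1], fs))
  b1 <- max(b0 + 1L, go_sample + ms_to_samples(baseline_ms[2], fs))
  base_sd <- sd(dv[b0:b1], na.rm = TRUE)
  if (!is.finite(base_sd) || base_sd == 0) base_sd <- .Machine$double.eps
  s0 <- go_sample
  s1 <- min(length(trace), go_sample + ms_to_samples(search_ms, fs))
  seg <- abs(dv[s0:s1]) > k_sd * base_sd
  seg[is.na(seg)] <- FALSE
  run_n <- max(1L, ms_to_samples(min_run_ms, fs))
  r <- rle(seg)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run_n)
  if (!length(hit)) return(NA_real_)
  onset_idx <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  (onset_idx - 1) * 1000 / fs
}

#' Flag trials with spontaneous eye movements during the delay period
#'
#' Scans the horizontal EOG between Cue 1 offset and shortly before Cue 2 for
#' derivative excursions using the same slope rule as
#' [detect_saccade_onset()].
#'
#' @param eog the 2-channel EOG recording (first channel horizontal)
#' @param trials trial table
#' @param guard_ms `c(after_cue1, before_cue2)` guard intervals in ms
#' @param k_sd,smooth_ms,min_run_ms detection parameters
#' @return logical vector, one flag per trial
#' @export
detect_delay_artifacts <- function(eog, trials, guard_ms = c(400, 100),
                                   k_sd = 3, smooth_ms = 10, min_run_ms = 5) {
  fs <- eog$sampling_rate
  h <- eog$signal[1, ]
  vapply(seq_len(nrow(trials)), function(i) {
    s0 <- trials$cue1_onset[i] + ms_to_samples(guard_ms[1], fs)
    s1 <- trials$cue2_onset[i] - ms_to_samples(guard_ms[2], fs)
    if (s1 <= s0) return(FALSE)
    lat <- detect_saccade_onset(h, fs, s0, search_ms = (s1 - s0) * 1000 / fs,
                                smooth_ms = smooth_ms, k_sd = k_sd,
                                min_run_ms = min_run_ms,
                                baseline_ms = c(-350, -50))
    !is.na(lat)
  }, logical(1))
}

#' Apply behavioral trial exclusions
#'
#' Trials are excluded (included = FALSE) when the saccade latency exceeds
#' `rt_max_ms`, is missing, or the trial carries a delay-period eye-movement
#' flag. Exclusion is idempotent.
#'
#' @param trials trial table with `saccade_latency_ms` populated
#' @param rt_max_ms latency ceiling in ms (default 750)
#' @param delay_artifact_flags optional logical vector of delay-period
#'   eye-movement flags
#' @return the trial table with `included` updated; counts are reported in the
#'   `exclusion_counts` attribute
#' @export
apply_trial_exclusions <- function(trials, rt_max_ms = 750,
                                   delay_artifact_flags = NULL) {
  flags <- delay_artifact_flags %||% rep(FALSE, nrow(trials))
  .assert(length(flags) == nrow(trials), "one artifact flag per trial is required")
  rt <- trials$saccade_latency_ms
  slow <- !is.na(rt) & rt > rt_max_ms
  missing <- is.na(rt)
  out <- trials
  out$included <- trials$included & !slow & !missing & !flags
  attr(out, "exclusion_counts") <- c(n_total = nrow(trials),
                                     n_slow = sum(slow & trials$included),
                                     n_missing = sum(missing & trials$included),
                                     n_artifact = sum(flags & trials$included),
                                     n_retained = sum(out$included))
  out
}

#' Reaction-time statistics with bootstrap-equalized pairwise t tests
#'
#' Per-condition mean, SEM and n over included trials, plus unpaired
#' two-tailed Student t tests for every condition pair. Unequal trial counts
#' are handled by the bootstrap: on each of `n_boot` draws, both conditions
#' are subsampled without replacement to the size of the smaller one, and the
#' reported p is the median (default) or mean over draws. With equal counts
#' the procedure reduces to the plain t test.
#'
#' @param trials trial table (only `included` trials are used)
#' @param n_boot number of bootstrap draws (default 100)
#' @param seed integer seed
#' @param aggregate "median" (default) or "mean" aggregation of bootstrap p
#' @return a list of class `rt_stats`: `per_condition` tibble (condition,
#'   mean_ms, sem_ms, n) and `pairwise` tibble (a, b, t, df, p, n_used)
#' @export
compare_reaction_times <- function(trials, n_boot = 100, seed = 1L,
                                   aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!is.null(seed)) set.seed(seed)
  d <- trials[trials$included & !is.na(trials$saccade_latency_ms), ]
  conds <- sort(unique(d$condition))
  .assert(length(conds) >= 2, "need at least 2 conditions with included trials")
  rt <- split(d$saccade_latency_ms, d$condition)
  for (cc in conds) .assert(length(rt[[cc]]) >= 2,
                            paste("condition", cc, "has fewer than 2 included trials"))

  per_cond <- tibble::tibble(
    condition = conds,
    mean_ms = vapply(rt[conds], mean, numeric(1)),
    sem_ms = vapply(rt[conds], function(x) sd(x) / sqrt(length(x)), numeric(1)),
    n = vapply(rt[conds], length, numeric(1)))

  pairs <- utils::combn(conds, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- rt[[pairs[1, j]]]; b <- rt[[pairs[2, j]]]
    m <- min(length(a), length(b))
    ts <- ps <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      xa <- if (length(a) > m) sample(a, m) else a
      xb <- if (length(b) > m) sample(b, m) else b
      st <- .student_t2(xa, xb)
      ts[i] <- st$t; ps[i] <- st$p
    }
    agg <- if (aggregate == "median") median else mean
    tibble::tibble(a = pairs[1, j], b = pairs[2, j],
                   t = agg(ts), df = 2 * m - 2, p = agg(ps), n_used = m)
  })
  structure(list(per_condition = per_cond, pairwise = do.call(rbind, rows),
                 n_boot = n_boot, aggregate = aggregate),
            class = "rt_stats")
}

# pooled-variance two-sample Student t (closed form)
.student_t2 <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- if (se == 0) 0 else (mean(a) - mean(b)) / se
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

#' @export
print.rt_stats <- function(x, ...) {
  cat("<rt_stats> per-condition reaction times:\n")
  print(x$per_condition)
  cat(sprintf("pairwise unpaired t (bootstrap-equalized, %s p over %d draws):\n",
              x$aggregate, x$n_boot))
  print(x$pairwise)
  invisible(x)
}

# conditional probabilities P(L|L), P(L|R), P(R|R), P(R|L) of a L/R sequence
.history_probs <- function(seq_lr) {
  prev <- seq_lr[-length(seq_lr)]
  cur <- seq_lr[-1]
  nL <- sum(prev == "L"); nR <- sum(prev == "R")
  c(`P(L|L)` = if (nL > 0) sum(prev == "L" & cur == "L") / nL else NA_real_,
    `P(L|R)` = if (nR > 0) sum(prev == "R" & cur == "L") / nR else NA_real_,
    `P(R|R)` = if (nR > 0) sum(prev == "R" & cur == "R") / nR else NA_real_,
    `P(R|L)` = if (nL > 0) sum(prev == "L" & cur == "R") / nL else NA_real_)
}

#' Trial-history conditional-probability test
#'
#' Computes the n-1 conditional probabilities P(L|L), P(L|R), P(R|R), P(R|L)
#' from consecutive free-choice directions, and tests each against a
#' permutation null obtained by randomly permuting the L/R labels of the
#' sequence. A probability is significant when it falls outside the two-sided
#' empirical `alpha/2` quantile band of its null. Conditionals of a preceding
#' state that never occurs are reported missing.
#'
#' @param directions character sequence of "L"/"R" choices (length >= 3)
#' @param n_perm number of permutations (default 1000)
#' @param alpha two-sided level (default 0.001)
#' @param seed integer seed
#' @return a list of class `history_result`: `probs`, `lower`, `upper`
#'   (per-probability permutation band) and `significant`
#' @export
trial_history_test <- function(directions, n_perm = 1000, alpha = 0.001,
                               seed = 1L) {
  .assert(length(directions) >= 3, "sequence must have length >= 3")
  .assert(all(directions %in% c("L", "R")), "directions must be L or R")
  if (!is.null(seed)) set.seed(seed)
  obs <- .history_probs(directions)

  n <- length(directions)
  null <- matrix(NA_real_, n_perm, 4, dimnames = list(NULL, names(obs)))
  for (p in seq_len(n_perm)) null[p, ] <- .history_probs(sample(directions))
  lower <- apply(null, 2, quantile, probs = alpha / 2, na.rm = TRUE, type = 1)
  upper <- apply(null, 2, quantile, probs = 1 - alpha / 2, na.rm = TRUE, type = 1)
  sig <- !is.na(obs) & (obs < lower | obs > upper)
  structure(list(probs = obs, lower = lower, upper = upper, significant = sig,
                 alpha = alpha, n_perm = n_perm),
            class = "history_result")
}

#' @export
print.history_result <- function(x, ...) {
  cat(sprintf("<history_result> permutation band at alpha = %g (n_perm = %d)\n",
              x$alpha, x$n_perm))
  print(round(rbind(prob = x$probs, lower = x$lower, upper = x$upper), 3))
  cat("significant:", paste(names(x$probs)[x$significant], collapse = " "),
      if (!any(x$significant)) "(none)", "\n")
  invisible(x)
}
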