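# Temporal-dynamics metrics on high-gamma envelopes and decoding curves:
# peaks, decoding onsets and durations, per-trial HG onset detection, group
# statistics and HG-onset x saccade-latency correlation.

#' Peak amplitude and latency of a relative-power series
#'
#' The maximum value and its window centre within the search span. Ties go to
#' the earliest window.
#'
#' @param series numeric series over the window grid
#' @param centers_ms window-centre times in ms
#' @param span_ms `c(start, stop)` search span in ms (half-open)
#' @return `list(peak_rel_amplitude, peak_latency_ms)`
#' @export
peak_metrics <- function(series, centers_ms, span_ms = range(centers_ms) + c(0, 1)) {
  keep <- centers_ms >= span_ms[1] & centers_ms < span_ms[2]
  .assert(any(keep), "empty search span")
  v <- series[keep]; cc <- centers_ms[keep]
  i <- which.max(v)
  list(peak_rel_amplitude = v[i], peak_latency_ms = cc[i])
}

#' Decoding onset, duration and peak latency for one site and band
#'
#' Onset is the centre of the first significant window, duration is the
#' window step times the total count of significant windows (non-contiguous
#' runs all count), and the peak-DA latency is the centre of the maximum-DA
#' window. All quantities can be restricted to a span.
#'
#' @param result a `decoding_result` with a significance mask
#' @param site site index or label
#' @param band band index or name
#' @param span_ms optional `c(start, stop)` restriction in ms (half-open)
#' @return `list(decoding_onset_ms, decoding_duration_ms, peak_da_latency_ms,
#'   n_sig_windows)`; onset is NA when the mask is empty
#' @export
decoding_onset_duration <- function(result, site = 1, band = 1, span_ms = NULL) {
  .assert(!is.null(result$sig_mask), "result has no significance mask")
  centers <- result$window_centers_ms
  keep <- if (is.null(span_ms)) rep(TRUE, length(centers)) else
    centers >= span_ms[1] & centers < span_ms[2]
  mask <- result$sig_mask[site, band, ] & keep
  da <- result$da[site, band, ]
  onset <- if (any(mask)) centers[which(mask)[1]] else NA_real_
  peak_idx <- which(keep)[which.max(da[keep])]
  list(decoding_onset_ms = onset,
       decoding_duration_ms = result$step_ms * sum(mask),
       peak_da_latency_ms = centers[peak_idx],
       n_sig_windows = sum(mask))
}

#' Two-tailed Student t comparison of two groups
#'
#' Closed-form paired or unpaired (pooled-variance) Student t. Degenerate
#' paired comparisons (all differences equal) return t = 0, p = 1 when the
#' common difference is zero and |t| = Inf, p = 0 otherwise.
#'
#' @param values_a,values_b numeric vectors (equal length when paired)
#' @param paired paired comparison flag
#' @return a tibble with t, df, p, means and SEMs of both groups
#' @export
group_compare <- function(values_a, values_b, paired = FALSE) {
  na <- length(values_a); nb <- length(values_b)
  .assert(na >= 2 && nb >= 2, "each group needs n >= 2")
  if (paired) {
    .assert(na == nb, "paired comparison needs equal lengths")
    d <- values_a - values_b
    se <- sd(d) / sqrt(na)
    if (se == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      t <- mean(d) / se
      p <- 2 * pt(-abs(t), na - 1)
    }
    df <- na - 1
  } else {
    st <- .student_t2(values_a, values_b)
    t <- st$t; df <- st$df; p <- st$p
  }
  tibble::tibble(t = t, df = df, p = p,
                 mean_a = mean(values_a), sem_a = sd(values_a) / sqrt(na),
                 mean_b = mean(values_b), sem_b = sd(values_b) / sqrt(nb),
                 paired = paired)
}

#' Per-trial high-gamma onset detection
#'
#' The onset is the grid time of the first bin opening a run of at least
#' `min_bins` consecutive bins whose value exceeds
#' `baseline_mean + k_sd * baseline_sd`.
#'
#' @param series numeric relative-power series over the bin grid
#' @param times_ms grid times in ms (bin starts or centres, caller's choice;
#'   the returned onset lies on this grid)
#' @param baseline_mean,baseline_sd baseline statistics (sd must be > 0)
#' @param k_sd threshold in baseline SDs (default 2)
#' @param min_bins minimum run length (default 2)
#' @return onset time in ms, or NA when no qualifying run exists
#' @export
detect_hg_onset_trial <- function(series, times_ms, baseline_mean, baseline_sd,
                                  k_sd = 2, min_bins = 2) {
  .assert(is.finite(baseline_sd) && baseline_sd > 0, "degenerate baseline")
  above <- series > baseline_mean + k_sd * baseline_sd
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= min_bins)
  if (!length(hit)) return(NA_real_)
  times_ms[ends[hit[1]] - r$lengths[hit[1]] + 1L]
}

#' Correlate per-trial HG onsets with saccade latencies
#'
#' Pearson correlation (default) on pairwise-complete trials with the
#' two-sided t-based p-value for the null hypothesis that the two sets are
#' uncorrelated; Spearman available by flag.
#'
#' @param onsets_ms per-trial HG onsets in ms (may contain NA)
#' @param latencies_ms per-trial saccade latencies in ms (may contain NA)
#' @param method "pearson" (default) or "spearman"
#' @return `list(r, p, n)`
#' @export
correlate_hg_saccade_onsets <- function(onsets_ms, latencies_ms,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  .assert(length(onsets_ms) == length(latencies_ms), "inputs must be the same length")
  ok <- complete.cases(onsets_ms, latencies_ms)
  n <- sum(ok)
  .assert(n >= 3, "need at least 3 complete pairs")
  x <- onsets_ms[ok]; y <- latencies_ms[ok]
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2), n = n)
}
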