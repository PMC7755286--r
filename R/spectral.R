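# Bipolar re-referencing and band-envelope power feature extraction:
# zero-phase FIR band-pass -> Hilbert envelope -> sliding-window mean power ->
# optional baseline normalization -> per-trial epoching.

# ---- band definitions -----------------------------------------------------

#' Standard frequency bands
#'
#' theta 4-8, alpha 8-15, beta 16-30, low-gamma 30-60 and high-gamma (HG)
#' 60-140 Hz.
#'
#' @return a tibble with columns `name`, `f_low`, `f_high`
#' @export
default_bands <- function() {
  tibble::tibble(name = c("theta", "alpha", "beta", "lowgamma", "highgamma"),
                 f_low = c(4, 8, 16, 30, 60),
                 f_high = c(8, 15, 30, 60, 140))
}

# ---- bipolar montage ------------------------------------------------------

#' Bipolar re-reference a recording along electrode shafts
#'
#' Each site is re-referenced to its direct neighbour on the same shaft: a
#' shaft with contacts c1..ck yields the k-1 derivations c2-c1, ..., ck-c(k-1).
#' Signal common to both members of a pair cancels exactly.
#'
#' @param recording an [new_recording()] object
#' @param shaft_layout named list mapping shaft name -> ordered character
#'   vector of contact labels (each shaft needs >= 2 contacts)
#' @return a new `fs_recording` of bipolar derivations labelled "b-a"
#' @export
bipolar_rereference <- function(recording, shaft_layout) {
  labs <- recording$channel_labels
  out <- list(); out_labs <- character(0)
  for (shaft in shaft_layout) {
    .assert(length(shaft) >= 2, "each shaft needs at least 2 contacts")
    missing <- setdiff(shaft, labs)
    .assert(length(missing) == 0,
            paste("contacts missing from recording:", paste(missing, collapse = ", ")))
    for (i in seq_len(length(shaft) - 1)) {
      a <- shaft[i]; b <- shaft[i + 1]
      out[[length(out) + 1]] <- recording$signal[b, ] - recording$signal[a, ]
      out_labs <- c(out_labs, paste0(b, "-", a))
    }
  }
  new_recording(do.call(rbind, out), recording$sampling_rate, out_labs,
                recording$participant_id)
}

# ---- filtering and envelope ----------------------------------------------

# Hamming-window FIR band-pass; length = `cycles` periods of f_low, forced odd
# so the group delay is integral and zero-phase compensation is exact.
.fir_bandpass <- function(band, fs, cycles = 3) {
  .assert(band[1] > 0 && band[1] < band[2], "band edges must satisfy 0 < f_low < f_high")
  .assert(band[2] < fs / 2, "band above Nyquist")
  ntaps <- round(cycles * fs / band[1])
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  ntaps <- max(ntaps, 15)
  signal::fir1(ntaps - 1, band / (fs / 2), type = "pass")
}

# linear-phase FIR applied with FFT convolution; the symmetric filter's group
# delay (L-1)/2 is removed, giving a zero-phase result in one pass
.filter_zerophase <- function(x, b) {
  L <- length(b)
  d <- (L - 1) / 2
  y <- signal::fftfilt(b, c(x, numeric(L)))
  out <- y[(d + 1):(d + length(x))]
  attr(out, "edge_samples") <- L
  out
}

# analytic signal via frequency-domain Hilbert transform; the input is
# zero-padded to a fast composite FFT length (edges are flagged upstream)
.analytic <- function(x) {
  n0 <- length(x)
  n <- nextn(n0, c(2, 3, 5))
  if (n > n0) x <- c(x, numeric(n - n0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  (fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Band-pass envelope of a single channel
#'
#' Zero-phase FIR band-pass (filter length three cycles of the band's lower
#' edge) followed by the magnitude of the analytic signal. One filter length
#' at each end is unreliable and flagged through the `edge_samples` attribute.
#'
#' @param x numeric signal vector
#' @param band c(f_low, f_high) in Hz
#' @param fs sampling rate in Hz
#' @param cycles filter length in cycles of `f_low` (default 3)
#' @return envelope vector, same length as `x`, with an `edge_samples`
#'   attribute
#' @export
band_envelope <- function(x, band, fs, cycles = 3) {
  b <- .fir_bandpass(band, fs, cycles)
  y <- .filter_zerophase(x, b)
  env <- Mod(.analytic(as.numeric(y)))
  attr(env, "edge_samples") <- length(b)
  env
}

# ---- windowed power -------------------------------------------------------

#' Mean power over sliding windows
#'
#' Windows are half-open `[t, t + window_ms)` relative to `ref_sample`; the
#' value reported at each window centre `t + window_ms/2` is the mean of the
#' envelope over the window. The number of windows is
#' `floor((span - window) / step) + 1`.
#'
#' @param envelope signal vector (an envelope, or any non-negative series)
#' @param fs sampling rate in Hz
#' @param window_ms window length in ms
#' @param step_ms hop between window starts in ms (> 0)
#' @param span_ms `c(start, stop)` in ms relative to the reference sample
#' @param ref_sample sample index corresponding to 0 ms
#' @return named numeric vector of window means; names are centre times in ms,
#'   also available via `attr(, "centers_ms")`
#' @export
windowed_power <- function(envelope, fs, window_ms, step_ms, span_ms,
                           ref_sample = 1L) {
  .assert(step_ms > 0, "`step_ms` must be positive")
  .assert(diff(span_ms) >= window_ms, "span shorter than one window")
  K <- floor((diff(span_ms) - window_ms) / step_ms) + 1
  starts_ms <- span_ms[1] + (0:(K - 1)) * step_ms
  wlen <- ms_to_samples(window_ms, fs)
  i0 <- ref_sample + ms_to_samples(starts_ms, fs)
  .assert(min(i0) >= 1 && max(i0) + wlen - 1 <= length(envelope),
          "window span exceeds the signal")
  cs <- c(0, cumsum(as.numeric(envelope)))
  vals <- (cs[i0 + wlen] - cs[i0]) / wlen
  centers <- starts_ms + window_ms / 2
  names(vals) <- centers
  attr(vals, "centers_ms") <- centers
  vals
}

# ---- power tensor ---------------------------------------------------------

#' Construct a site x band x trial x window power tensor
#'
#' @param values 4-d numeric array, dimensions site x band x trial x window
#' @param window_centers_ms window-centre times in ms relative to the
#'   alignment event (strictly increasing, uniform)
#' @param window_length_ms window length in ms
#' @param step_ms window hop in ms
#' @param alignment "cue1" or "cue2"
#' @param normalized whether values are baseline-normalized relative power
#' @param site_labels,band_names,trial_index optional dimension labels
#' @return an object of class `fs_power`
#' @export
power_tensor <- function(values, window_centers_ms, window_length_ms, step_ms,
                         alignment = c("cue1", "cue2"), normalized = FALSE,
                         site_labels = NULL, band_names = NULL,
                         trial_index = NULL) {
  alignment <- match.arg(alignment)
  .assert(length(dim(values)) == 4, "`values` must be a 4-d array")
  .assert(dim(values)[4] == length(window_centers_ms),
          "one centre per window is required")
  if (length(window_centers_ms) > 1) {
    d <- diff(window_centers_ms)
    .assert(all(d > 0) && max(abs(d - d[1])) < 1e-9,
            "window grid must be strictly increasing and uniform")
  }
  if (!normalized) .assert(min(values, na.rm = TRUE) >= 0, "raw power must be >= 0")
  dimnames(values) <- list(
    site_labels %||% paste0("site", seq_len(dim(values)[1])),
    band_names %||% paste0("band", seq_len(dim(values)[2])),
    NULL, NULL)
  structure(list(values = values,
                 window_centers_ms = window_centers_ms,
                 window_length_ms = window_length_ms,
                 step_ms = step_ms,
                 alignment = alignment,
                 normalized = normalized,
                 trial_index = trial_index %||% seq_len(dim(values)[3])),
            class = "fs_power")
}

#' @export
print.fs_power <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(paste0("<fs_power> %d sites x %d bands x %d trials x %d windows",
                     " (%g/%g ms, %s-aligned%s)\n"),
              d[1], d[2], d[3], d[4], x$window_length_ms, x$step_ms,
              x$alignment, if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Subset a power tensor by site, band or trial
#'
#' @param tensor an `fs_power` object
#' @param sites,bands,trials indices or dimnames to keep (NULL keeps all);
#'   `trials` indexes the tensor's trial dimension
#' @return an `fs_power` object
#' @export
tensor_subset <- function(tensor, sites = NULL, bands = NULL, trials = NULL) {
  v <- tensor$values
  s <- sites %||% seq_len(dim(v)[1])
  b <- bands %||% seq_len(dim(v)[2])
  tr <- trials %||% seq_len(dim(v)[3])
  power_tensor(v[s, b, tr, , drop = FALSE], tensor$window_centers_ms,
               tensor$window_length_ms, tensor$step_ms, tensor$alignment,
               tensor$normalized,
               site_labels = dimnames(v)[[1]][s], band_names = dimnames(v)[[2]][b],
               trial_index = tensor$trial_index[tr])
}

#' Extract per-trial windowed band power from a recording
#'
#' For every included trial, the envelope of each channel in each band is
#' averaged over sliding windows laid out on `span_ms` relative to the chosen
#' alignment event. Aligning on Cue 2 with a negative span selects the final
#' part of each delay regardless of delay length, so the grid is identical
#' across trials.
#'
#' @param recording an `fs_recording`
#' @param trials trial table ([build_trial_schedule()] output); only rows with
#'   `included == TRUE` enter the tensor
#' @param bands band tibble as from [default_bands()] (any subset)
#' @param alignment "cue1" or "cue2"
#' @param span_ms `c(start, stop)` in ms relative to the alignment event
#' @param window_ms,step_ms window length and hop in ms
#' @return an `fs_power` tensor over included trials
#' @export
epoch_features <- function(recording, trials, bands = default_bands(),
                           alignment = c("cue1", "cue2"),
                           span_ms = c(-500, 2500), window_ms = 400,
                           step_ms = 50) {
  alignment <- match.arg(alignment)
  fs <- recording$sampling_rate
  keep <- which(trials$included)
  .assert(length(keep) > 0, "no included trials")
  align_samp <- if (alignment == "cue1") trials$cue1_onset[keep] else trials$cue2_onset[keep]

  K <- floor((diff(span_ms) - window_ms) / step_ms) + 1
  .assert(K >= 1, "span shorter than one window")
  starts_ms <- span_ms[1] + (0:(K - 1)) * step_ms
  wlen <- ms_to_samples(window_ms, fs)
  off <- ms_to_samples(starts_ms, fs)
  .assert(min(align_samp) + min(off) >= 1 &&
            max(align_samp) + max(off) + wlen - 1 <= ncol(recording$signal),
          "epoch exceeds recording bounds")

  ns <- nrow(recording$signal); nb <- nrow(bands); nt <- length(keep)
  vals <- array(NA_real_, c(ns, nb, nt, K))
  for (ch in seq_len(ns)) {
    for (b in seq_len(nb)) {
      env <- band_envelope(recording$signal[ch, ], c(bands$f_low[b], bands$f_high[b]), fs)
      cs <- c(0, cumsum(as.numeric(env)))
      for (j in seq_len(nt)) {
        i0 <- align_samp[j] + off
        vals[ch, b, j, ] <- (cs[i0 + wlen] - cs[i0]) / wlen
      }
    }
  }
  power_tensor(vals, starts_ms + window_ms / 2, window_ms, step_ms, alignment,
               site_labels = recording$channel_labels, band_names = bands$name,
               trial_index = trials$trial[keep])
}

# ---- baseline normalization ----------------------------------------------

#' Baseline-normalize a power tensor to relative power change
#'
#' Per site, band and trial: `(x - b) / b` where `b` is the mean over the
#' windows lying entirely inside the baseline interval (default the
#' pre-stimulus `[-500, -100)` ms before Cue 1). Degenerate baselines
#' (`b <= 0` or non-finite) flag the trial: its normalized values become NA
#' and the affected (site, band, trial) triples are listed in the `flagged`
#' attribute, never silently divided. Intended for visualization and dynamics;
#' classification consumes raw power.
#'
#' @param tensor an `fs_power` tensor to normalize
#' @param baseline_ms `c(start, stop)` ms of the baseline interval, on the
#'   grid of `baseline_tensor`
#' @param baseline_tensor tensor providing the baseline windows (defaults to
#'   `tensor` itself; must be cue1-aligned and cover the interval, with the
#'   same sites/bands/trials)
#' @return a normalized `fs_power` tensor
#' @export
baseline_normalize <- function(tensor, baseline_ms = c(-500, -100),
                               baseline_tensor = NULL) {
  bt <- baseline_tensor %||% tensor
  .assert(bt$alignment == "cue1", "baseline must be taken from a cue1-aligned tensor")
  .assert(baseline_ms[2] > baseline_ms[1], "baseline stop must exceed start")
  half <- bt$window_length_ms / 2
  in_base <- bt$window_centers_ms - half >= baseline_ms[1] &
    bt$window_centers_ms + half <= baseline_ms[2] + 1e-9
  .assert(any(in_base), "no baseline windows exist in the tensor")
  .assert(all(dim(bt$values)[1:3] == dim(tensor$values)[1:3]),
          "baseline tensor shape mismatch")

  b <- apply(bt$values[, , , in_base, drop = FALSE], 1:3, mean)
  bad <- !is.finite(b) | b <= 0
  v <- tensor$values
  K <- dim(v)[4]
  denom <- array(rep(b, K), dim = dim(v))
  out <- (v - denom) / denom
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) out[idx[r, 1], idx[r, 2], idx[r, 3], ] <- NA_real_
    flagged <- tibble::tibble(site = idx[, 1], band = idx[, 2], trial = idx[, 3])
  } else flagged <- tibble::tibble(site = integer(0), band = integer(0), trial = integer(0))

  res <- power_tensor(out, tensor$window_centers_ms, tensor$window_length_ms,
                      tensor$step_ms, tensor$alignment, normalized = TRUE,
                      site_labels = dimnames(tensor$values)[[1]],
                      band_names = dimnames(tensor$values)[[2]],
                      trial_index = tensor$trial_index)
  attr(res, "flagged") <- flagged
  res
}
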