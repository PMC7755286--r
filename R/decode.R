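# Two-class LDA decoding with stratified cross-validation, permutation
# maximum-statistics inference, binomial chance thresholds, cross-temporal
# generalization and exhaustive frequency-band selection.
#
# The classifier is a two-class linear discriminant with pooled within-class
# covariance regularized by Ledoit-Wolf analytic shrinkage (single-window
# multisite feature spaces can approach the trial count) and equal priors, so
# decoding accuracy is invariant under swapping the two class labels.

# ---- folds ----------------------------------------------------------------

# stratified fold assignment; folds are reduced (with a message) when the
# smaller class has fewer members than requested folds
.stratified_folds <- function(y, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.factor(y)
  min_n <- min(table(y))
  nf <- min(n_folds, min_n)
  if (nf < n_folds)
    message(sprintf("reducing folds from %d to %d (smallest class has %d trials)",
                    n_folds, nf, min_n))
  .assert(nf >= 2, "need at least 2 observations per class")
  fold <- integer(length(y))
  # classes are processed in order of first occurrence, so the assignment is
  # invariant under a pure relabeling of the two classes
  levs <- levels(y)[order(vapply(levels(y), function(l) min(which(y == l)), numeric(1)))]
  for (lev in levs) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(nf), length(idx))
  }
  fold
}

# ---- LDA ------------------------------------------------------------------

# Ledoit-Wolf shrinkage intensity toward mu*I for rows-centred data Xc
.lw_lambda <- function(Xc) {
  n <- nrow(Xc); d <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / d
  delta2 <- sum((S - diag(mu, d))^2) / d
  if (delta2 < .Machine$double.eps) return(1)
  q <- rowSums(Xc^2)
  beta2 <- (mean(q^2) / d - sum(S^2) / d) / n
  max(0, min(1, beta2 / delta2))
}

# fit two-class LDA; z is the logical class indicator (TRUE = second level)
.lda_fit <- function(X, z) {
  X <- as.matrix(X)
  n1 <- sum(z); n0 <- sum(!z)
  .assert(n1 >= 1 && n0 >= 1, "single-class input")
  m1 <- colMeans(X[z, , drop = FALSE])
  m0 <- colMeans(X[!z, , drop = FALSE])
  Xc <- X
  Xc[z, ] <- sweep(X[z, , drop = FALSE], 2, m1)
  Xc[!z, ] <- sweep(X[!z, , drop = FALSE], 2, m0)
  d <- ncol(X)
  S <- crossprod(Xc) / max(nrow(X) - 2, 1)
  lam <- .lw_lambda(Xc)
  mu <- sum(diag(S)) / d
  if (mu <= 0) mu <- 1
  Sigma <- (1 - lam) * S + diag(lam * mu, d)
  w <- tryCatch(solve(Sigma, m1 - m0),
                error = function(e) (m1 - m0) / mu)
  list(w = as.numeric(w), b = -sum(w * (m1 + m0) / 2))
}

.lda_predict <- function(fit, X) {
  as.numeric(as.matrix(X) %*% fit$w + fit$b) > 0
}

#' Cross-validated decoding accuracy of a two-class feature set
#'
#' Stratified k-fold cross-validation of a shrinkage-regularized two-class
#' linear discriminant. Every observation is tested exactly once; the
#' decoding accuracy (DA) is the overall fraction of correct held-out
#' predictions. Folds are reduced automatically (with a message) if the
#' smaller class has fewer observations than requested folds.
#'
#' @param features numeric matrix (observations x features) or vector
#' @param labels two-level factor (or coercible) of class labels
#' @param n_folds number of folds (default 10)
#' @param seed integer seed controlling the fold assignment
#' @return decoding accuracy in `[0, 1]`
#' @export
cross_validated_da <- function(features, labels, n_folds = 10, seed = 1L) {
  X <- as.matrix(features)
  y <- as.factor(labels)
  .assert(nlevels(y) == 2, "exactly two classes are required")
  .assert(!anyNA(X), "features must not contain missing values")
  z <- y == levels(y)[2]
  folds <- .stratified_folds(y, n_folds, seed)
  correct <- 0L
  for (f in seq_len(max(folds))) {
    te <- folds == f
    fit <- .lda_fit(X[!te, , drop = FALSE], z[!te])
    correct <- correct + sum(.lda_predict(fit, X[te, , drop = FALSE]) == z[te])
  }
  correct / nrow(X)
}

# ---- fast per-cell (1-D feature) path -------------------------------------

# DA for every column of M (trials x cells) under shared folds; each cell is a
# univariate feature, for which shrinkage LDA reduces to the midpoint rule
# sign((m1 - m0) * (x - (m1 + m0)/2)). Class sums are updated per fold so the
# cost per fold is proportional to the held-out block only.
.cell_da <- function(M, z, folds) {
  n <- nrow(M)
  s1 <- colSums(M[z, , drop = FALSE]);  n1 <- sum(z)
  s0 <- colSums(M[!z, , drop = FALSE]); n0 <- sum(!z)
  correct <- numeric(ncol(M))
  for (f in seq_len(max(folds))) {
    te <- folds == f
    te1 <- te & z; te0 <- te & !z
    m1 <- (s1 - colSums(M[te1, , drop = FALSE])) / (n1 - sum(te1))
    m0 <- (s0 - colSums(M[te0, , drop = FALSE])) / (n0 - sum(te0))
    d <- m1 - m0
    mid <- (m1 + m0) / 2
    S <- M[te, , drop = FALSE]
    pred <- sweep(sweep(S, 2, mid), 2, d, `*`) > 0     # TRUE -> second class
    correct <- correct + colSums(pred == z[te])
  }
  correct / n
}

# trials x (site, band, window) matrix from a tensor; site varies fastest
.tensor_matrix <- function(tensor) {
  v <- aperm(tensor$values, c(3, 1, 2, 4))
  dim(v) <- c(dim(tensor$values)[3], prod(dim(tensor$values)[c(1, 2, 4)]))
  v
}

.check_tensor_labels <- function(tensor, labels) {
  .assert(length(labels) == dim(tensor$values)[3],
          "labels and tensor trial dimension mismatch")
  y <- as.factor(labels)
  .assert(nlevels(y) == 2, "exactly two classes are required")
  y
}

#' Time-resolved single-site decoding accuracies
#'
#' One DA per (site, band, window). All cells share the same seed-fixed fold
#' assignment so comparisons across windows are paired.
#'
#' @param tensor an `fs_power` tensor (raw power)
#' @param labels per-trial class labels, aligned with the tensor's trials
#' @param n_folds number of CV folds
#' @param seed integer seed for the fold assignment
#' @return a `decoding_result` with the `da` array (site x band x window);
#'   permutation fields are NULL until [permutation_maxstat()] fills them
#' @export
time_resolved_decoding <- function(tensor, labels, n_folds = 10, seed = 1L) {
  y <- .check_tensor_labels(tensor, labels)
  z <- y == levels(y)[2]
  folds <- .stratified_folds(y, n_folds, seed)
  da <- .cell_da(.tensor_matrix(tensor), z, folds)
  dims <- dim(tensor$values)[c(1, 2, 4)]
  da <- array(da, dims, dimnames = c(dimnames(tensor$values)[1:2], list(NULL)))
  structure(list(da = da, null_maxima = NULL, threshold = NULL,
                 sig_mask = NULL, alpha = NULL, n_folds = max(folds),
                 window_centers_ms = tensor$window_centers_ms,
                 step_ms = tensor$step_ms, alignment = tensor$alignment,
                 labels = levels(y), multisite = FALSE),
            class = "decoding_result")
}

#' Permutation maximum-statistics decoding inference
#'
#' The observed DA array is recomputed once per permutation after shuffling
#' the class labels (one shuffle reused across every site, band and window, as
#' the maximum distribution requires); the null distribution is the global
#' maximum DA per permutation, the threshold is the
#' `ceiling((1 - alpha) * (n_perm + 1))`-th order statistic of those maxima,
#' and a cell is significant when its DA exceeds the threshold. This corrects
#' family-wise across electrodes, frequency bands and time.
#'
#' @param tensor an `fs_power` tensor (raw power)
#' @param labels per-trial class labels
#' @param n_perm number of permutations (default 100)
#' @param alpha family-wise level (default 0.01)
#' @param n_folds number of CV folds
#' @param seed integer seed (folds and permutations)
#' @param multisite if TRUE, sites are concatenated into the feature vector
#'   and the DA array is 1 x band x window
#' @return a complete `decoding_result` (da, null_maxima, threshold, sig_mask)
#' @export
permutation_maxstat <- function(tensor, labels, n_perm = 100, alpha = 0.01,
                                n_folds = 10, seed = 1L, multisite = FALSE) {
  .assert(n_perm >= 1, "`n_perm` must be positive")
  .assert(alpha > 0 && alpha < 1, "`alpha` must lie in (0, 1)")
  if (n_perm < 1 / alpha - 1)
    warning(sprintf("n_perm = %d is below the 1/alpha - 1 = %g recommended for alpha = %g",
                    n_perm, 1 / alpha - 1, alpha))
  y <- .check_tensor_labels(tensor, labels)
  z <- y == levels(y)[2]
  folds <- .stratified_folds(y, n_folds, seed)

  da_fun <- if (multisite) {
    function(zz) .multisite_da(tensor, zz, folds)
  } else {
    M <- .tensor_matrix(tensor)
    function(zz) .cell_da(M, zz, folds)
  }

  da <- da_fun(z)
  null_max <- vapply(seq_len(n_perm), function(p) max(da_fun(sample(z))), numeric(1))
  k <- min(ceiling((1 - alpha) * (n_perm + 1)), n_perm)
  threshold <- sort(null_max)[k]
  dims <- if (multisite) c(1L, dim(tensor$values)[c(2, 4)]) else dim(tensor$values)[c(1, 2, 4)]
  da <- array(da, dims,
              dimnames = c(if (multisite) list("multisite") else dimnames(tensor$values)[1],
                           dimnames(tensor$values)[2], list(NULL)))
  structure(list(da = da, null_maxima = null_max, threshold = threshold,
                 sig_mask = da > threshold, alpha = alpha, n_folds = max(folds),
                 window_centers_ms = tensor$window_centers_ms,
                 step_ms = tensor$step_ms, alignment = tensor$alignment,
                 labels = levels(y), multisite = multisite),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  d <- dim(x$da)
  cat(sprintf("<decoding_result> %s vs %s: %d sites x %d bands x %d windows\n",
              x$labels[1], x$labels[2], d[1], d[2], d[3]))
  if (!is.null(x$threshold))
    cat(sprintf("  max-stat threshold %.3f (alpha %g), %d significant cells\n",
                x$threshold, x$alpha, sum(x$sig_mask)))
  invisible(x)
}

# multisite DA per (band, window) under fixed folds: features concatenate all
# sites of the band at the given window
.multisite_da <- function(tensor, z, folds) {
  v <- tensor$values
  nb <- dim(v)[2]; nw <- dim(v)[4]; n <- dim(v)[3]
  da <- matrix(0, nb, nw)
  for (b in seq_len(nb)) {
    for (w in seq_len(nw)) {
      X <- t(matrix(v[, b, , w], nrow = dim(v)[1]))   # trials x sites
      if (ncol(X) == 1) {
        da[b, w] <- .cell_da(X, z, folds)
      } else {
        correct <- 0L
        for (f in seq_len(max(folds))) {
          te <- folds == f
          fit <- .lda_fit(X[!te, , drop = FALSE], z[!te])
          correct <- correct + sum(.lda_predict(fit, X[te, , drop = FALSE]) == z[te])
        }
        da[b, w] <- correct / n
      }
    }
  }
  da
}

#' Multisite decoding accuracies per band and window
#'
#' At each window the feature vector concatenates all sites for the given
#' band; the same stratified CV machinery applies. With a single site this
#' equals single-site decoding exactly.
#'
#' @inheritParams time_resolved_decoding
#' @return matrix of DA, bands x windows, with band dimnames
#' @export
multisite_decoding <- function(tensor, labels, n_folds = 10, seed = 1L) {
  y <- .check_tensor_labels(tensor, labels)
  z <- y == levels(y)[2]
  folds <- .stratified_folds(y, n_folds, seed)
  da <- .multisite_da(tensor, z, folds)
  rownames(da) <- dimnames(tensor$values)[[2]]
  colnames(da) <- tensor$window_centers_ms
  da
}

# ---- binomial threshold ---------------------------------------------------

#' Chance-level decoding threshold from the binomial tail
#'
#' The smallest accuracy `k / n_test` whose exact tail probability
#' `P(X >= k)` under `X ~ Binomial(n_test, 1/n_classes)` falls below `alpha`.
#'
#' @param n_test number of held-out test trials
#' @param n_classes number of classes (default 2)
#' @param alpha significance level in (0, 1)
#' @return the DA threshold
#' @export
binomial_da_threshold <- function(n_test, n_classes = 2, alpha = 0.01) {
  .assert(n_test >= 1, "`n_test` must be >= 1")
  .assert(alpha > 0 && alpha < 1, "`alpha` must lie in (0, 1)")
  kk <- 0:n_test
  tail_p <- pbinom(kk - 1, n_test, 1 / n_classes, lower.tail = FALSE)  # P(X >= k)
  k <- kk[match(TRUE, tail_p < alpha)]
  .assert(!is.na(k), "no accuracy reaches significance at this alpha")
  k / n_test
}

# ---- temporal generalization ----------------------------------------------

#' Cross-temporal generalization matrix
#'
#' For every training window t, the fold-wise classifiers (trained on that
#' fold's training trials at t) are applied to the fold's held-out trials at
#' every test window t2, so off-diagonal cells involve no train/test leakage
#' and the diagonal equals the per-window CV decoding of the same features
#' under the same folds. Features concatenate the supplied site set in the
#' chosen band. Significance uses the exact binomial threshold on the total
#' held-out trial count.
#'
#' @param tensor an `fs_power` tensor (raw power)
#' @param labels per-trial class labels
#' @param sites site indices or labels to include (default: all); must be
#'   non-empty
#' @param band band name or index (single band)
#' @param n_folds number of CV folds
#' @param alpha level for the binomial threshold
#' @param seed integer seed for the fold assignment
#' @return a `generalization_matrix`: `da` (train x test windows),
#'   `threshold`, `sig_mask` (DA >= threshold), window grid
#' @export
temporal_generalization <- function(tensor, labels, sites = NULL,
                                    band = "highgamma", n_folds = 10,
                                    alpha = 0.01, seed = 1L) {
  if (!is.null(sites)) .assert(length(sites) > 0, "empty site set")
  tn <- tensor_subset(tensor, sites = sites, bands = band)
  y <- .check_tensor_labels(tn, labels)
  z <- y == levels(y)[2]
  folds <- .stratified_folds(y, n_folds, seed)
  v <- tn$values
  nw <- dim(v)[4]; n <- dim(v)[3]

  correct <- matrix(0, nw, nw)
  for (f in seq_len(max(folds))) {
    te <- folds == f
    for (t_train in seq_len(nw)) {
      Xtr <- t(matrix(v[, 1, !te, t_train], nrow = dim(v)[1]))
      fit <- .lda_fit(Xtr, z[!te])
      for (t_test in seq_len(nw)) {
        Xte <- t(matrix(v[, 1, te, t_test], nrow = dim(v)[1]))
        correct[t_train, t_test] <- correct[t_train, t_test] +
          sum(.lda_predict(fit, Xte) == z[te])
      }
    }
  }
  da <- correct / n
  thr <- binomial_da_threshold(n, 2, alpha)
  structure(list(da = da, threshold = thr, sig_mask = da >= thr,
                 window_centers_ms = tn$window_centers_ms, alpha = alpha,
                 band = band, n_folds = max(folds)),
            class = "generalization_matrix")
}

#' @export
print.generalization_matrix <- function(x, ...) {
  cat(sprintf("<generalization_matrix> %d x %d windows, binomial threshold %.3f, %d significant cells\n",
              nrow(x$da), ncol(x$da), x$threshold, sum(x$sig_mask)))
  invisible(x)
}

# ---- exhaustive band selection --------------------------------------------

#' Exhaustive frequency-band subset selection per site
#'
#' For every site, all nonempty subsets of the supplied bands (2^B - 1; 31 for
#' the 5 standard bands) are fitted on two thirds of the trials and scored on
#' the held-out stratified third, repeated over the three disjoint validation
#' thirds. The winning subset per repetition is the highest-scoring one, ties
#' resolved in favour of the smallest subset and then band order.
#'
#' @param tensor an `fs_power` tensor with >= 2 bands; each band contributes
#'   its full window series to the feature block
#' @param labels per-trial class labels
#' @param seed integer seed for the third assignment
#' @return a tibble with columns `site`, `subset` (band names joined by "+")
#'   and `count` over the 3 validation splits; the `subsets` attribute lists
#'   all evaluated subsets
#' @export
exhaustive_band_selection <- function(tensor, labels, seed = 1L) {
  y <- .check_tensor_labels(tensor, labels)
  .assert(min(table(y)) >= 3, "need at least 3 observations per class to form thirds")
  nb <- dim(tensor$values)[2]
  .assert(nb >= 2, "need at least 2 bands")
  z <- y == levels(y)[2]
  thirds <- .stratified_folds(y, 3, seed)

  subsets <- list()
  for (sz in seq_len(nb)) {
    cmb <- utils::combn(nb, sz)
    subsets <- c(subsets, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  band_names <- dimnames(tensor$values)[[2]]
  sub_labels <- vapply(subsets, function(s) paste(band_names[s], collapse = "+"),
                       character(1))

  ns <- dim(tensor$values)[1]
  out <- list()
  for (s in seq_len(ns)) {
    blocks <- lapply(seq_len(nb), function(b)
      matrix(tensor$values[s, b, , ], nrow = dim(tensor$values)[3]))
    wins <- character(0)
    for (v3 in 1:3) {
      tr <- thirds != v3
      scores <- vapply(subsets, function(sb) {
        X <- do.call(cbind, blocks[sb])
        fit <- .lda_fit(X[tr, , drop = FALSE], z[tr])
        mean(.lda_predict(fit, X[!tr, , drop = FALSE]) == z[!tr])
      }, numeric(1))
      wins <- c(wins, sub_labels[which.max(scores)])   # subsets ordered by size, band order
    }
    tab <- table(factor(wins, levels = unique(sub_labels)))
    tab <- tab[tab > 0]
    out[[s]] <- tibble::tibble(site = dimnames(tensor$values)[[1]][s],
                               subset = names(tab), count = as.integer(tab))
  }
  res <- do.call(rbind, out)
  attr(res, "subsets") <- sub_labels
  res
}
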