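test_that("cross-validated LDA separates separable data and stays at chance on noise", {
  y <- factor(rep(c("a", "b"), each = 20))
  x <- c(rnorm(20, -5, 0.1), rnorm(20, 5, 0.1))
  expect_equal(cross_validated_da(x, y, 10, seed = 1), 1.0)

  # label-independent features -> mean DA 0.50 +- 0.01 over 200 seeds
  set.seed(99)
  das <- vapply(1:200, function(s) {
    cross_validated_da(matrix(rnorm(200 * 2), 200), factor(rep(c("a", "b"), 100)),
                       10, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(das) - 0.5), 0.01)

  expect_error(cross_validated_da(rnorm(10), factor(rep("a", 10))), "two classes")
})

test_that("stratified folds preserve class proportions within one observation", {
  y <- factor(rep(c("a", "b"), each = 20))
  folds <- freesacc:::.stratified_folds(y, 10, seed = 4)
  tab <- table(folds, y)
  expect_true(all(tab == 2))                      # 20+20 -> 2 per class per fold

  y2 <- factor(rep(c("a", "b"), c(23, 17)))
  f2 <- freesacc:::.stratified_folds(y2, 10, seed = 4)
  t2 <- table(f2, y2)
  expect_true(all(abs(t2[, 1] - 2.3) < 1) && all(abs(t2[, 2] - 1.7) < 1))

  expect_message(freesacc:::.stratified_folds(factor(rep(c("a", "b"), c(30, 5))), 10, 1),
                 "reducing folds")
})

test_that("decoding accuracy is invariant under swapping the class labels", {
  set.seed(12)
  X <- matrix(rnorm(60 * 3), 60)
  X[1:30, 1] <- X[1:30, 1] + 1
  y <- factor(rep(c("a", "b"), each = 30))
  y_swap <- factor(ifelse(y == "a", "b", "a"), levels = c("a", "b"))
  expect_equal(cross_validated_da(X, y, 10, 7), cross_validated_da(X, y_swap, 10, 7))
})

test_that("shrinkage LDA agrees with a reference discriminant on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(5)
  n <- 200
  X <- rbind(matrix(rnorm(n, 0), n / 2, 2), matrix(rnorm(n, 1), n / 2, 2))
  z <- rep(c(FALSE, TRUE), each = n / 2)
  fit <- freesacc:::.lda_fit(X, z)
  mine <- freesacc:::.lda_predict(fit, X)
  ref <- MASS::lda(X, grouping = z, prior = c(0.5, 0.5))
  theirs <- stats::predict(ref, X)$class == "TRUE"
  expect_gt(mean(mine == theirs), 0.95)           # Ledoit-Wolf shrinkage is mild here
})

test_that("time-resolved decoding confines significance to informative windows", {
  z <- rep(c(FALSE, TRUE), each = 30)
  # strong class shift only in windows 11..20 of 30 (site 2)
  tens <- shift_tensor(z, ns = 3, nw = 30, sites = 2, windows = 11:20,
                       delta = 4, seed = 6)
  lab <- factor(ifelse(z, "B", "A"))
  res <- permutation_maxstat(tens, lab, n_perm = 100, alpha = 0.01, seed = 2)
  expect_equal(dim(res$da), c(3, 1, 30))
  sig_w <- which(apply(res$sig_mask, 3, any))
  expect_true(all(sig_w >= 10 & sig_w <= 21))     # within +-1 window of the span
  expect_true(all(11:20 %in% sig_w))
  sig_s <- which(apply(res$sig_mask, 1, any))
  expect_equal(unname(sig_s), 2L)

  # determinism and the sig_mask <-> threshold contract
  res2 <- permutation_maxstat(tens, lab, n_perm = 100, alpha = 0.01, seed = 2)
  expect_identical(res$da, res2$da)
  expect_identical(res$null_maxima, res2$null_maxima)
  expect_identical(res$sig_mask, res$da > res$threshold)
  expect_gte(res$threshold, 0.5)
})

test_that("max-stat threshold dominates pointwise permutation thresholds", {
  tens <- rand_tensor(ns = 4, nt = 40, nw = 8, seed = 9)
  lab <- factor(rep(c("A", "B"), 20))
  res <- permutation_maxstat(tens, lab, n_perm = 60, alpha = 0.05, seed = 3)
  # the global-max null is stochastically above any single-cell null by construction
  expect_gte(res$threshold, quantile(res$null_maxima, 0.5))
  expect_true(all(res$null_maxima <= 1 & res$null_maxima >= 0))
  expect_warning(permutation_maxstat(tens, lab, n_perm = 5, alpha = 0.01, seed = 1),
                 "n_perm")
  expect_error(permutation_maxstat(tens, lab, n_perm = 0), "positive")
})

test_that("multisite decoding reduces to single-site with one site and pools information", {
  z <- rep(c(FALSE, TRUE), each = 24)
  lab <- factor(ifelse(z, "B", "A"))
  one <- shift_tensor(z, ns = 1, nw = 6, sites = 1, windows = 3:4, delta = 1, seed = 2)
  single <- time_resolved_decoding(one, lab, 8, seed = 5)
  multi <- multisite_decoding(one, lab, 8, seed = 5)
  expect_equal(as.numeric(multi), as.numeric(single$da[1, 1, ]))

  # several redundant moderately informative sites beat the best single site
  gains <- vapply(1:15, function(s) {
    tens <- shift_tensor(z, ns = 4, nw = 4, sites = 1:4, windows = 2:3,
                         delta = 0.8, seed = 100 + s)
    best_single <- max(time_resolved_decoding(tens, lab, 8, seed = s)$da[, 1, 2:3])
    max(multisite_decoding(tens, lab, 8, seed = s)[1, 2:3]) - best_single
  }, numeric(1))
  expect_gte(median(gains), 0)

  # uninformative sites stay near chance
  das <- vapply(1:20, function(s) {
    tens <- rand_tensor(ns = 4, nt = 48, nw = 3, seed = 200 + s)
    mean(multisite_decoding(tens, factor(rep(c("A", "B"), 24)), 8, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(das) - 0.5), 0.05)
})

test_that("binomial DA thresholds match exact tail sums and are monotone", {
  # oracle: explicit binomial tail enumeration at n = 10, alpha = 0.05
  tail_p <- vapply(0:10, function(k) sum(choose(10, k:10)) / 2^10, numeric(1))
  k_star <- (0:10)[match(TRUE, tail_p < 0.05)]
  expect_equal(k_star, 9)
  expect_equal(binomial_da_threshold(10, 2, 0.05), 0.9)
  expect_equal(binomial_da_threshold(10, 2, 0.05), k_star / 10)

  thr <- vapply(c(10, 20, 40, 80, 160, 320), binomial_da_threshold,
                numeric(1), n_classes = 2, alpha = 0.01)
  expect_true(all(diff(thr) <= 0))               # non-increasing in n_test
  # alpha -> 1 pushes the threshold just above chance
  expect_lt(binomial_da_threshold(100, 2, 0.999), 0.55)
  expect_error(binomial_da_threshold(10, 2, 1.5), "alpha")
  expect_error(binomial_da_threshold(0), "n_test")
})

test_that("temporal generalization shares folds with per-window decoding on its diagonal", {
  z <- rep(c(FALSE, TRUE), each = 24)
  lab <- factor(ifelse(z, "B", "A"))
  tens <- shift_tensor(z, ns = 2, nw = 8, sites = 1:2, windows = 3:6,
                       delta = 1.5, seed = 8)
  tg <- temporal_generalization(tens, lab, band = 1, n_folds = 8, seed = 10)
  ms <- multisite_decoding(tens, lab, n_folds = 8, seed = 10)
  expect_equal(diag(tg$da), as.numeric(ms[1, ]))
  expect_identical(tg$sig_mask, tg$da >= tg$threshold)
  expect_error(temporal_generalization(tens, lab, sites = integer(0)), "empty site")
})

test_that("exhaustive band selection scores all subsets and prefers the informative band", {
  z <- rep(c(FALSE, TRUE), each = 15)
  set.seed(44)
  v <- array(exp(rnorm(1 * 5 * 30 * 4, sd = 0.5)), c(1, 5, 30, 4))
  v[1, 5, z, ] <- v[1, 5, z, ] + 4                # only band 5 (HG) informative
  tens <- power_tensor(v, seq(200, 350, 50), 400, 50, "cue1",
                       band_names = default_bands()$name)
  sel <- exhaustive_band_selection(tens, factor(ifelse(z, "B", "A")), seed = 2)
  expect_length(attr(sel, "subsets"), 31)
  expect_equal(sel$subset, "highgamma")
  expect_equal(sel$count, 3)                      # all three validation thirds
  expect_equal(sum(sel$count), 3)

  # tie between duplicated informative bands -> smallest subset, band order
  v2 <- v
  v2[1, 1, , ] <- v2[1, 5, , ]                    # theta duplicates HG exactly
  tens2 <- power_tensor(v2, seq(200, 350, 50), 400, 50, "cue1",
                        band_names = default_bands()$name)
  sel2 <- exhaustive_band_selection(tens2, factor(ifelse(z, "B", "A")), seed = 2)
  expect_equal(sel2$subset, "theta")

  expect_error(exhaustive_band_selection(tensor_subset(tens, bands = 1),
                                         factor(ifelse(z, "B", "A"))), "2 bands")
})
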