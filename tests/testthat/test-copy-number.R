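test_that("the multiplier grid search finds the exact ploidy scale", {
  segs <- data.frame(start_bin = c(0, 10, 20), end_bin = c(10, 20, 30),
                     n_bins = 10, mean_ratio = c(0.5, 1.0, 1.5))
  fit <- fit_absolute(segs)
  expect_equal(fit$multiplier, 2)
  expect_equal(fit$fit_error, 0)
  expect_equal(fit$segments$cn, c(1L, 2L, 3L))
  expect_equal(fit$cn_per_bin, rep(c(1L, 2L, 3L), each = 10))
  # independent full-grid scan confirms the global optimum and tie-break
  grid <- seq(0.55, 8, by = 0.01)
  obj <- vapply(grid, function(m)
    sum(10 * (segs$mean_ratio * m - round(segs$mean_ratio * m))^2), numeric(1))
  expect_true(all(obj >= obj[grid == 2] - 1e-12))
  expect_equal(min(grid[obj < 1e-12]), 2)
  expect_error(fit_absolute(segs[0, ]), "empty")
})

test_that("the flat-profile ploidy degeneracy is handled both ways", {
  segs <- data.frame(start_bin = 0, end_bin = 50, n_bins = 50, mean_ratio = 1)
  raw <- fit_absolute(segs, diploid_fallback = FALSE)
  expect_equal(raw$multiplier, 1)   # smallest grid value with zero error
  expect_equal(raw$fit_error, 0)
  expect_false(raw$ploidy_unresolvable)
  dip <- fit_absolute(segs)
  expect_equal(dip$multiplier, 2)
  expect_true(dip$ploidy_unresolvable)
  expect_equal(dip$segments$cn, 2L)
})

test_that("the fitted multiplier is the bin-weighted grid optimum", {
  set.seed(13)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    segs <- data.frame(start_bin = 0, end_bin = 0,
                       n_bins = sample(5:200, k, replace = TRUE),
                       mean_ratio = runif(k, 0.3, 2.5))
    fit <- fit_absolute(segs, diploid_fallback = FALSE)
    grid <- seq(0.55, 8, by = 0.01)
    obj <- vapply(grid, function(m)
      sum(segs$n_bins * (segs$mean_ratio * m - round(segs$mean_ratio * m))^2),
      numeric(1))
    expect_equal(fit$fit_error, min(obj))
    expect_equal(fit$multiplier, grid[which.min(obj)])
  }
})

test_that("downsampling is an exact hypergeometric subsample", {
  set.seed(21)
  counts <- rpois(200, 50)
  prof <- bin_profile(counts)
  same <- downsample_counts(prof, sum(counts), seed = 1)
  expect_identical(same$count, prof$count)
  sub <- downsample_counts(prof, 2000, seed = 2)
  expect_equal(sum(sub$count), 2000)
  expect_true(all(sub$count <= counts))
  expect_identical(downsample_counts(prof, 2000, seed = 2)$count, sub$count)
  expect_error(downsample_counts(prof, sum(counts) + 1), "more reads")
  # per-bin expectation preserved within 3 Monte-Carlo SE
  frac <- counts / sum(counts)
  expected <- 2000 * frac
  se <- sqrt(2000 * frac * (1 - frac))
  expect_lt(mean(abs(sub$count - expected) > 3 * se + 1e-9), 0.01)
})

test_that("boundary bookkeeping counts spurious and missed transitions", {
  tr <- simulate_cn_profile(100, events = data.frame(start = 20, end = 40, cn = 1))
  expect_equal(truth_boundaries(tr), c(20, 40))
  expect_equal(spurious_segments(c(20, 40), tr), list(spurious = 0L, missed = 0L))
  expect_equal(spurious_segments(c(20, 40, 70), tr)$spurious, 1L)
  expect_equal(spurious_segments(c(21, 39), tr, tol = 2)$spurious, 0L)
  expect_equal(spurious_segments(numeric(0), tr)$missed, 2L)
  expect_equal(breakpoint_recall(c(20, 41), tr, tol = 1), 1)
  expect_equal(breakpoint_recall(c(20, 43), tr, tol = 1), 0.5)
})

test_that("event resolution is the five-bin rule times the bin size", {
  expect_equal(cn_resolution(5, 600000), 3e6)
  expect_equal(cn_resolution(5, 150000), 7.5e5)
  expect_equal(cn_resolution(1, 12345), 12345)
})

test_that("profile correlation is scale-invariant with guarded degeneracy", {
  set.seed(2)
  x <- rnorm(500, 1, 0.2)
  expect_equal(profile_pearson(x, x), 1)
  expect_equal(profile_pearson(x, 2 * x), 1)
  expect_warning(r <- profile_pearson(rep(1, 10), rnorm(10)), "zero variance")
  expect_true(is.na(r))
  # two noisy replicates land in the band predicted by the variance split
  tr <- simulate_cn_profile(1000, events = data.frame(
    start = c(100, 600), end = c(400, 700), cn = c(1, 4)))
  a <- normalize_bins(simulate_bin_counts(tr, 1e6, seed = 1), gc_correct = FALSE)
  b <- normalize_bins(simulate_bin_counts(tr, 1e6, seed = 2), gc_correct = FALSE)
  r <- profile_pearson(a, b)
  vs <- var(tr$cn / mean(tr$cn))
  vn <- mean(tr$cn / mean(tr$cn)) * 1000 / 1e6   # ~Poisson ratio noise
  pred <- vs / (vs + vn)
  expect_lt(abs(r - pred), 0.02)
})

test_that("full-depth profiles recover truth end to end", {
  tr <- benchmark_truth()
  prof <- simulate_bin_counts(tr, 2e6, seed = 17)
  fit <- call_cn(prof, params = cbs_params(seed = 17), gc_correct = FALSE)
  expect_gte(breakpoint_recall(fit$segments, tr, tol = 1), 0.95)
  expect_gte(cn_accuracy(fit, tr), 0.99)
  expect_equal(fit$multiplier, 1.9, tolerance = 0.03)
  expect_true(all(fit$segments$n_bins >= 5))
  # segments partition all 5,000 bins
  expect_equal(sum(fit$segments$n_bins), 5000)
})
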