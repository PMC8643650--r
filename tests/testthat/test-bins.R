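test_that("uniform tracks produce equal-width bins with the expected median", {
  tr <- uniform_track(c(chr1 = 3e9), window = 1e5)
  sch <- build_bins(tr, 5000)
  expect_equal(nrow(sch), 5000)
  expect_true(all(sch$end - sch$start == 6e5))
  expect_equal(median(sch$end - sch$start), 6e5)
  one <- build_bins(tr, 1)
  expect_equal(c(one$start, one$end), c(0, 3e9))
  expect_error(build_bins(tr[1:10, ], 50), "exceeds")
})

test_that("bins halve in width where unique-read density doubles", {
  tr <- data.frame(chrom = "chr1", start = 0:199, end = 1:200,
                   weight = c(rep(2, 100), rep(1, 100)))
  sch <- build_bins(tr, 3)
  expect_equal(sch$end - sch$start, c(50, 50, 100))
  expect_equal(sch$weight, rep(100, 3))
})

test_that("equal-mass construction is tight and respects chromosome edges", {
  sch <- build_bins(uniform_track(synthetic_genome(), window = 5e4), 5000)
  expect_equal(nrow(sch), 5000)
  # coefficient of variation of bin mass bounded by one track window's share
  expect_lt(sd(sch$weight) / mean(sch$weight), 5e4 / (sum(synthetic_genome()) / 5000))
  # bins tile each chromosome without crossing its ends
  for (ch in unique(sch$chrom)) {
    b <- sch[sch$chrom == ch, ]
    expect_equal(b$start[-1], b$end[-nrow(b)])
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], unname(synthetic_genome()[ch]))
  }
  expect_true(all(sch$gc > 0.2 & sch$gc < 0.7))
})

test_that("alignment filtering applies the MAPQ threshold and 0x904 mask", {
  rec <- data.frame(read_id = paste0("r", 1:6),
                    chrom = "chr1", position = 1:6 * 100,
                    mapq = c(0, 0, 60, 5, 25, 60),
                    is_unmapped = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                    is_secondary = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                    is_supplementary = FALSE)
  kept <- filter_alignments(rec)
  expect_equal(kept$read_id, c("r5", "r6"))
  expect_equal(nrow(filter_alignments(data.frame(
    mapq = c(19, 20), is_unmapped = FALSE, is_secondary = FALSE,
    is_supplementary = FALSE))), 1)
})

test_that("reads land in bins by leftmost position, half-open", {
  sch <- build_bins(data.frame(chrom = "chr1", start = seq(0, 900, 100),
                               end = seq(100, 1000, 100), weight = 1), 10)
  rec <- data.frame(chrom = "chr1", position = c(0, 99, 100, 999))
  prof <- count_in_bins(rec, sch)
  expect_equal(prof$count, c(2, 1, rep(0, 7), 1))
  expect_equal(prof$outside, 0)
  rec2 <- data.frame(chrom = c("chr1", "chrUn"), position = c(1000, 5))
  expect_warning(prof2 <- count_in_bins(rec2, sch), "chrUn")
  expect_equal(sum(prof2$count), 0)
  expect_equal(prof2$outside, 2)
})

test_that("binned counts equal a brute-force interval scan", {
  set.seed(31)
  sch <- build_bins(uniform_track(c(chrA = 1e6, chrB = 5e5), window = 1e4), 30)
  rec <- data.frame(chrom = sample(c("chrA", "chrB", "chrZ"), 500, replace = TRUE,
                                   prob = c(0.6, 0.35, 0.05)),
                    position = sample.int(1.2e6, 500) - 1L)
  oracle <- brute_count(rec, sch)
  prof <- suppressWarnings(count_in_bins(rec, sch))
  expect_equal(prof$count, oracle$count)
  expect_equal(prof$outside, oracle$outside)
  expect_equal(sum(prof$count) + prof$outside, nrow(rec))
})

test_that("plain normalization centres ratios at exactly one", {
  prof <- normalize_bins(rep(50L, 200), gc_correct = FALSE)
  expect_equal(prof$ratio, rep(1, 200))
  set.seed(4)
  counts <- rpois(300, 100)
  a <- normalize_bins(counts, gc_correct = FALSE)
  expect_lt(abs(mean(a$ratio) - 1), 1e-9)
  # scale invariance
  b <- normalize_bins(counts * 7L, gc_correct = FALSE)
  expect_equal(a$ratio, b$ratio)
  expect_error(normalize_bins(rep(0L, 10)), "zero")
})

test_that("lowess GC correction removes an injected quadratic bias", {
  tr <- simulate_cn_profile(1000, events = NULL, n_events = 0)
  gc <- uniform_track(c(chr1 = 5e8), window = 5e5)$gc
  biased <- simulate_bin_counts(tr, 2e6, gc = gc, gc_bias_strength = 30,
                                seed = 8)
  raw <- normalize_bins(biased, gc_correct = FALSE)
  corr <- normalize_bins(biased, gc = gc, gc_correct = TRUE)
  expect_gt(abs(cor(raw$ratio, exp(-30 * (gc - 0.45)^2))), 0.5)
  expect_lt(abs(cor(corr$ratio, gc)), 0.05)
  expect_lt(abs(cor(corr$ratio, (gc - 0.45)^2)), 0.05)
  expect_error(normalize_bins(c(0L, 0L, 1L, 2L), gc = c(.3, .4, .5, .6),
                              gc_correct = TRUE), "100 bins")
})
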