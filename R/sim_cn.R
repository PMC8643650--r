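#' Synthetic genome chromosome sizes
#'
#' A deterministic, human-like set of 23 chromosome lengths (autosomes plus X,
#' ~3.1 Gbp total) used to give simulated bin schemes a realistic chromosome
#' structure without shipping a reference genome.
#'
#' @param scale Multiplier applied to all lengths.
#' @return Named numeric vector of chromosome sizes in bp.
#' @export
synthetic_genome <- function(scale = 1) {
  mb <- c(chr1 = 249, chr2 = 243, chr3 = 198, chr4 = 191, chr5 = 181,
          chr6 = 171, chr7 = 159, chr8 = 146, chr9 = 141, chr10 = 136,
          chr11 = 135, chr12 = 134, chr13 = 115, chr14 = 107, chr15 = 103,
          chr16 = 90, chr17 = 81, chr18 = 78, chr19 = 59, chr20 = 63,
          chr21 = 48, chr22 = 51, chrX = 155)
  mb * 1e6 * scale
}

#' Uniform mappability track with a smooth synthetic GC profile
#'
#' Produces a windowed genome track carrying per-window unique-read weight
#' (uniform here) and GC fraction.  GC varies smoothly along each chromosome
#' (a long-wavelength sinusoid around 0.41, mimicking isochore-scale GC
#' structure), which is what makes GC-bias injection and correction testable.
#'
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param window Window width in bp (the track's resolution).
#' @return Data frame with columns `chrom`, `start`, `end`, `weight`, `gc`
#'   (0-based half-open coordinates).
#' @export
uniform_track <- function(chrom_sizes = synthetic_genome(), window = 5e4) {
  stopifnot(window > 0, all(chrom_sizes > 0))
  pieces <- lapply(seq_along(chrom_sizes), function(ci) {
    len <- chrom_sizes[ci]
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    mid <- (starts + ends) / 2
    gc <- 0.41 + 0.06 * sin(2 * pi * (mid / 3e7 + ci / 3)) +
      0.02 * sin(2 * pi * mid / 7.1e6)
    data.frame(chrom = names(chrom_sizes)[ci], start = starts, end = ends,
               weight = (ends - starts) / window, gc = gc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Simulate an integer copy-number truth profile
#'
#' Builds a per-bin integer copy-number vector equal to `baseline_cn`
#' everywhere except on the supplied (or randomly drawn) event intervals.
#'
#' @param n_bins Number of bins.
#' @param events Data frame with columns `start`, `end` (0-based half-open bin
#'   indices) and `cn` (integer copy number), or `NULL` to draw `n_events`
#'   random non-overlapping events.
#' @param baseline_cn Background copy number (default diploid, 2).
#' @param purity Tumor cell fraction in `[0, 1]`; the remaining fraction is
#'   assumed diploid at `baseline_cn`.
#' @param n_events Number of random events when `events` is `NULL`.
#' @param seed Optional seed for the random event draw.
#' @return A `sim_truth` list with fields `n_bins`, `cn`, `events`, `purity`,
#'   `baseline_cn`.
#' @export
#' @examples
#' tr <- simulate_cn_profile(100, events = data.frame(start = 20, end = 40, cn = 1))
#' table(tr$cn)
simulate_cn_profile <- function(n_bins, events = NULL, baseline_cn = 2L,
                                purity = 1, n_events = 5L, seed = NULL) {
  stopifnot(n_bins >= 1, baseline_cn >= 0, purity >= 0, purity <= 1)
  if (is.null(events)) {
    events <- with_seed(seed, {
      picked <- data.frame(start = integer(0), end = integer(0), cn = integer(0))
      free <- rep(TRUE, n_bins)
      for (i in seq_len(n_events)) {
        width <- sample(5:max(5, n_bins %/% 10), 1)
        for (try in 1:50) {
          s <- sample.int(n_bins - width + 1, 1) - 1L
          if (all(free[(s + 1):(s + width)])) {
            free[(s + 1):(s + width)] <- FALSE
            picked <- rbind(picked,
                            data.frame(start = s, end = s + width,
                                       cn = sample(c(0L, 1L, 3L, 4L), 1)))
            break
          }
        }
      }
      picked[order(picked$start), , drop = FALSE]
    })
  }
  events <- as.data.frame(events)
  stopifnot(all(c("start", "end", "cn") %in% names(events)))
  if (nrow(events)) {
    stopifnot(all(events$start >= 0), all(events$end <= n_bins),
              all(events$end > events$start), all(events$cn >= 0))
    ev <- events[order(events$start), , drop = FALSE]
    if (nrow(ev) > 1 && any(ev$start[-1] < ev$end[-nrow(ev)]))
      stop("overlapping events")
    events <- ev
  }
  cn <- rep(as.integer(baseline_cn), n_bins)
  for (r in seq_len(nrow(events)))
    cn[(events$start[r] + 1):events$end[r]] <- as.integer(events$cn[r])
  structure(list(n_bins = as.integer(n_bins), cn = cn, events = events,
                 purity = purity, baseline_cn = as.integer(baseline_cn)),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d bins, baseline CN %d, %d events, purity %.2f\n",
              x$n_bins, x$baseline_cn, nrow(x$events), x$purity))
  invisible(x)
}

#' Standard complex-karyotype benchmark truth
#'
#' Deterministic benchmark profile used throughout the package's validation:
#' 5,000 variable bins over the synthetic genome with 30% of bins in
#' single-copy loss (CN 1, large interstitial deletions on eight
#' chromosomes), 10% in focal high-level gain (CN 4, ~40-bin amplicons), and
#' the remainder diploid.  All event boundaries lie at least 5 bins inside
#' their chromosome, so every true breakpoint is interior.
#'
#' @param n_bins Number of bins (default 5,000).
#' @param purity Tumor cell fraction.
#' @return A `sim_truth` whose `scheme` field holds the matching
#'   [build_bins()] bin scheme (with `chrom` and `gc` columns).
#' @export
standard_complex_truth <- function(n_bins = 5000L, purity = 1) {
  scheme <- build_bins(uniform_track(synthetic_genome(), window = 5e4), n_bins)
  bins_per <- table(factor(scheme$chrom, levels = unique(scheme$chrom)))
  offset <- c(0, cumsum(as.numeric(bins_per)))
  names(offset) <- c(names(bins_per), "")
  events <- data.frame(start = integer(0), end = integer(0), cn = integer(0))
  add <- function(events, chrom, cn, width, at = 0.5) {
    nb <- as.integer(bins_per[[chrom]])
    width <- min(width, nb - 12L)
    s <- offset[[chrom]] + max(5L, round(at * (nb - width)))
    rbind(events, data.frame(start = s, end = s + width, cn = cn))
  }
  # CN 1 losses: large interstitial deletions until 30% of bins are covered.
  target1 <- round(0.30 * n_bins)
  for (chrom in c("chr2", "chr4", "chr5", "chr7", "chr9", "chr13",
                  "chr17", "chr18")) {
    left <- target1 - sum(events$end - events$start)
    if (left <= 0) break
    nb <- as.integer(bins_per[[chrom]])
    w <- min(round(0.8 * nb), left)
    if (w < 10) w <- 10L
    events <- add(events, chrom, 1L, w)
  }
  n1 <- nrow(events)
  # CN 4 gains: focal amplicons until 10% of bins are covered.
  target4 <- round(0.10 * n_bins)
  for (chrom in c("chr1", "chr3", "chr6", "chr8", "chr10", "chr11", "chr12",
                  "chr14", "chr15", "chr16", "chr19", "chr20", "chr22")) {
    covered4 <- if (nrow(events) > n1)
      sum(events$end[-seq_len(n1)] - events$start[-seq_len(n1)]) else 0
    left <- target4 - covered4
    if (left <= 0) break
    w <- min(40L, left)
    if (w < 10) w <- 10L
    events <- add(events, chrom, 4L, w, at = 0.35)
  }
  truth <- simulate_cn_profile(n_bins, events = events, baseline_cn = 2L,
                               purity = purity)
  truth$scheme <- scheme
  truth
}

#' Simulate bin-level read counts from a copy-number truth
#'
#' Draws per-bin read counts from a multinomial whose bin probabilities are
#' proportional to `purity * cn + (1 - purity) * baseline_cn`, optionally
#' distorted by a multiplicative GC bias `exp(-strength * (gc - 0.45)^2)`.
#' This is the statistical structure copy-number inference assumes: expected
#' depth proportional to copy number.
#'
#' @param truth A [simulate_cn_profile()] `sim_truth`.
#' @param total_reads Total reads to distribute (the multinomial size).
#' @param gc Optional per-bin GC fraction (defaults to the truth's scheme GC
#'   when present).
#' @param gc_bias_strength Bias strength; 0 disables GC bias.
#' @param seed Optional seed.
#' @return A [bin_profile()] carrying integer `count` per bin (and the
#'   truth's scheme, if any).
#' @export
simulate_bin_counts <- function(truth, total_reads, gc = NULL,
                                gc_bias_strength = 0, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), total_reads >= 0)
  if (is.null(gc) && !is.null(truth$scheme)) gc <- truth$scheme$gc
  eff <- truth$purity * truth$cn + (1 - truth$purity) * truth$baseline_cn
  prob <- as.numeric(eff)
  if (gc_bias_strength != 0) {
    stopifnot(length(gc) == truth$n_bins)
    prob <- prob * exp(-gc_bias_strength * (gc - 0.45)^2)
  }
  if (sum(prob) <= 0) stop("truth has zero total copy mass")
  counts <- with_seed(seed,
                      as.integer(rmultinom(1, size = total_reads, prob = prob)))
  bin_profile(counts, scheme = truth$scheme, gc = gc)
}
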