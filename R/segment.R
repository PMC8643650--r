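#' Segmentation parameters
#'
#' Tuning knobs for circular binary segmentation.  `min_width = 5` encodes
#' the stringent five-contiguous-bin rule: no copy-number transition is
#' called unless every resulting segment holds at least five bins, which at
#' median bin sizes of 600 kb / 150 kb corresponds to event resolutions of
#' 3 Mb / 0.75 Mb.
#'
#' @param alpha Permutation significance level for accepting a split.
#' @param n_perm Number of permutations per test (`>= 100`).
#' @param min_width Minimum segment width in bins (`>= 1`).
#' @param seed Optional seed making segmentation fully deterministic.
#' @return A `cbs_params` list.
#' @export
cbs_params <- function(alpha = 0.01, n_perm = 1000L, min_width = 5L,
                       seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100, min_width >= 1)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), seed = seed),
            class = "cbs_params")
}

#' CBS arc statistic
#'
#' Pooled-variance two-sample t statistic comparing the mean of the circular
#' arc `(i, j]` (0-based cut positions) against the mean of its complement.
#' Symmetric in arc/complement.  Returns `Inf` when the two sides are each
#' constant but differ (perfect separation) and 0 for constant input.
#'
#' @param ratios Numeric vector.
#' @param i,j Cut positions with `0 <= i < j <= length(ratios)`; arc and
#'   complement must both be non-empty.
#' @return Absolute t-like statistic.
#' @export
#' @examples
#' cbs_statistic(c(1, 1, 2, 2, 2, 3), 0, 2)
cbs_statistic <- function(ratios, i, j) {
  n <- length(ratios)
  if (n < 3) stop("need at least 3 observations")
  if (!(i >= 0 && i < j && j <= n)) stop("require 0 <= i < j <= n")
  if (j - i >= n) stop("complement is empty")
  arc <- ratios[(i + 1):j]
  comp <- ratios[-((i + 1):j)]
  k <- length(arc); m <- length(comp)
  d <- mean(arc) - mean(comp)
  sp2 <- (sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)) / (n - 2)
  if (sp2 <= 1e-300) return(if (abs(d) > 1e-12) Inf else 0)
  abs(d) / sqrt(sp2 * (1 / k + 1 / m))
}

#' Exhaustive best-split search (reference implementation)
#'
#' Scans every admissible arc `(i, j]` by brute force and returns the argmax
#' of [cbs_statistic()].  Because an arc and its complement describe the same
#' partition, only canonical arcs with `j < n` are enumerated (the suffix arc
#' `(i, n]` equals the prefix arc `(0, i]`).  This is the slow reference path
#' used to validate the segmentation engine at small `n`; exact ties keep
#' the leftmost `(i, j)` and are flagged.
#'
#' @param ratios Numeric vector (intended for `n <= 200`).
#' @param min_width Minimum width of every non-empty resulting piece; 1
#'   scans all splits.
#' @return List with `i`, `j`, `stat`, and `tie` (TRUE when another candidate
#'   attains the same statistic).
#' @export
exhaustive_best_split <- function(ratios, min_width = 1L) {
  n <- length(ratios)
  S <- c(0, cumsum(ratios))
  Q <- c(0, cumsum(ratios^2))
  best <- list(i = -1L, j = -1L, stat = -Inf, tie = FALSE)
  if (n < 3) return(best)
  for (i in 0:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      if (i > 0 && i < min_width) next
      if (j - i < min_width) next
      if (n - j < min_width) next
      k <- j - i; m <- n - k
      ma <- (S[j + 1] - S[i + 1]) / k
      mc <- (S[n + 1] - S[j + 1] + S[i + 1]) / m
      ssw <- (Q[n + 1] - k * ma^2 - m * mc^2)
      sp2 <- ssw / (n - 2)
      st <- if (sp2 <= 1e-300) {
        if (abs(ma - mc) > 1e-12) Inf else 0
      } else abs(ma - mc) / sqrt(sp2 * (1 / k + 1 / m))
      if (st > best$stat) best <- list(i = i, j = j, stat = st, tie = FALSE)
      else if (st == best$stat) best$tie <- TRUE
    }
  }
  best
}

.segment_recurse <- function(x, offset, params) {
  n <- length(x)
  one <- data.frame(start_bin = offset, end_bin = offset + n)
  if (n < 2 * params$min_width || n < 3) return(one)
  res <- cpp_segment_test(x, params$min_width, params$n_perm, params$alpha)
  if (res$i < 0 || !is.finite(res$p) || res$p >= params$alpha) return(one)
  cuts <- unique(c(res$i, res$j))
  cuts <- cuts[cuts > 0 & cuts < n]
  if (!length(cuts)) return(one)
  bounds <- c(0, cuts, n)
  do.call(rbind, lapply(seq_len(length(bounds) - 1), function(b) {
    .segment_recurse(x[(bounds[b] + 1):bounds[b + 1]], offset + bounds[b],
                     params)
  }))
}

#' Circular binary segmentation of a ratio profile
#'
#' Recursively splits the profile at the maximal arc-vs-complement statistic,
#' accepting a split only when its within-segment permutation p-value falls
#' below `alpha` and every resulting piece holds at least `min_width` bins.
#' When `chrom` labels are supplied, chromosome boundaries are hard breaks
#' and segmentation runs per chromosome.  Deterministic given
#' `params$seed`.
#'
#' @param ratios Normalized ratio vector (see [normalize_bins()]), or a
#'   [bin_profile()] with ratios.
#' @param params A [cbs_params()] object.
#' @param chrom Optional per-bin chromosome labels (taken from the profile's
#'   scheme when a profile is passed).
#' @return A `segment_set` data frame: `chrom` (if given), `start_bin`,
#'   `end_bin` (0-based half-open global bin indices), `n_bins`,
#'   `mean_ratio`.  Segments partition the profile.
#' @export
segment_ratios <- function(ratios, params = cbs_params(), chrom = NULL) {
  if (inherits(ratios, "bin_profile")) {
    if (is.null(ratios$ratio)) stop("profile is not normalized yet")
    if (is.null(chrom) && !is.null(ratios$scheme)) chrom <- ratios$scheme$chrom
    ratios <- ratios$ratio
  }
  stopifnot(is.numeric(ratios), !anyNA(ratios))
  n <- length(ratios)
  if (n < 2 * params$min_width)
    warning("profile shorter than twice the minimum segment width; ",
            "returning a single segment")
  segs <- with_seed(params$seed, {
    if (is.null(chrom)) {
      .segment_recurse(ratios, 0L, params)
    } else {
      stopifnot(length(chrom) == n)
      runs <- rle(as.character(chrom))
      off <- c(0L, cumsum(runs$lengths))
      out <- lapply(seq_along(runs$values), function(ci) {
        s <- .segment_recurse(ratios[(off[ci] + 1):off[ci + 1]], off[ci],
                              params)
        s$chrom <- runs$values[ci]
        s
      })
      do.call(rbind, out)
    }
  })
  segs$n_bins <- segs$end_bin - segs$start_bin
  segs$mean_ratio <- vapply(seq_len(nrow(segs)), function(s)
    mean(ratios[(segs$start_bin[s] + 1):segs$end_bin[s]]), numeric(1))
  if (!is.null(chrom)) segs <- segs[c("chrom", "start_bin", "end_bin",
                                      "n_bins", "mean_ratio")]
  rownames(segs) <- NULL
  class(segs) <- c("segment_set", "data.frame")
  segs
}

#' Interior segment boundaries
#'
#' Cut positions between adjacent segments in global bin coordinates,
#' excluding chromosome starts (which are forced breaks, not data-driven
#' transitions) and the profile ends.
#'
#' @param segments A `segment_set` from [segment_ratios()].
#' @return Integer vector of boundary positions.
#' @export
segment_boundaries <- function(segments) {
  b <- segments$start_bin
  if (!is.null(segments$chrom)) {
    first <- !duplicated(segments$chrom)
    b <- b[!first]
  } else {
    b <- b[-1]
  }
  sort(unique(b))
}
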