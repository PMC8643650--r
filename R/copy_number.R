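#' Fit segment ratios to absolute integer copy numbers
#'
#' Searches a grid of multipliers `m` (the ploidy scale mapping ratios to
#' copies) for the value minimising the bin-weighted least-squares distance
#' of scaled segment ratios to integers,
#' `sum_s n_s * (r_s * m - round(r_s * m))^2`, then assigns each segment the
#' integer `round(r_s * m)`.  Exact ties break toward the smallest
#' multiplier.  A flat profile (all segment ratios equal, the
#' normal-karyotype case) cannot identify ploidy from depth alone; with
#' `diploid_fallback = TRUE` (default) it is called diploid and flagged
#' `ploidy_unresolvable`.
#'
#' @param segments A `segment_set` from [segment_ratios()].
#' @param grid Candidate multipliers, strictly positive (default 0.55-8.0 in
#'   steps of 0.01; a step this fine keeps the true ratio scale from falling
#'   between grid points, which would let a doubled multiplier win the fit).
#' @param diploid_fallback Resolve the flat-profile degeneracy to ploidy 2.
#' @return A `cn_profile` list: `segments` (with an integer `cn` column),
#'   `multiplier`, `fit_error`, `ploidy_unresolvable`, and `cn_per_bin`.
#' @export
#' @examples
#' segs <- data.frame(start_bin = c(0, 10, 20), end_bin = c(10, 20, 30),
#'                    n_bins = 10, mean_ratio = c(0.5, 1.0, 1.5))
#' fit_absolute(segs)$multiplier  # 2: ratios scale exactly to CN 1,2,3
fit_absolute <- function(segments, grid = seq(0.55, 8, by = 0.01),
                         diploid_fallback = TRUE) {
  if (is.null(segments) || nrow(segments) == 0) stop("empty segment set")
  stopifnot(all(grid > 0))
  r <- segments$mean_ratio
  w <- segments$n_bins
  sc <- outer(r, grid)                       # segments x grid
  obj <- colSums(w * (sc - round(sc))^2)
  best <- which.min(obj)                     # first minimum = smallest m
  multiplier <- grid[best]
  unresolvable <- FALSE
  if (diploid_fallback && (max(r) - min(r)) < 1e-6) {
    multiplier <- 2
    unresolvable <- TRUE
  }
  cn <- pmax(0L, as.integer(round(r * multiplier)))
  segments$cn <- cn
  fit_error <- sum(w * (r * multiplier - round(r * multiplier))^2)
  structure(list(segments = segments, multiplier = multiplier,
                 fit_error = fit_error, ploidy_unresolvable = unresolvable,
                 cn_per_bin = rep(cn, segments$n_bins)),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf(paste0("cn_profile: %d segments over %d bins, multiplier %.2f",
                     " (fit error %.4g)%s\n"),
              nrow(x$segments), length(x$cn_per_bin), x$multiplier,
              x$fit_error,
              if (x$ploidy_unresolvable) " [ploidy unresolvable from data]"
              else ""))
  print(head(as.data.frame(x$segments), 8))
  invisible(x)
}

#' Downsample a bin-count profile
#'
#' Draws a multivariate hypergeometric subsample of the bin counts summing
#' exactly to `n`, equivalent in distribution to subsampling reads without
#' replacement before counting.  Used for the read-depth resolution
#' analysis.
#'
#' @param profile A [bin_profile()] or bare count vector.
#' @param n Target total reads (`<=` current total).
#' @param seed Optional seed.
#' @return A profile of the same shape with downsampled counts (any previous
#'   ratios are dropped).
#' @export
downsample_counts <- function(profile, n, seed = NULL) {
  prof <- if (inherits(profile, "bin_profile")) profile else bin_profile(profile)
  counts <- prof$count
  total <- sum(counts)
  if (n > total) stop("cannot downsample to more reads than available")
  out <- with_seed(seed, {
    res <- integer(length(counts))
    remaining <- total
    left <- as.integer(n)
    for (i in seq_along(counts)) {
      remaining <- remaining - counts[i]
      k <- rhyper(1, counts[i], remaining, left)
      res[i] <- k
      left <- left - k
      if (left == 0) break
    }
    res
  })
  bin_profile(out, scheme = prof$scheme, gc = prof$gc, outside = prof$outside)
}

#' Count spurious and missed segment boundaries against a known truth
#'
#' A called boundary is spurious when no true copy-number transition lies
#' within `tol` bins of it; a true transition is missed when no called
#' boundary lies within `tol` bins.  Chromosome starts are never counted as
#' called boundaries (they are forced breaks).
#'
#' @param called A `segment_set` (or integer vector of called boundary
#'   positions in bins).
#' @param truth A `sim_truth` (or integer vector of true boundary positions).
#' @param tol Matching tolerance in bins.
#' @return List with integer fields `spurious` and `missed`.
#' @export
spurious_segments <- function(called, truth, tol = 2L) {
  cb <- if (is.numeric(called)) sort(unique(called)) else segment_boundaries(called)
  tb <- if (inherits(truth, "sim_truth")) truth_boundaries(truth)
        else sort(unique(truth))
  near <- function(x, ref) length(ref) > 0 && min(abs(ref - x)) <= tol
  list(spurious = sum(!vapply(cb, near, logical(1), ref = tb)),
       missed = sum(!vapply(tb, near, logical(1), ref = cb)))
}

#' True copy-number transition positions of a simulated truth
#'
#' @param truth A `sim_truth`.
#' @return Sorted integer vector of bin cut positions where the true copy
#'   number changes.
#' @export
truth_boundaries <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  which(diff(truth$cn) != 0)
}

#' Fraction of true breakpoints recovered
#'
#' @param called A `segment_set` or boundary vector.
#' @param truth A `sim_truth` or boundary vector.
#' @param tol Tolerance in bins for declaring a breakpoint recovered.
#' @return Fraction in `[0, 1]` (1 when there are no true breakpoints).
#' @export
breakpoint_recall <- function(called, truth, tol = 1L) {
  cb <- if (is.numeric(called)) sort(unique(called)) else segment_boundaries(called)
  tb <- if (inherits(truth, "sim_truth")) truth_boundaries(truth)
        else sort(unique(truth))
  if (!length(tb)) return(1)
  mean(vapply(tb, function(x) length(cb) > 0 && min(abs(cb - x)) <= tol,
              logical(1)))
}

#' Per-bin integer copy-number accuracy against a known truth
#'
#' @param fit A `cn_profile` from [fit_absolute()].
#' @param truth A `sim_truth`.
#' @return Fraction of bins whose called integer copy number equals the
#'   truth.
#' @export
cn_accuracy <- function(fit, truth) {
  stopifnot(inherits(fit, "cn_profile"), inherits(truth, "sim_truth"),
            length(fit$cn_per_bin) == truth$n_bins)
  mean(fit$cn_per_bin == truth$cn)
}

#' Copy-number event resolution
#'
#' The smallest detectable event span: the minimum segment width times the
#' median bin length.  At the five-bin rule this is 3 Mb for 600 kb bins
#' (5,000-bin analysis) and 0.75 Mb for 150 kb bins (20,000-bin analysis).
#'
#' @param min_width Minimum segment width in bins.
#' @param median_bin_bp Median bin length in bp.
#' @return Resolution in bp.
#' @export
#' @examples
#' cn_resolution(5, 600000)   # 3 Mb
#' cn_resolution(5, 150000)   # 0.75 Mb
cn_resolution <- function(min_width, median_bin_bp) {
  stopifnot(min_width >= 1, median_bin_bp >= 1)
  min_width * median_bin_bp
}

#' Pearson correlation between two ratio profiles
#'
#' Standard Pearson correlation over paired bins, the concordance metric
#' used to compare copy-number profiles across platforms or runs.
#'
#' @param a,b [bin_profile()]s with ratios, or bare numeric vectors, of equal
#'   length on the same bin scheme.
#' @return Pearson r in `[-1, 1]`; `NA` (with a warning) when either profile
#'   has zero variance.
#' @export
profile_pearson <- function(a, b) {
  val <- function(x) {
    if (inherits(x, "bin_profile")) {
      if (is.null(x$ratio)) stop("profile is not normalized")
      x$ratio
    } else as.numeric(x)
  }
  av <- val(a); bv <- val(b)
  if (length(av) != length(bv)) stop("profiles differ in length")
  if (sd(av) == 0 || sd(bv) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(av, bv)
}
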