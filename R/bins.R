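#' Build variable-width bins of equal expected unique-read mass
#'
#' Divides the genome into `n_bins` intervals so that each interval carries
#' (as nearly as the track resolution allows) the same expected number of
#' uniquely mappable reads: bins are narrow where unique-read density is high
#' and wide where it is low, so downstream count differences reflect copy
#' number rather than mappability.  Bins are allocated to chromosomes in
#' proportion to their total mass (largest-remainder rounding, at least one
#' per chromosome) and then placed by greedy cumulative-mass cuts at track
#' window boundaries; bins never cross a chromosome boundary.  On a uniform
#' track over ~3 Gbp, `n_bins = 5000` gives ~600 kb bins and
#' `n_bins = 20000` gives ~150 kb bins.
#'
#' @param track Data frame with columns `chrom`, `start`, `end`, `weight`
#'   (expected unique-read mass per window) and optionally `gc` (see
#'   [uniform_track()]).
#' @param n_bins Number of bins (`>= 1`, at most the number of track windows).
#' @return A `bin_scheme` data frame: `chrom`, `start`, `end` (0-based
#'   half-open bp), `gc` (mass-weighted window mean, `NA` without a GC
#'   track), `weight` (realised mass).
#' @export
build_bins <- function(track, n_bins) {
  stopifnot(all(c("chrom", "start", "end", "weight") %in% names(track)),
            n_bins >= 1)
  if (n_bins > nrow(track))
    stop("n_bins exceeds the number of track windows")
  total <- sum(track$weight)
  if (total <= 0) stop("track has no mass")
  chroms <- unique(track$chrom)
  mass_c <- vapply(chroms, function(ch) sum(track$weight[track$chrom == ch]),
                   numeric(1))
  # largest-remainder allocation, at least 1 bin per chromosome
  raw <- n_bins * mass_c / total
  alloc <- pmax(1L, floor(raw))
  rem <- n_bins - sum(alloc)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    alloc[extra[seq_len(rem)]] <- alloc[extra[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    shrink <- order(raw - floor(raw))
    for (i in shrink) {
      if (rem == 0) break
      if (alloc[i] > 1) { alloc[i] <- alloc[i] - 1L; rem <- rem + 1L }
    }
  }
  has_gc <- "gc" %in% names(track)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    tw <- track[track$chrom == chroms[ci], , drop = FALSE]
    tw <- tw[order(tw$start), , drop = FALSE]
    nb <- alloc[ci]
    target <- mass_c[ci] / nb
    cum <- cumsum(tw$weight)
    # cut after the window where cumulative mass first reaches k * target
    # relative epsilon: a window whose cumulative mass equals the target up
    # to float roundoff closes the bin
    cuts <- findInterval(seq_len(nb - 1) * target * (1 - 1e-12), cum) + 1L
    cuts <- pmin(pmax(cuts, seq_len(nb - 1)), nrow(tw) - (nb - 1):1)
    if (nb > 2)  # keep cuts strictly increasing (one window per bin minimum)
      for (k in 2:(nb - 1))
        if (cuts[k] <= cuts[k - 1]) cuts[k] <- cuts[k - 1] + 1L
    lo <- c(1L, cuts + 1L)
    hi <- c(cuts, nrow(tw))
    gc <- rep(NA_real_, nb)
    wt <- numeric(nb)
    for (b in seq_len(nb)) {
      idx <- lo[b]:hi[b]
      wt[b] <- sum(tw$weight[idx])
      if (has_gc)
        gc[b] <- sum(tw$gc[idx] * tw$weight[idx]) / max(wt[b], 1e-300)
    }
    out[[ci]] <- data.frame(chrom = chroms[ci], start = tw$start[lo],
                            end = tw$end[hi], gc = gc, weight = wt,
                            stringsAsFactors = FALSE)
  }
  scheme <- do.call(rbind, out)
  rownames(scheme) <- NULL
  class(scheme) <- c("bin_scheme", "data.frame")
  scheme
}

#' Construct a bin profile
#'
#' A bin profile couples per-bin read counts (and, after [normalize_bins()],
#' normalized ratios) to an optional bin scheme.
#'
#' @param count Integer vector of per-bin counts.
#' @param scheme Optional [build_bins()] scheme with one row per bin.
#' @param gc Optional per-bin GC fraction (defaults to the scheme's).
#' @param ratio Optional normalized ratio vector.
#' @param outside Reads falling outside all bins.
#' @return A `bin_profile` list.
#' @export
bin_profile <- function(count, scheme = NULL, gc = NULL, ratio = NULL,
                        outside = 0L) {
  count <- as.integer(count)
  if (any(count < 0)) stop("counts must be >= 0")
  if (!is.null(scheme) && nrow(scheme) != length(count))
    stop("scheme and counts disagree on the number of bins")
  if (is.null(gc) && !is.null(scheme)) gc <- scheme$gc
  structure(list(count = count, ratio = ratio, gc = gc, scheme = scheme,
                 outside = as.integer(outside)),
            class = "bin_profile")
}

#' @export
print.bin_profile <- function(x, ...) {
  cat(sprintf("bin_profile: %d bins, %s reads%s%s\n", length(x$count),
              format(sum(x$count), big.mark = ","),
              if (x$outside) sprintf(" (+%d outside bins)", x$outside) else "",
              if (is.null(x$ratio)) "" else ", normalized"))
  invisible(x)
}

#' Count filtered alignments in bins
#'
#' Assigns each record to the bin containing its 0-based leftmost mapped
#' position (bins are half-open, so a read at a bin's `end` belongs to the
#' next bin).  Reads on unknown chromosomes or outside every bin are tallied
#' separately, never dropped silently.
#'
#' @param records Filtered alignment records (see [filter_alignments()]).
#' @param scheme A [build_bins()] scheme.
#' @return A [bin_profile()] with counts and the `outside` tally.
#' @export
count_in_bins <- function(records, scheme) {
  counts <- integer(nrow(scheme))
  outside <- 0L
  unknown <- setdiff(unique(records$chrom), unique(scheme$chrom))
  if (length(unknown))
    warning("reads on chromosomes absent from the bin scheme: ",
            paste(unknown, collapse = ", "))
  for (ch in unique(scheme$chrom)) {
    rows <- which(scheme$chrom == ch)
    pos <- records$position[records$chrom == ch]
    if (!length(pos)) next
    # bins are sorted and contiguous within a chromosome
    idx <- findInterval(pos, scheme$start[rows])
    inb <- idx >= 1 & pos < scheme$end[rows][pmax(idx, 1)]
    outside <- outside + sum(!inb)
    tab <- tabulate(idx[inb], nbins = length(rows))
    counts[rows] <- counts[rows] + tab
  }
  outside <- outside + sum(records$chrom %in% unknown)
  bin_profile(counts, scheme = scheme, outside = outside)
}

#' Normalize bin counts to a ratio profile
#'
#' Divides counts by their mean and, when a GC track is supplied, removes
#' GC bias by dividing by a lowess fit of ratio against GC fraction, then
#' rescales so the mean ratio is exactly 1.  A ratio of 1 is the average copy
#' state; deviations are proportional to copy number.
#'
#' @param profile A [bin_profile()] (or bare count vector).
#' @param gc Per-bin GC fraction; defaults to the profile's own.  Set to
#'   `NULL` with `gc_correct = FALSE` for plain mean normalization.
#' @param gc_correct Whether to apply the lowess GC correction.
#' @param span Lowess smoother span in the GC dimension.
#' @return The profile with its `ratio` field filled.
#' @export
normalize_bins <- function(profile, gc = NULL, gc_correct = !is.null(gc_used),
                           span = 0.3) {
  if (!inherits(profile, "bin_profile")) profile <- bin_profile(profile)
  gc_used <- gc %||% profile$gc
  if (all(is.na(gc_used %||% NA))) gc_used <- NULL
  force(gc_correct)
  count <- profile$count
  if (all(count == 0)) stop("all bin counts are zero")
  ratio <- count / mean(count)
  if (gc_correct) {
    if (is.null(gc_used)) stop("gc_correct = TRUE but no GC values available")
    nz <- count > 0
    if (sum(nz) < 100)
      stop("need at least 100 bins with nonzero counts for the GC fit")
    fit <- lowess(gc_used[nz], ratio[nz], f = span)
    pred <- approx(fit$x, fit$y, xout = gc_used, rule = 2, ties = mean)$y
    pred[pred <= 0] <- min(pred[pred > 0])
    ratio <- ratio / pred
  }
  profile$ratio <- ratio / mean(ratio)
  profile$gc <- gc_used
  profile
}
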