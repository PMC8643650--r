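#' End-to-end copy-number calling from bin counts
#'
#' Convenience wrapper chaining the pipeline stages: [normalize_bins()] (with
#' GC correction when GC values are available), [segment_ratios()] per
#' chromosome, and [fit_absolute()].
#'
#' @param profile A [bin_profile()] with counts (or a bare count vector).
#' @param params A [cbs_params()] object.
#' @param grid Multiplier grid for [fit_absolute()].
#' @param gc_correct Apply the lowess GC correction (default: when GC values
#'   are present).
#' @param ... Passed on to [fit_absolute()].
#' @return A `cn_profile`; its `segments` carry bp coordinates when the
#'   profile has a bin scheme, and the normalized profile is attached as
#'   `$profile`.
#' @export
#' @examples
#' truth <- simulate_cn_profile(300, events = data.frame(
#'   start = c(50, 200), end = c(120, 240), cn = c(1, 4)))
#' counts <- simulate_bin_counts(truth, 3e5, seed = 1)
#' fit <- call_cn(counts, params = cbs_params(seed = 1))
#' fit$segments
call_cn <- function(profile, params = cbs_params(), grid = seq(0.55, 8, 0.01),
                    gc_correct = NULL, ...) {
  if (!inherits(profile, "bin_profile")) profile <- bin_profile(profile)
  has_gc <- !is.null(profile$gc) && !all(is.na(profile$gc))
  gc_correct <- gc_correct %||% has_gc
  prof <- normalize_bins(profile, gc_correct = gc_correct)
  segs <- segment_ratios(prof, params = params)
  fit <- fit_absolute(segs, grid = grid, ...)
  if (!is.null(prof$scheme)) {
    sch <- prof$scheme
    fit$segments$start_bp <- sch$start[fit$segments$start_bin + 1]
    fit$segments$end_bp <- sch$end[fit$segments$end_bin]
  }
  fit$profile <- prof
  fit
}
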