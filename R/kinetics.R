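#' Cumulative reads over time
#'
#' Counts, at each time point of `grid`, the reads whose sequencing has
#' finished (a read contributes once its end time `start_time + duration` has
#' passed), i.e. a cumulative sum of completed molecules over the run.
#'
#' @param summary A `run_summary` data frame (see [simulate_run()] /
#'   [read_sequencing_summary()]).
#' @param grid Sorted ascending vector of time points in seconds.
#' @return Integer vector of counts, one per grid point; non-decreasing and
#'   ending at the total read count once the grid passes the last read.
#' @export
cumulative_reads <- function(summary, grid) {
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  ends <- sort(summary$start_time + summary$duration)
  findInterval(grid, ends)
}

#' Channel lifetimes
#'
#' The lifetime of a channel is the time it finished sequencing its final
#' read.  Channels that produced no reads are absent from the result.
#'
#' @param summary A `run_summary` data frame.
#' @return Named numeric vector (seconds), names = channel numbers.
#' @export
channel_lifetimes <- function(summary) {
  if (!nrow(summary)) return(stats::setNames(numeric(0), character(0)))
  ends <- summary$start_time + summary$duration
  out <- tapply(ends, summary$channel, max)
  stats::setNames(as.numeric(out), names(out))
}

#' Pore vacancy times
#'
#' Idle gaps between consecutive reads of the same pore within the same
#' channel: `next start - previous end`.  Consecutive reads sequenced by
#' different pores of a channel contribute no gap.
#'
#' @param summary A `run_summary` data frame.
#' @return Numeric vector of gap durations in seconds (all `>= 0` on valid
#'   input).
#' @export
vacancy_times <- function(summary) {
  if (!nrow(summary)) return(numeric(0))
  key <- interaction(summary$channel, summary$pore, drop = TRUE)
  gaps <- lapply(split(summary[c("start_time", "duration")], key), function(d) {
    d <- d[order(d$start_time), , drop = FALSE]
    if (nrow(d) < 2) return(numeric(0))
    g <- d$start_time[-1] - (d$start_time + d$duration)[-nrow(d)]
    if (any(g < -1e-9))
      stop("overlapping reads within a (channel, pore): invalid run summary")
    g
  })
  unname(unlist(gaps))
}

#' Residence time of a molecule in a pore
#'
#' Time a molecule spends translocating: `length / speed`.  At 450 bases per
#' second a 10 kb molecule occupies its pore for ~22 s versus ~1 s for a
#' 400 bp molecule, which is why short libraries return more molecules.
#'
#' @param length Molecule length in bases (`>= 0`).
#' @param speed Sequencing speed in bases per second (`> 0`).
#' @return Residence time in seconds.
#' @export
#' @examples
#' residence_time(10000, 450)   # ~22 s
#' residence_time(400, 450)     # ~1 s
residence_time <- function(length, speed = 450) {
  if (any(speed <= 0)) stop("speed must be > 0")
  if (any(length < 0)) stop("length must be >= 0")
  length / speed
}

#' Channel activity matrix
#'
#' Divides the run into fixed windows (five minutes by default) and marks a
#' channel/window cell `TRUE` if the channel sequenced any length of a read
#' during that window; a read spanning several windows marks all of them.
#'
#' @param summary A `run_summary` data frame.
#' @param window Window width in seconds.
#' @param n_channels Number of rows; defaults to the largest channel seen.
#' @param run_duration Run length in seconds; defaults to the last read end.
#' @return Logical matrix `n_channels x n_windows`.
#' @export
channel_activity <- function(summary, window = 300, n_channels = NULL,
                             run_duration = NULL) {
  stopifnot(window > 0)
  ends <- summary$start_time + summary$duration
  run_duration <- run_duration %||% if (nrow(summary)) max(ends) else window
  n_channels <- n_channels %||% if (nrow(summary)) max(summary$channel) else 0L
  n_win <- max(1L, as.integer(ceiling(run_duration / window)))
  mat <- matrix(FALSE, nrow = n_channels, ncol = n_win)
  if (nrow(summary)) {
    w0 <- pmax(0L, as.integer(floor(summary$start_time / window)))
    w1 <- pmin(n_win - 1L, as.integer(ceiling(ends / window)) - 1L)
    for (r in seq_len(nrow(summary)))
      mat[summary$channel[r], (w0[r]:w1[r]) + 1L] <- TRUE
  }
  mat
}

#' Relative reads per channel
#'
#' Total reads divided by the number of channels on the device (512 for a
#' MinION flow cell, 126 for a Flongle), putting yields from devices with
#' different channel counts on a common scale.
#'
#' @param total_reads Total read count.
#' @param n_channels Channels on the device (`>= 1`).
#' @return Dimensionless reads-per-channel value.
#' @export
relative_reads_per_channel <- function(total_reads, n_channels) {
  if (any(n_channels < 1)) stop("n_channels must be >= 1")
  total_reads / n_channels
}

#' Mapping quality from alignment error probability
#'
#' `MAPQ = -10 * log10(Pr(alignment is wrong))`, rounded and capped at the
#' aligner maximum of 60.
#'
#' @param p Error probability in `(0, 1]`.
#' @return Integer MAPQ in `[0, 60]`.
#' @export
#' @examples
#' mapq_from_error_prob(1e-6)  # 60, the reported cap
mapq_from_error_prob <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p must be in (0, 1]")
  as.integer(pmin(60L, round(-10 * log10(p))))
}

#' Length-stratified mapping outcome fractions
#'
#' Partitions alignment records into read-length strata and computes, within
#' each stratum, the fractions of unaligned reads, reads with perfect MAPQ
#' (60), and reads with sub-optimal MAPQ.  Used to pick a molecule length
#' that still maps uniquely: mappability degrades as reads shorten.
#'
#' @param records Alignment records data frame (see [read_alignments()]);
#'   needs `read_length`, `mapq`, `is_unmapped`.
#' @param length_bins Stratum boundaries in bp.  The default makes 100 bp
#'   strata from 100 bp to 1 kb with open-ended guard strata on both sides.
#' @return Data frame with one row per non-empty stratum: `stratum`, `n`,
#'   `unaligned`, `perfect`, `suboptimal` (the three fractions sum to 1).
#' @export
length_stratified_mapq_fractions <- function(records,
                                             length_bins = c(0, seq(100, 1000, 100), Inf)) {
  if (is.unsorted(length_bins)) stop("length_bins must be sorted")
  stratum <- cut(records$read_length, breaks = length_bins, right = FALSE)
  out <- lapply(split(records, stratum, drop = TRUE), function(d) {
    n <- nrow(d)
    una <- sum(d$is_unmapped)
    per <- sum(!d$is_unmapped & d$mapq == 60)
    data.frame(n = n, unaligned = una / n, perfect = per / n,
               suboptimal = (n - una - per) / n)
  })
  res <- do.call(rbind, out)
  data.frame(stratum = rownames(res), res, row.names = NULL,
             stringsAsFactors = FALSE)
}
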