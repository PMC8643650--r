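#' Parameters for a simulated nanopore sequencing run
#'
#' Bundles the knobs of the pore-kinetics simulator.  The defaults describe a
#' MinION-like device (512 channels) running for 48 hours at 450 bases per
#' second on a short-fragment library (median 500 bp), the configuration that
#' maximises molecule yield in short-molecule sequencing.
#'
#' @param n_channels Number of addressable channels (512 MinION-like,
#'   126 Flongle-like).
#' @param run_duration Run length in seconds (default 48 h).
#' @param speed Sequencing speed in bases per second.
#' @param median_bp Median read length in bases of the loaded library.
#' @param sdlog Log-scale dispersion of the log-normal read-length
#'   distribution; 0 gives fixed-length reads.
#' @param min_length Lower floor on read length in bases.
#' @param mean_vacancy Mean pore vacancy time in seconds at 1 molar
#'   equivalent: the idle gap between the end of one read and the start of
#'   the next within a pore.  Scaled down by `loading_factor` (more molecules
#'   dock faster).
#' @param channel_death_hazard Per-hour hazard of a channel dying; scaled up
#'   by `loading_factor` (over-loaded flow cells decay faster).  0 keeps all
#'   channels alive for the whole run.
#' @param loading_factor Library loading concentration in molar equivalents
#'   (ME) of the manufacturer-suggested amount.
#' @param n_pores Pores (muxes) sequencing independently per channel.
#' @param vacancy_model `"exponential"` (default) or `"fixed"` (deterministic
#'   gaps, useful for exact kinetics checks).
#' @param qscore_mean,qscore_sd Normal model for per-read mean Q-scores.
#' @param pass_q Q-score pass-filter threshold.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A `run_sim_params` list.
#' @export
#' @examples
#' p <- run_sim_params(n_channels = 8, run_duration = 3600)
#' run <- simulate_run(p)
run_sim_params <- function(n_channels = 512L, run_duration = 48 * 3600,
                           speed = 450, median_bp = 500, sdlog = 0.55,
                           min_length = 50, mean_vacancy = 10,
                           channel_death_hazard = 0.02, loading_factor = 1,
                           n_pores = 1L, vacancy_model = c("exponential", "fixed"),
                           qscore_mean = 10, qscore_sd = 1.5, pass_q = 7,
                           seed = NULL) {
  vacancy_model <- match.arg(vacancy_model)
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (run_duration < 0) stop("run_duration must be >= 0")
  if (speed <= 0) stop("speed must be > 0")
  if (median_bp <= 0) stop("median_bp must be > 0")
  if (mean_vacancy <= 0) stop("mean_vacancy must be > 0")
  if (channel_death_hazard < 0) stop("channel_death_hazard must be >= 0")
  if (loading_factor <= 0) stop("loading_factor must be > 0")
  structure(list(n_channels = as.integer(n_channels),
                 run_duration = run_duration, speed = speed,
                 median_bp = median_bp, sdlog = sdlog,
                 min_length = min_length, mean_vacancy = mean_vacancy,
                 channel_death_hazard = channel_death_hazard,
                 loading_factor = loading_factor, n_pores = as.integer(n_pores),
                 vacancy_model = vacancy_model, qscore_mean = qscore_mean,
                 qscore_sd = qscore_sd, pass_q = pass_q, seed = seed),
            class = "run_sim_params")
}

#' Simulate a nanopore sequencing run
#'
#' Generates a per-read run summary from a simple pore-occupancy model.  Each
#' pore alternates between a vacancy gap and a read whose residence time is
#' `length / speed`; channels die with an exponential lifetime whose hazard
#' grows with loading concentration, and vacancy gaps shrink with loading
#' concentration.  Only reads that finish before both the run end and their
#' channel's death are emitted, so shorter libraries return more molecules
#' over a fixed run.
#'
#' @param params A [run_sim_params()] object.
#' @return A `run_summary` data frame with columns `read_id`, `channel`,
#'   `pore`, `start_time`, `duration` (seconds), `length` (bases), `mean_q`
#'   and `pass`, sorted by start time.
#' @seealso [vacancy_times()], [channel_lifetimes()], [cumulative_reads()]
#' @export
simulate_run <- function(params) {
  stopifnot(inherits(params, "run_sim_params"))
  p <- params
  with_seed(p$seed, {
    vac_mean <- p$mean_vacancy / p$loading_factor
    res_med <- p$median_bp / p$speed
    cycle <- res_med + vac_mean
    out <- vector("list", p$n_channels * p$n_pores)
    k <- 0L
    for (ch in seq_len(p$n_channels)) {
      death <- if (p$channel_death_hazard > 0)
        rexp(1, rate = p$channel_death_hazard * p$loading_factor) * 3600
      else Inf
      horizon <- min(p$run_duration, death)
      for (po in seq_len(p$n_pores)) {
        k <- k + 1L
        if (horizon <= 0) next
        lens <- numeric(0); vacs <- numeric(0)
        repeat {
          need <- ceiling(max(horizon - sum(lens / p$speed + vacs), 0) /
                            cycle * 1.3) + 10
          lens <- c(lens, round(pmax(p$min_length,
                                     rlnorm(need, meanlog = log(p$median_bp),
                                            sdlog = p$sdlog))))
          vacs <- c(vacs, if (p$vacancy_model == "fixed") rep(vac_mean, need)
                    else rexp(need, rate = 1 / vac_mean))
          if (sum(lens / p$speed + vacs) >= horizon) break
        }
        dur <- lens / p$speed
        ends <- cumsum(vacs + dur)
        keep <- ends <= horizon
        if (!any(keep)) next
        out[[k]] <- data.frame(channel = ch, pore = po,
                               start_time = ends[keep] - dur[keep],
                               duration = dur[keep],
                               length = lens[keep])
      }
    }
    reads <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(reads))
      reads <- data.frame(channel = integer(0), pore = integer(0),
                          start_time = numeric(0), duration = numeric(0),
                          length = numeric(0))
    reads <- reads[order(reads$start_time), , drop = FALSE]
    n <- nrow(reads)
    reads <- data.frame(read_id = sprintf("read-%07d", seq_len(n))[seq_len(n)],
                        reads,
                        mean_q = if (n) rnorm(n, p$qscore_mean, p$qscore_sd)
                        else numeric(0),
                        stringsAsFactors = FALSE)
    reads$pass <- reads$mean_q >= p$pass_q
    rownames(reads) <- NULL
    class(reads) <- c("run_summary", "data.frame")
    reads
  })
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("run_summary: %d reads on %d channels", nrow(x),
              length(unique(x$channel))))
  if (nrow(x))
    cat(sprintf("; median length %.0f bp; last read ends %.1f h",
                median(x$length), max(x$start_time + x$duration) / 3600))
  cat("\n")
  if (nrow(x)) print(head(as.data.frame(x), 5))
  invisible(x)
}
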