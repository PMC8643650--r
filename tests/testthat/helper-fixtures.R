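# Shared fixtures built in code.

# A tiny run summary laid out by hand: two channels, channel 1 has two pores.
toy_summary <- function() {
  structure(data.frame(
    read_id = paste0("r", 1:5),
    channel = c(1L, 1L, 1L, 2L, 2L),
    pore = c(1L, 1L, 2L, 1L, 1L),
    start_time = c(0, 4, 2, 10, 30),
    duration = c(1, 1, 3, 5, 2),
    length = c(450, 450, 1350, 2250, 900),
    mean_q = c(10, 11, 9, 8, 12),
    pass = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  ), class = c("run_summary", "data.frame"))
}

# Deterministic pore-kinetics configuration: fixed 450 bp reads at 450 bp/s
# (1 s residence), fixed 5 s vacancy, immortal channels.
deterministic_params <- function(n_channels = 4L, run_duration = 600) {
  run_sim_params(n_channels = n_channels, run_duration = run_duration,
                 speed = 450, median_bp = 450, sdlog = 0, mean_vacancy = 5,
                 vacancy_model = "fixed", channel_death_hazard = 0, seed = 42)
}

# Noisy step profile with a single elevated block; truth cut positions are
# `from` and `to`.
noisy_step <- function(n = 100, from = 50, to = n, shift = 1, sd = 0.05) {
  x <- rnorm(n, 1, sd)
  x[(from + 1):to] <- x[(from + 1):to] + shift
  x
}

# O(n*m) brute-force bin counter used as oracle for count_in_bins().
brute_count <- function(records, scheme) {
  counts <- integer(nrow(scheme))
  outside <- 0L
  for (r in seq_len(nrow(records))) {
    hit <- which(scheme$chrom == records$chrom[r] &
                   scheme$start <= records$position[r] &
                   records$position[r] < scheme$end)
    if (length(hit) == 1) counts[hit] <- counts[hit] + 1L
    else outside <- outside + 1L
  }
  list(count = counts, outside = outside)
}

# The 5,000-bin complex-karyotype benchmark is expensive enough to share
# across tests.
benchmark_truth <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- standard_complex_truth()
    val
  }
})
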