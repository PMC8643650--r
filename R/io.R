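#' Write a run summary as an ONT-dialect sequencing-summary TSV
#'
#' Column names follow the basecaller's sequencing-summary convention:
#' `read_id`, `channel`, `mux`, `start_time`, `duration`,
#' `sequence_length_template`, `mean_qscore_template`, `passes_filtering`
#' (plus `barcode_arrangement` when present).
#'
#' @param summary A `run_summary` data frame.
#' @param file Output path.
#' @export
write_sequencing_summary <- function(summary, file) {
  out <- data.frame(read_id = summary$read_id, channel = summary$channel,
                    mux = summary$pore, start_time = summary$start_time,
                    duration = summary$duration,
                    sequence_length_template = summary$length,
                    mean_qscore_template = summary$mean_q,
                    passes_filtering = summary$pass)
  if (!is.null(summary$barcode)) out$barcode_arrangement <- summary$barcode
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an ONT-dialect sequencing-summary TSV
#'
#' Header matching is case-insensitive and tolerates extra columns; several
#' common column name variants are recognised.
#'
#' @param file Path to a sequencing-summary TSV.
#' @return A `run_summary` data frame (see [simulate_run()]).
#' @export
read_sequencing_summary <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  names(d) <- tolower(names(d))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(d)) return(d[[nm]])
    NULL
  }
  out <- data.frame(
    read_id = pick("read_id", "read id") %||% sprintf("read-%07d", seq_len(nrow(d))),
    channel = as.integer(pick("channel")),
    pore = as.integer(pick("mux", "pore") %||% rep(1L, nrow(d))),
    start_time = as.numeric(pick("start_time")),
    duration = as.numeric(pick("duration")),
    length = as.numeric(pick("sequence_length_template", "length")),
    mean_q = as.numeric(pick("mean_qscore_template", "mean_q") %||%
                          rep(NA_real_, nrow(d))),
    stringsAsFactors = FALSE)
  pass <- pick("passes_filtering", "pass")
  out$pass <- if (is.null(pass)) rep(NA, nrow(d)) else as.logical(pass)
  bc <- pick("barcode_arrangement", "barcode")
  if (!is.null(bc)) out$barcode <- bc
  if (anyNA(out$channel) || anyNA(out$start_time) || anyNA(out$duration))
    stop("sequencing summary lacks channel/start_time/duration columns")
  class(out) <- c("run_summary", "data.frame")
  out
}

#' Write a bin scheme or profile as BED-like TSV
#'
#' @param x A `bin_scheme` or [bin_profile()] (profiles need a scheme).
#' @param file Output path.
#' @export
write_bin_tsv <- function(x, file) {
  if (inherits(x, "bin_profile")) {
    if (is.null(x$scheme)) stop("profile has no bin scheme to write")
    d <- x$scheme[c("chrom", "start", "end")]
    d$gc <- x$gc %||% x$scheme$gc
    d$count <- x$count
    if (!is.null(x$ratio)) d$ratio <- x$ratio
  } else {
    d <- as.data.frame(x)
  }
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a BED-like bin TSV
#'
#' @param file Path with header columns `chrom`, `start`, `end` and any of
#'   `gc`, `weight`, `count`, `ratio`.
#' @return A [bin_profile()] when a `count` column is present, else a
#'   `bin_scheme` data frame.
#' @export
read_bin_tsv <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if ("count" %in% names(d)) {
    scheme <- d[intersect(c("chrom", "start", "end", "gc", "weight"), names(d))]
    class(scheme) <- c("bin_scheme", "data.frame")
    bin_profile(d$count, scheme = scheme, gc = d$gc %||% NULL,
                ratio = d$ratio %||% NULL)
  } else {
    class(d) <- c("bin_scheme", "data.frame")
    d
  }
}

#' Write segments (or a fitted copy-number profile) as a seg-style TSV
#'
#' Emits `chrom`, `start_bp`, `end_bp`, `n_bins`, `mean_ratio` (and `cn` for
#' fitted profiles), the layout common seg-file consumers expect.  The
#' fitted multiplier is recorded as a `#multiplier=` header line.
#'
#' @param x A `segment_set` or `cn_profile`.
#' @param file Output path.
#' @param scheme Bin scheme used to map bin indices to bp; optional when the
#'   segments already carry bp columns.
#' @export
write_seg <- function(x, file, scheme = NULL) {
  header <- NULL
  if (inherits(x, "cn_profile")) {
    header <- sprintf("#multiplier=%.4f fit_error=%.6g", x$multiplier,
                      x$fit_error)
    x <- x$segments
  }
  d <- as.data.frame(x)
  if (!("start_bp" %in% names(d)) && !is.null(scheme)) {
    d$start_bp <- scheme$start[d$start_bin + 1]
    d$end_bp <- scheme$end[d$end_bin]
    if (is.null(d$chrom)) d$chrom <- scheme$chrom[d$start_bin + 1]
  }
  keep <- intersect(c("chrom", "start_bp", "end_bp", "start_bin", "end_bin",
                      "n_bins", "mean_ratio", "cn"), names(d))
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  write.table(d[keep], con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a simulated truth (events, purity, seed provenance) as JSON
#'
#' @param truth A `sim_truth`.
#' @param file Output path.
#' @export
write_truth_json <- function(truth, file) {
  jsonlite::write_json(list(n_bins = truth$n_bins,
                            baseline_cn = truth$baseline_cn,
                            purity = truth$purity,
                            events = truth$events),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read barcodes from FASTA or two-column TSV
#'
#' @param file FASTA (via Biostrings, when installed) or headerless
#'   two-column `name<TAB>sequence` TSV.
#' @return A [barcode_set()].
#' @export
read_barcodes <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("fa", "fasta", "fna")) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("reading FASTA barcodes requires the Biostrings package")
    s <- Biostrings::readDNAStringSet(file)
    barcode_set(names(s), as.character(s))
  } else {
    d <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
    barcode_set(d[[1]], d[[2]])
  }
}
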