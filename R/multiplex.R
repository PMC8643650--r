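#' Construct a barcode set
#'
#' @param names Unique sample/barcode identifiers.
#' @param sequences Uppercase DNA barcode sequences, all the same length.
#' @return Named character vector of class `barcode_set`.
#' @export
barcode_set <- function(names, sequences) {
  sequences <- toupper(as.character(sequences))
  if (length(names) != length(sequences)) stop("names/sequences length mismatch")
  if (anyDuplicated(names)) stop("barcode names must be unique")
  if (length(unique(nchar(sequences))) > 1)
    stop("all barcode sequences must have the same length")
  if (any(grepl("[^ACGT]", sequences)))
    stop("barcode sequences must contain only A, C, G, T")
  structure(stats::setNames(sequences, names), class = "barcode_set")
}

#' The five native barcodes used for multiplexed short-molecule runs
#'
#' The standard 24-nt ONT native barcode sequences BC01-BC05, designed for
#' unique sample indexing with large pairwise Hamming separation (at least 10
#' mismatches between any two).
#'
#' @return A [barcode_set()] of five 24-nt sequences.
#' @export
#' @examples
#' min_pairwise_distance(ont_native_barcodes())
ont_native_barcodes <- function() {
  barcode_set(c("BC01", "BC02", "BC03", "BC04", "BC05"),
              c("AAGAAAGTTGTCGGTGTCTTTGTG",
                "TCGATTCCGTTTGTAGTCGTCTGT",
                "GAGTCTTGTGTCCCAGTTACCAGG",
                "TTCGGATTCTATCGTGTTTCCCTA",
                "CTTGTCCAGGGTTTGTGTAACCTT"))
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Character strings of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' Enumerates all unordered pairs.
#'
#' @param barcodes A [barcode_set()] (or character vector) of >= 2 equal-length
#'   sequences.
#' @return Integer minimum over all pairs.
#' @export
min_pairwise_distance <- function(barcodes) {
  seqs <- as.character(barcodes)
  if (length(seqs) < 2) stop("need at least two barcodes")
  pairs <- combn(length(seqs), 2)
  min(apply(pairs, 2, function(p) hamming_distance(seqs[p[1]], seqs[p[2]])))
}

#' Simulate barcoded reads with substitution errors
#'
#' Emits `n_per_sample` reads per barcode: the barcode sequence with
#' independent per-base substitutions at rate `sub_error_rate`, together with
#' the true sample label.  Indels are not modelled.
#'
#' @param barcodes A [barcode_set()].
#' @param n_per_sample Reads per barcode.
#' @param sub_error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Optional seed.
#' @return Data frame with columns `read_id`, `true_barcode`, `sequence`.
#' @export
simulate_barcoded_reads <- function(barcodes, n_per_sample,
                                    sub_error_rate = 0.02, seed = NULL) {
  if (length(barcodes) == 0) stop("empty barcode set")
  stopifnot(sub_error_rate >= 0, sub_error_rate < 1, n_per_sample >= 0)
  seqs <- as.character(barcodes)
  labs <- names(barcodes) %||% as.character(seq_along(seqs))
  L <- nchar(seqs[1])
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    per <- lapply(seq_along(seqs), function(b) {
      chars <- matrix(rep(strsplit(seqs[b], "")[[1]], n_per_sample),
                      nrow = n_per_sample, ncol = L, byrow = TRUE)
      hit <- matrix(runif(n_per_sample * L) < sub_error_rate,
                    nrow = n_per_sample)
      if (any(hit)) {
        # substitute with one of the three other bases, uniformly
        cur <- chars[hit]
        sub <- vapply(cur, function(x) sample(setdiff(bases, x), 1), "")
        chars[hit] <- sub
      }
      data.frame(true_barcode = labs[b],
                 sequence = apply(chars, 1, paste0, collapse = ""),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per)
    data.frame(read_id = sprintf("bc-read-%06d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  })
}

#' Demultiplex reads by nearest barcode
#'
#' Compares the leading bases of each read (at a fixed offset) against every
#' barcode and assigns the read to the unique barcode within `max_dist`
#' mismatches; ties at the minimum distance, or no barcode within `max_dist`,
#' leave the read unclassified.  With the native barcode set (pairwise
#' distance >= 10) the default `max_dist = 4 = floor((10 - 1) / 2)` makes
#' mis-assignment by substitution errors alone impossible.
#'
#' @param reads Character vector of read sequences, or a data frame with a
#'   `sequence` column (e.g. from [simulate_barcoded_reads()]).
#' @param barcodes A [barcode_set()].
#' @param max_dist Maximum mismatches allowed for an assignment.
#' @param offset 0-based position of the barcode within the read.
#' @return A `demux_result` list: `assignments` (per-read data frame with
#'   `read_id`, `assignment`, `distance`), `counts` and `fractions` per
#'   sample including `"unclassified"`.
#' @export
demultiplex <- function(reads, barcodes, max_dist = 4L, offset = 0L) {
  ids <- NULL
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    reads <- reads$sequence
  }
  seqs <- as.character(barcodes)
  labs <- names(barcodes) %||% as.character(seq_along(seqs))
  L <- nchar(seqs[1])
  if (length(reads) && any(nchar(reads) < offset + L))
    stop("reads shorter than barcode length at the given offset")
  ids <- ids %||% sprintf("read-%06d", seq_along(reads))
  n <- length(reads)
  prefix <- substr(reads, offset + 1, offset + L)
  dist <- matrix(0L, nrow = n, ncol = length(seqs))
  if (n) {
    pm <- matrix(unlist(strsplit(prefix, ""), use.names = FALSE),
                 nrow = n, byrow = TRUE)
    for (b in seq_along(seqs)) {
      bc <- strsplit(seqs[b], "")[[1]]
      dist[, b] <- rowSums(pm != matrix(bc, n, L, byrow = TRUE))
    }
  }
  mind <- if (n) apply(dist, 1, min) else integer(0)
  nmin <- if (n) rowSums(dist == mind) else integer(0)
  assign <- rep("unclassified", n)
  ok <- mind <= max_dist & nmin == 1
  assign[ok] <- labs[apply(dist[ok, , drop = FALSE], 1, which.min)]
  counts <- table(factor(assign, levels = c(labs, "unclassified")))
  res <- list(assignments = data.frame(read_id = ids, assignment = assign,
                                       distance = as.integer(mind),
                                       stringsAsFactors = FALSE),
              counts = counts,
              fractions = if (n) counts / n else counts)
  class(res) <- "demux_result"
  res
}

#' @export
print.demux_result <- function(x, ...) {
  n <- nrow(x$assignments)
  cat(sprintf("demux_result: %d reads, %.1f%% assigned\n", n,
              100 * (1 - x$fractions[["unclassified"]])))
  print(x$counts)
  invisible(x)
}
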