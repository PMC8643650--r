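#' Read alignment records
#'
#' Loads per-read alignment records from SAM/BAM (via Rsamtools, when
#' installed) or from a BED-like tab-delimited dialect with a header row
#' containing at least `read_id`, `chrom`, `position`, `mapq`, and the flag
#' columns `is_unmapped`, `is_secondary`, `is_supplementary` (0/1 or
#' TRUE/FALSE); `read_length` is carried through when present.  Positions are
#' 0-based leftmost mapped bases.
#'
#' @param file Path to a `.sam`, `.bam` or tab-delimited file.
#' @return Data frame of alignment records.
#' @export
read_alignments <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("sam", "bam")) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading SAM/BAM requires the Rsamtools package")
    bam <- if (ext == "sam") Rsamtools::asBam(file, tempfile(), overwrite = TRUE)
           else file
    prm <- Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "mapq", "flag", "qwidth"))
    b <- Rsamtools::scanBam(bam, param = prm)[[1]]
    flag <- b$flag
    data.frame(read_id = b$qname,
               chrom = as.character(b$rname),
               position = ifelse(is.na(b$pos), NA_integer_, b$pos - 1L),
               mapq = ifelse(is.na(b$mapq), 0L, b$mapq),
               is_unmapped = bitwAnd(flag, 0x4L) > 0L,
               is_secondary = bitwAnd(flag, 0x100L) > 0L,
               is_supplementary = bitwAnd(flag, 0x800L) > 0L,
               read_length = b$qwidth,
               stringsAsFactors = FALSE)
  } else {
    d <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
    names(d) <- tolower(names(d))
    need <- c("chrom", "position", "mapq")
    if (!all(need %in% names(d)))
      stop("alignment TSV needs columns: ", paste(need, collapse = ", "))
    for (fl in c("is_unmapped", "is_secondary", "is_supplementary"))
      d[[fl]] <- if (fl %in% names(d)) as.logical(d[[fl]]) else FALSE
    d
  }
}

#' Filter alignments for unique, confidently mapped reads
#'
#' Retains records with `mapq >= min_mapq` (boundary inclusive, matching
#' `samtools view -q`) and none of the unmapped / secondary / supplementary
#' flags set (the 0x904 flag mask).
#'
#' @param records Alignment records data frame.
#' @param min_mapq Minimum mapping quality (default 20).
#' @return The surviving records.
#' @export
filter_alignments <- function(records, min_mapq = 20L) {
  keep <- !records$is_unmapped & !records$is_secondary &
    !records$is_supplementary & records$mapq >= min_mapq
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}
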