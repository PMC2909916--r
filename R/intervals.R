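# Shared genomic-interval data model.
#
# All coordinates inside the package are 0-based half-open [start, end) on
# named chromosomes, the BED convention; GFF3 input is converted on read.

#' Construct a genomic interval table
#'
#' The package-wide interval container: a data frame with columns `chrom`,
#' `start`, `end`, `strand` (and optionally `name`), holding 0-based
#' half-open coordinates. Invariants (`0 <= start < end`, non-empty `chrom`,
#' strand one of `+`, `-`, `*`) are enforced on construction.
#'
#' @param chrom chromosome names
#' @param start 0-based inclusive start positions
#' @param end exclusive end positions
#' @param strand `"+"`, `"-"` or `"*"` (unstranded); recycled
#' @param name optional feature names
#' @return a `genomic_intervals` data frame
#' @export
genomic_intervals <- function(chrom = character(), start = numeric(),
                              end = numeric(), strand = "*", name = NULL) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = if (n) rep_len(as.character(strand), n) else character(),
    stringsAsFactors = FALSE
  )
  if (!is.null(name)) df$name <- if (n) rep_len(as.character(name), n) else character()
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  if (!nrow(df)) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end)) stop("interval coordinates must not be NA")
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom)) stop("chromosome names must be non-empty")
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval start must be < end (0-based half-open)")
  if (any(!df$strand %in% c("+", "-", "*"))) stop("strand must be one of '+', '-', '*'")
  invisible(df)
}

#' Convert an interval table to a GRanges object
#'
#' Converts package-internal 0-based half-open coordinates to the 1-based
#' closed convention GRanges uses.
#' @param gi a `genomic_intervals` data frame
#' @return a [GenomicRanges::GRanges] object
#' @export
gi_to_granges <- function(gi) {
  if (!nrow(gi)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = gi$chrom,
    ranges = IRanges::IRanges(start = gi$start + 1, end = gi$end),
    strand = gi$strand
  )
}

#' Convert a GRanges object to the internal interval table
#' @param gr a [GenomicRanges::GRanges] object
#' @return a `genomic_intervals` data frame (0-based half-open)
#' @export
granges_to_gi <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = s
  )
}

gi_width <- function(gi) gi$end - gi$start
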