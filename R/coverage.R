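# Binned read-coverage tracks.
#
# A coverage_track stores, per chromosome, non-negative integer read counts
# in fixed-width bins. bedGraph values are interpreted as mean per-bp read
# depth over the stated span; binning integrates depth x bp and rounds to
# the nearest integer count, which makes the Poisson count model downstream
# well-defined.

#' Construct a coverage track
#' @param counts named list of non-negative integer count vectors, one per
#'   chromosome
#' @param bin_width bin width in bp (shared by all chromosomes)
#' @return a `coverage_track` object
#' @export
coverage_track <- function(counts, bin_width) {
  stopifnot(is.list(counts), bin_width > 0)
  if (length(counts) && is.null(names(counts))) stop("counts must be named by chromosome")
  counts <- lapply(counts, function(x) {
    if (any(x < 0)) stop("coverage counts must be non-negative")
    as.integer(round(x))
  })
  structure(list(bin_width = bin_width, counts = counts), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosome(s), bin width %d bp, %d bins total\n",
              length(x$counts), as.integer(x$bin_width),
              sum(lengths(x$counts))))
  invisible(x)
}

#' Read a bedGraph (or fixed-step wiggle) file into a binned coverage track
#'
#' Values are treated as mean per-bp read depth over the stated span;
#' each bin receives the integral of depth over the bases it covers,
#' rounded to the nearest integer. Uncovered bins are 0. Overlapping
#' bedGraph spans or negative values are errors.
#'
#' @param path bedGraph path
#' @param bin_width bin width in bp (default 50)
#' @return a [coverage_track()]
#' @export
read_coverage <- function(path, bin_width = 50) {
  dat <- .filter_data_lines(readLines(path))
  lines <- dat$lines
  if (length(lines) && any(grepl("^fixedStep", lines))) {
    return(.read_wiggle(lines, dat$lineno, bin_width, path))
  }
  if (!length(lines)) return(coverage_track(structure(list(), names = character()), bin_width))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4)) {
    stop(sprintf("malformed bedGraph line %d in '%s': fewer than 4 fields",
                 dat$lineno[which(nf < 4)[1]], path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(s) | is.na(e) | is.na(v) | e <= s)
  if (length(bad)) {
    stop(sprintf("malformed bedGraph line %d in '%s'", dat$lineno[bad[1]], path))
  }
  if (any(v < 0)) {
    stop(sprintf("negative coverage value on line %d of '%s'",
                 dat$lineno[which(v < 0)[1]], path))
  }
  counts <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    o <- i[order(s[i])]
    if (any(s[o][-1] < e[o][-length(o)])) {
      stop(sprintf("overlapping bedGraph intervals on chromosome '%s' in '%s'", ch, path))
    }
    counts[[ch]] <- .bin_depth(s[o], e[o], v[o], bin_width)
  }
  coverage_track(counts, bin_width)
}

.read_wiggle <- function(lines, lineno, bin_width, path) {
  hdr <- which(grepl("^fixedStep", lines))
  counts <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    h <- lines[hdr[i]]
    ch <- sub(".*chrom=(\\S+).*", "\\1", h)
    start1 <- as.numeric(sub(".*start=(\\d+).*", "\\1", h))
    step <- as.numeric(sub(".*step=(\\d+).*", "\\1", h))
    span <- if (grepl("span=", h)) as.numeric(sub(".*span=(\\d+).*", "\\1", h)) else step
    vals <- as.numeric(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)])
    if (any(vals < 0)) stop(sprintf("negative coverage value in wiggle block at line %d of '%s'",
                                    lineno[hdr[i]], path))
    s <- start1 - 1 + (seq_along(vals) - 1) * step
    new <- .bin_depth(s, s + span, vals, bin_width)
    old <- counts[[ch]]
    if (!is.null(old)) {
      n <- max(length(old), length(new))
      new <- c(new, numeric(n - length(new))) + c(old, numeric(n - length(old)))
    }
    counts[[ch]] <- new
  }
  coverage_track(counts, bin_width)
}

# integrate per-bp depth over spans [s, e) into bins of width bw
.bin_depth <- function(s, e, v, bw) {
  nb <- as.integer(ceiling(max(e) / bw))
  acc <- numeric(nb)
  aligned <- (s %% bw == 0) & (e - s == bw)
  if (any(aligned)) {
    idx <- s[aligned] / bw + 1
    acc[idx] <- acc[idx] + v[aligned] * bw
  }
  for (i in which(!aligned)) {
    b0 <- floor(s[i] / bw)
    b1 <- floor((e[i] - 1) / bw)
    for (b in b0:b1) {
      ov <- min(e[i], (b + 1) * bw) - max(s[i], b * bw)
      acc[b + 1] <- acc[b + 1] + v[i] * ov
    }
  }
  round(acc)
}

#' Write a coverage track as bedGraph
#'
#' Emits one span per non-zero bin with value `count / bin_width` (mean
#' per-bp depth), the exact inverse of the [read_coverage()] binning rule.
#' @param track a [coverage_track()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  bw <- track$bin_width
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  for (ch in names(track$counts)) {
    x <- track$counts[[ch]]
    nz <- which(x != 0)
    if (!length(nz)) next
    writeLines(paste(ch, fmt((nz - 1) * bw), fmt(nz * bw), fmt(x[nz] / bw),
                     sep = "\t"), con)
  }
  invisible(path)
}

# counts for bins fully covering [start, end) on one chromosome; bins
# outside the stored vector count 0
track_window <- function(track, chrom, start, end) {
  x <- track$counts[[chrom]]
  if (is.null(x)) stop(sprintf("chromosome '%s' absent from coverage track", chrom))
  bw <- track$bin_width
  b0 <- floor(start / bw)
  b1 <- ceiling(end / bw) - 1
  idx <- (b0:b1) + 1
  out <- integer(length(idx))
  ok <- idx >= 1 & idx <= length(x)
  out[ok] <- x[idx[ok]]
  out
}
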