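# Readers and writers for the standard formats the pipeline touches:
# BED3/BED6, GFF3, bedGraph, FASTA, TRANSFAC/JASPAR-style matrix files and
# tab-separated result tables. FASTA goes through Biostrings; the flat
# tabular formats use dedicated line-level readers so parse errors can name
# the offending line and the bedGraph binning semantics stay explicit.

.filter_data_lines <- function(lines) {
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a BED3/BED6 file
#'
#' Coordinates are kept in their native 0-based half-open convention.
#' Strand is taken from column 6 when present; malformed lines raise an
#' error naming the line number.
#'
#' @param path path to a BED file
#' @return a [genomic_intervals()] table (with `name` column when present)
#' @export
read_bed <- function(path) {
  dat <- .filter_data_lines(readLines(path))
  if (!length(dat$lines)) return(genomic_intervals())
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    stop(sprintf("malformed BED line %d in '%s': fewer than 3 fields",
                 dat$lineno[i], path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d in '%s': non-numeric coordinates",
                 dat$lineno[bad[1]], path))
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d in '%s': requires 0 <= start < end",
                 dat$lineno[bad[1]], path))
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6L, length(f))], "*"), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gi <- genomic_intervals(chrom, start, end, strand)
  if (any(nf >= 4)) gi$name <- name
  gi
}

#' Write intervals as BED
#'
#' Writes BED3 when no name/score/strand information is present, BED6
#' otherwise. Scores are clamped to the BED 0-1000 range.
#' @param gi a [genomic_intervals()] table
#' @param path output path
#' @param score optional numeric score vector (column 5)
#' @return `path`, invisibly
#' @export
write_bed <- function(gi, path, score = NULL) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (!nrow(gi)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  bed6 <- !is.null(score) || !is.null(gi$name) || any(gi$strand != "*")
  if (bed6) {
    nm <- gi$name %||% paste0("region_", seq_len(nrow(gi)))
    sc <- if (is.null(score)) rep(0, nrow(gi)) else pmin(1000, pmax(0, round(score)))
    strand <- ifelse(gi$strand == "*", ".", gi$strand)
    lines <- paste(gi$chrom, fmt(gi$start), fmt(gi$end), nm, fmt(sc), strand,
                   sep = "\t")
  } else {
    lines <- paste(gi$chrom, fmt(gi$start), fmt(gi$end), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene and miRNA annotations from GFF3
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention. Features whose type mentions `miRNA` are
#' classified as `mirna`, everything else as `coding`. The TSS is the
#' strand-aware 5' position (`start` on `+`, `end - 1` on `-`). Every
#' feature must carry an `ID` attribute.
#'
#' @param path path to a GFF3 file
#' @return a data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `kind`, `type`
#' @export
read_gff3 <- function(path) {
  dat <- .filter_data_lines(readLines(path))
  if (!length(dat$lines)) {
    return(data.frame(id = character(), chrom = character(), start = numeric(),
                      end = numeric(), strand = character(), tss = numeric(),
                      kind = character(), type = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(dat$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    i <- which(nf != 9)[1]
    stop(sprintf("malformed GFF3 line %d in '%s': expected 9 fields, got %d",
                 dat$lineno[i], path, nf[i]))
  }
  m <- do.call(rbind, fields)
  attrs <- m[, 9]
  has_id <- grepl("(^|;)\\s*ID=", attrs)
  if (any(!has_id)) {
    stop(sprintf("GFF3 line %d in '%s': missing ID attribute",
                 dat$lineno[which(!has_id)[1]], path))
  }
  id <- sub(".*(^|;)\\s*ID=([^;]+).*", "\\2", attrs)
  start1 <- as.numeric(m[, 4])
  end1 <- as.numeric(m[, 5])
  strand <- m[, 7]
  strand[!strand %in% c("+", "-")] <- "*"
  start0 <- start1 - 1
  end0 <- end1
  tss <- ifelse(strand == "-", end0 - 1, start0)
  data.frame(
    id = id, chrom = m[, 1], start = start0, end = end0, strand = strand,
    tss = tss,
    kind = ifelse(grepl("miRNA", m[, 3], ignore.case = TRUE), "mirna", "coding"),
    type = m[, 3], stringsAsFactors = FALSE
  )
}

#' Write annotations as GFF3
#' @param annots data frame as returned by [read_gff3()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(annots, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("##gff-version 3", con)
  if (nrow(annots)) {
    type <- annots$type %||% ifelse(annots$kind == "mirna", "pre_miRNA", "gene")
    lines <- paste(annots$chrom, "mipronet", type,
                   fmt(annots$start + 1), fmt(annots$end), ".",
                   ifelse(annots$strand == "*", ".", annots$strand), ".",
                   paste0("ID=", annots$id), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a library of position-specific score matrices
#'
#' Accepts TRANSFAC-style flat files (records with `ID`/`AC`, optional
#' `DE`/`NA` factor names, a `P0`/`PO` header and numbered count rows,
#' terminated by `//`) and JASPAR-style records (`>id name` followed by four
#' `A/C/G/T [ ... ]` rows). Returns a list of [pssm()] objects.
#'
#' @param path path to the matrix file
#' @return list of `pssm` objects (empty, with a warning, for empty input)
#' @export
read_pssm_library <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning(sprintf("empty PSSM file '%s': returning empty library", path))
    return(list())
  }
  if (any(startsWith(lines, ">"))) {
    return(.read_pssm_jaspar(lines, path))
  }
  .read_pssm_transfac(lines, path)
}

.read_pssm_transfac <- function(lines, path) {
  rec_id <- cumsum(startsWith(lines, "//"))
  out <- list()
  for (r in split(lines, rec_id)) {
    r <- r[!startsWith(r, "//") & !startsWith(r, "XX")]
    if (!length(r)) next
    tag <- toupper(substr(r, 1, 2))
    val <- trimws(substr(r, 3, nchar(r)))
    id <- val[tag %in% c("ID", "AC")][1]
    tf <- val[tag %in% c("NA", "DE")][1]
    rows <- r[grepl("^[0-9]+\\s", r)]
    if (!length(rows)) {
      if (is.na(id)) next
      stop(sprintf("PSSM record '%s' in '%s' has no count rows", id, path))
    }
    toks <- strsplit(rows, "\\s+")
    nt <- lengths(toks)
    if (any(nt < 5)) {
      stop(sprintf("PSSM record '%s' in '%s': count row of wrong arity (need position + 4 counts)",
                   if (is.na(id)) "?" else id, path))
    }
    counts <- t(vapply(toks, function(x) as.numeric(x[2:5]), numeric(4)))
    if (anyNA(counts)) {
      stop(sprintf("PSSM record '%s' in '%s': non-numeric count", id, path))
    }
    mat <- t(counts)
    rownames(mat) <- c("A", "C", "G", "T")
    out[[length(out) + 1L]] <- pssm(
      id = if (is.na(id)) paste0("M", length(out) + 1L) else id,
      tf_name = if (is.na(tf)) NA_character_ else tf,
      counts = mat
    )
  }
  if (!length(out)) warning(sprintf("no PSSM records found in '%s'", path))
  out
}

.read_pssm_jaspar <- function(lines, path) {
  hdr <- which(startsWith(lines, ">"))
  out <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    toks <- strsplit(sub("^>\\s*", "", lines[hdr[i]]), "\\s+")[[1]]
    rows <- lapply(block, function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    base <- toupper(substr(trimws(block), 1, 1))
    if (length(rows) != 4 || !setequal(base, c("A", "C", "G", "T"))) {
      stop(sprintf("malformed JASPAR record '%s' in '%s'", toks[1], path))
    }
    if (length(unique(lengths(rows))) != 1) {
      stop(sprintf("JASPAR record '%s' in '%s': rows of unequal length", toks[1], path))
    }
    mat <- do.call(rbind, rows[order(match(base, c("A", "C", "G", "T")))])
    rownames(mat) <- c("A", "C", "G", "T")
    out[[i]] <- pssm(id = toks[1], tf_name = if (length(toks) > 1) toks[2] else NA_character_,
                     counts = mat)
  }
  out
}

#' Write a PSSM library as a TRANSFAC-style flat file
#' @param pssms list of [pssm()] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pssm_library <- function(pssms, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (p in pssms) {
    writeLines(c(sprintf("ID %s", p$id), sprintf("NA %s", p$tf_name),
                 "P0 A C G T"), con)
    for (j in seq_len(ncol(p$counts))) {
      writeLines(sprintf("%02d %s", j,
                         paste(format(p$counts[, j], trim = TRUE), collapse = " ")), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences as FASTA
#' @param seqs named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
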