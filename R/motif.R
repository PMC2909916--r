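# PSSM scanning and collaborating-factor enrichment.
#
# Binding potential of a factor at an L-bp window is the log-odds sum of
# its position-specific score matrix (pseudocount-regularised, against
# background base frequencies), min-max normalised to [0, 1] so cutoffs are
# comparable across matrices. A matrix is "enriched" in a set of
# ChIP-selected regions when, at some cutoff, the per-kb density of
# super-cutoff windows in the ChIP set is at least five times the density
# in background promoter sequence -- equivalently when the density-ratio
# FDR (background density / ChIP density) drops to <= 20%.

#' Construct a position-specific score matrix
#'
#' @param id matrix identifier
#' @param tf_name transcription-factor name
#' @param counts 4 x L numeric count matrix with rows A, C, G, T; L >= 4
#' @return a `pssm` object (weights are attached by [pssm_prepare()])
#' @export
pssm <- function(id, tf_name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PSSM counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4) stop("PSSM length must be >= 4")
  if (anyNA(counts) || any(counts < 0)) stop("PSSM counts must be non-negative")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(id = as.character(id), tf_name = as.character(tf_name),
                 counts = counts),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM %s (%s), length %d, consensus %s\n", x$id, x$tf_name,
              ncol(x$counts), pssm_consensus(x)))
  invisible(x)
}

#' Attach log-odds weights to a PSSM
#'
#' Adds `pseudocount` to every cell, converts column counts to
#' probabilities, and stores the log2-odds weight matrix against the given
#' background base frequencies along with the per-matrix minimum and
#' maximum attainable scores used for min-max normalisation.
#'
#' @param p a [pssm()] object
#' @param background length-4 background base frequencies (A, C, G, T)
#' @param pseudocount pseudocount added per cell (default 0.8)
#' @return the `pssm` with `w`, `score_min`, `score_max` fields
#' @export
pssm_prepare <- function(p, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(inherits(p, "pssm"), length(background) == 4)
  background <- background / sum(background)
  prob <- sweep(p$counts + pseudocount, 2,
                colSums(p$counts) + 4 * pseudocount, "/")
  w <- log2(prob / background)
  p$w <- w
  p$background <- background
  p$pseudocount <- pseudocount
  p$score_min <- sum(apply(w, 2, min))
  p$score_max <- sum(apply(w, 2, max))
  if (!all(is.finite(w)) || p$score_min >= p$score_max) {
    stop("degenerate PSSM: non-finite weights or score_min >= score_max")
  }
  p
}

pssm_consensus <- function(p) {
  paste(rownames(p$counts)[apply(p$counts, 2, which.max)], collapse = "")
}

.ensure_prepared <- function(p) if (is.null(p$w)) pssm_prepare(p) else p

.DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_dna <- function(seq) {
  unname(.DNA_CODE[strsplit(toupper(seq), "", fixed = TRUE)[[1]]])
}

# normalised scores of every L-window on the + orientation of `seq`;
# windows containing non-ACGT characters score -Inf
.window_scores <- function(p, seq) {
  code <- encode_dna(seq)
  L <- ncol(p$w)
  n <- length(code)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  S <- numeric(nw)
  for (j in seq_len(L)) {
    S <- S + p$w[, j][code[j:(j + nw - 1L)]]
  }
  S[is.na(S)] <- -Inf
  unname((S - p$score_min) / (p$score_max - p$score_min))
}

#' Normalised PSSM match score of a single window
#'
#' `score = (S - score_min) / (score_max - score_min)` where `S` is the
#' log-odds sum; the per-column consensus scores 1 and the per-column
#' anti-consensus scores 0. Windows containing `N` score `-Inf`.
#'
#' @param p a [pssm()] (prepared with [pssm_prepare()] or raw)
#' @param window DNA string of exactly the matrix length
#' @return normalised score in `[0, 1]` (or `-Inf`)
#' @export
match_score <- function(p, window) {
  p <- .ensure_prepared(p)
  if (nchar(window) != ncol(p$w)) {
    stop(sprintf("window length %d does not match PSSM length %d",
                 nchar(window), ncol(p$w)))
  }
  .window_scores(p, window)
}

# both-strand window scores for a region sequence; minus-strand windows are
# reported at their forward-strand start (1-based)
.region_scores <- function(p, seq) {
  n <- nchar(seq)
  L <- ncol(p$w)
  plus <- .window_scores(p, seq)
  minus <- .window_scores(p, revcomp(seq))
  nw <- n - L + 1L
  data.frame(
    start = c(seq_len(max(nw, 0L)), if (nw > 0) nw + 1L - seq_len(nw) else integer()),
    strand = rep(c("+", "-"), times = c(length(plus), length(minus))),
    score = c(plus, minus),
    stringsAsFactors = FALSE
  )
}

#' Best PSSM match in a region (both strands)
#'
#' @param p a [pssm()]
#' @param seq region DNA sequence (length >= matrix length)
#' @return list with `score`, `start` (1-based forward-strand window start),
#'   `strand`; ties are broken leftmost, then `+` strand
#' @export
best_match_in_region <- function(p, seq) {
  p <- .ensure_prepared(p)
  if (nchar(seq) < ncol(p$w)) stop("region shorter than PSSM")
  sc <- .region_scores(p, seq)
  o <- order(-sc$score, sc$start, sc$strand)
  b <- sc[o[1], ]
  list(score = b$score, start = b$start, strand = b$strand)
}

#' Extract background promoter sequences
#'
#' The strand-aware 1,000-bp (by default) upstream sequence of every gene
#' whose upstream window does not overlap any ChIP-enriched region. Windows
#' truncated at a chromosome boundary are kept with a warning.
#'
#' @param genes annotation data frame with `id`, `chrom`, `tss`, `strand`
#' @param chip_regions [genomic_intervals()] of ChIP-enriched regions
#' @param genome named character vector of chromosome sequences
#' @param upstream window size in bp (default 1000)
#' @return named character vector of background promoter sequences
#' @export
build_background_promoters <- function(genes, chip_regions, genome,
                                       upstream = 1000) {
  out <- character(0)
  truncated <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    chrlen <- nchar(genome[[g$chrom]])
    if (is.null(chrlen)) next
    if (g$strand == "-") {
      s <- g$tss + 1
      e <- g$tss + 1 + upstream
    } else {
      s <- g$tss - upstream
      e <- g$tss
    }
    s0 <- max(0, s); e0 <- min(chrlen, e)
    if (e0 <= s0) next
    if (s0 != s || e0 != e) truncated <- truncated + 1L
    ov <- chip_regions$chrom == g$chrom &
      chip_regions$start < e0 & chip_regions$end > s0
    if (any(ov)) next
    sq <- substr(genome[[g$chrom]], s0 + 1, e0)
    if (g$strand == "-") sq <- revcomp(sq)
    out[[as.character(g$id)]] <- sq
  }
  if (truncated > 0) {
    warning(sprintf("%d promoter window(s) truncated at a chromosome boundary",
                    truncated))
  }
  out
}

#' Base frequencies of a sequence set
#' @param seqs character vector of DNA sequences
#' @return length-4 frequency vector (A, C, G, T)
#' @export
base_frequencies <- function(seqs) {
  tab <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(toupper(seqs)))
  f <- colSums(tab)[c("A", "C", "G", "T")]
  if (sum(f) == 0) return(rep(0.25, 4))
  unname(f / sum(f))
}

#' Binding-site density and density-ratio FDR across a cutoff grid
#'
#' Scans both strands of the ChIP and background sequence sets; at each
#' cutoff `c`, `density(c)` is the number of windows scoring `>= c` per kb
#' of scanned sequence (sum of `length - L + 1` over sequences), computed
#' separately per set, and `fdr(c) = bg_density(c) / chip_density(c)` (1 by
#' convention when both densities are 0).
#'
#' @param p a [pssm()]
#' @param chip_seqs character vector of ChIP-region sequences
#' @param bg_seqs character vector of background promoter sequences
#' @param cutoffs ascending cutoff grid (default `seq(0.60, 1.00, 0.01)`)
#' @return an `enrichment_curve` data frame with columns `cutoff`,
#'   `chip_hits`, `bg_hits`, `chip_density`, `bg_density`, `fdr`
#' @export
density_fdr_curve <- function(p, chip_seqs, bg_seqs,
                              cutoffs = seq(0.60, 1.00, by = 0.01)) {
  p <- .ensure_prepared(p)
  if (!length(chip_seqs) || !length(bg_seqs)) {
    stop("both the ChIP and background sequence sets must be non-empty")
  }
  L <- ncol(p$w)
  tally <- function(seqs) {
    scores <- sort(unlist(lapply(seqs, function(s) {
      c(.window_scores(p, s), .window_scores(p, revcomp(s)))
    }), use.names = FALSE))
    kb <- sum(pmax(nchar(seqs) - L + 1, 0)) / 1000
    hits <- length(scores) - findInterval(cutoffs - 1e-9, scores)
    list(hits = hits, kb = kb)
  }
  chip <- tally(chip_seqs)
  bg <- tally(bg_seqs)
  chip_density <- chip$hits / chip$kb
  bg_density <- bg$hits / bg$kb
  fdr <- ifelse(chip$hits == 0 & bg$hits == 0, 1, bg_density / chip_density)
  out <- data.frame(cutoff = cutoffs, chip_hits = chip$hits, bg_hits = bg$hits,
                    chip_density = chip_density, bg_density = bg_density,
                    fdr = fdr)
  attr(out, "pssm_id") <- p$id
  attr(out, "pssm") <- p
  attr(out, "chip_kb") <- chip$kb
  attr(out, "bg_kb") <- bg$kb
  class(out) <- c("enrichment_curve", "data.frame")
  out
}

#' Select the PSSM-specific cutoff from a density-ratio curve
#'
#' The lowest grid cutoff where the density-ratio FDR is at most `fdr_max`
#' and the ChIP set still carries at least `min_chip_hits` hits; `NA` (not
#' enriched) when no cutoff qualifies.
#'
#' @param curve an `enrichment_curve` from [density_fdr_curve()]
#' @param fdr_max maximum density-ratio FDR (default 0.2)
#' @param min_chip_hits minimum ChIP hit count at the cutoff (default 5)
#' @return selected cutoff, or `NA_real_` when not enriched
#' @export
select_cutoff <- function(curve, fdr_max = 0.2, min_chip_hits = 5) {
  ok <- which(curve$fdr <= fdr_max & curve$chip_hits >= min_chip_hits)
  if (!length(ok)) return(NA_real_)
  curve$cutoff[min(ok)]
}

#' Enrichment report for a PSSM library
#'
#' Computes the density-ratio curve and selected cutoff for every matrix,
#' groups enriched matrices by factor name, and flags factor pairs whose
#' consensus strings are near-identical (Hamming distance <= 1 on either
#' orientation), since such enrichment may be a sequence-similarity
#' artifact rather than independent evidence.
#'
#' @param pssms list of [pssm()] objects
#' @param chip_seqs ChIP-region sequences
#' @param bg_seqs background promoter sequences (also used to estimate the
#'   background base frequencies for the log-odds weights)
#' @param cutoffs cutoff grid
#' @param fdr_max,min_chip_hits passed to [select_cutoff()]
#' @return list with `report` (per-PSSM data frame), `curves` (named list
#'   of enrichment curves), `tf_report` (per-factor summary) and
#'   `similar_pairs` (data frame of flagged factor pairs)
#' @export
enriched_factors <- function(pssms, chip_seqs, bg_seqs,
                             cutoffs = seq(0.60, 1.00, by = 0.01),
                             fdr_max = 0.2, min_chip_hits = 5) {
  if (!length(chip_seqs)) stop("empty ChIP sequence set")
  if (!length(pssms)) stop("empty PSSM library")
  bgf <- base_frequencies(bg_seqs)
  prepared <- lapply(pssms, pssm_prepare, background = bgf)
  curves <- list()
  rows <- vector("list", length(prepared))
  for (i in seq_along(prepared)) {
    p <- prepared[[i]]
    cur <- density_fdr_curve(p, chip_seqs, bg_seqs, cutoffs)
    cut <- select_cutoff(cur, fdr_max, min_chip_hits)
    curves[[p$id]] <- cur
    at <- if (is.na(cut)) NA_integer_ else match(cut, cur$cutoff)
    rows[[i]] <- data.frame(
      pssm_id = p$id, tf = p$tf_name, cutoff = cut,
      chip_density = if (is.na(cut)) NA_real_ else cur$chip_density[at],
      bg_density = if (is.na(cut)) NA_real_ else cur$bg_density[at],
      fdr = if (is.na(cut)) min(cur$fdr) else cur$fdr[at],
      enriched = !is.na(cut), stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  enr <- report[report$enriched, , drop = FALSE]
  tf_report <- if (nrow(enr)) {
    agg <- stats::aggregate(pssm_id ~ tf, data = enr, FUN = length)
    names(agg)[2] <- "n_enriched_pssms"
    agg$min_fdr <- vapply(agg$tf, function(t) min(enr$fdr[enr$tf == t]), numeric(1))
    agg
  } else {
    data.frame(tf = character(), n_enriched_pssms = integer(), min_fdr = numeric())
  }
  sim <- .similar_consensus_pairs(prepared[match(enr$pssm_id,
                                                 vapply(prepared, `[[`, "", "id"))])
  list(report = report, curves = curves, tf_report = tf_report,
       similar_pairs = sim)
}

# flag enriched matrices of *different* factors whose consensus strings
# agree at >= L - 1 positions on either orientation
.similar_consensus_pairs <- function(prepared) {
  out <- data.frame(tf_a = character(), tf_b = character(),
                    pssm_a = character(), pssm_b = character(),
                    stringsAsFactors = FALSE)
  if (length(prepared) < 2) return(out)
  cons <- vapply(prepared, pssm_consensus, "")
  for (i in seq_along(prepared)) {
    for (j in seq_along(prepared)) {
      if (j <= i) next
      a <- prepared[[i]]; b <- prepared[[j]]
      if (identical(a$tf_name, b$tf_name)) next
      if (nchar(cons[i]) != nchar(cons[j])) next
      hd <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
      if (hd(cons[i], cons[j]) <= 1 || hd(cons[i], revcomp(cons[j])) <= 1) {
        out <- rbind(out, data.frame(tf_a = a$tf_name, tf_b = b$tf_name,
                                     pssm_a = a$id, pssm_b = b$id,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Call binding instances of a PSSM in regions
#'
#' Reports every window (both strands) scoring at or above the selected
#' cutoff; overlapping windows are all reported.
#'
#' @param p a [pssm()]
#' @param cutoff score cutoff from [select_cutoff()]
#' @param regions [genomic_intervals()] of regions to scan
#' @param genome named character vector of chromosome sequences
#' @return data frame of instances (`pssm_id`, `tf`, `chrom`, `start`,
#'   `end`, `strand`, `score`, `region_idx`) in 0-based half-open
#'   coordinates
#' @export
call_instances <- function(p, cutoff, regions, genome) {
  p <- .ensure_prepared(p)
  L <- ncol(p$w)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    sq <- substr(genome[[r$chrom]], r$start + 1, r$end)
    if (nchar(sq) < L) next
    sc <- .region_scores(p, sq)
    hit <- sc[sc$score >= cutoff, , drop = FALSE]
    if (!nrow(hit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pssm_id = p$id, tf = p$tf_name, chrom = r$chrom,
      start = r$start + hit$start - 1, end = r$start + hit$start - 1 + L,
      strand = hit$strand, score = hit$score, region_idx = i,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(pssm_id = character(), tf = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), score = numeric(),
                      region_idx = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Sample a sequence from a PSSM's column distributions
#' @param p a [pssm()]
#' @param pseudocount pseudocount used for the column probabilities
#' @return a sampled site string of the matrix length
#' @export
sample_pssm_site <- function(p, pseudocount = 0.8) {
  prob <- sweep(p$counts + pseudocount, 2, colSums(p$counts) + 4 * pseudocount, "/")
  paste(vapply(seq_len(ncol(prob)), function(j) {
    sample(rownames(prob), 1, prob = prob[, j])
  }, ""), collapse = "")
}
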