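# Interval-overlap statistics and sequence-feature profiling:
# permutation null models for region overlap, the binomial co-occurrence
# test, CpG-island detection and binding-site density profiles around TSSs.

#' Count query intervals overlapping a reference set
#'
#' Half-open overlap test (>= 1 bp shared); containment counts as overlap.
#' Strand is ignored.
#'
#' @param query,reference [genomic_intervals()] tables
#' @return number of query intervals overlapping at least one reference
#'   interval
#' @export
overlap_count <- function(query, reference) {
  if (!nrow(query) || !nrow(reference)) return(0L)
  q <- gi_to_granges(query)
  r <- gi_to_granges(reference)
  sum(GenomicRanges::countOverlaps(q, r, ignore.strand = TRUE) > 0)
}

#' Permutation test for interval-set overlap
#'
#' Each replicate places `nrow(query)` length-matched intervals uniformly
#' at random in the eligible space and counts how many overlap the
#' reference. `p_hat` is the mean per-region overlap fraction across
#' replicates, and the p-value is the binomial tail
#' `P(X >= n_overlapping)` with `X ~ Binomial(n_query, p_hat)`.
#'
#' @param query,reference [genomic_intervals()] tables
#' @param eligible_space [genomic_intervals()] giving the placement universe
#' @param n_perm number of permutation replicates (default 10000)
#' @param seed optional integer seed (bit-exact reproducibility)
#' @return an `overlap_result` list: `n_query`, `n_overlapping`,
#'   `replicates` (per-replicate overlap counts), `p_hat`, `p_value`
#' @export
permutation_overlap_test <- function(query, reference, eligible_space,
                                     n_perm = 10000, seed = NULL) {
  n_query <- nrow(query)
  if (!n_query) stop("empty query set")
  n_overlapping <- overlap_count(query, reference)
  widths <- gi_width(query)
  seg_w <- gi_width(eligible_space)
  if (max(widths) > max(seg_w)) {
    stop("a query interval is longer than every eligible segment")
  }
  ref_by_chrom <- .merge_by_chrom(reference)

  counts <- with_seed(seed, {
    hit <- matrix(FALSE, nrow = n_query, ncol = n_perm)
    for (i in seq_len(n_query)) {
      len <- widths[i]
      ok <- which(seg_w >= len)
      wts <- seg_w[ok] - len + 1
      segs <- ok[sample.int(length(ok), n_perm, replace = TRUE, prob = wts)]
      starts <- eligible_space$start[segs] +
        floor(stats::runif(n_perm) * (seg_w[segs] - len + 1))
      hit[i, ] <- .points_overlap(eligible_space$chrom[segs], starts,
                                  starts + len, ref_by_chrom)
    }
    colSums(hit)
  })
  p_hat <- mean(counts) / n_query
  p_value <- if (n_overlapping == 0) 1 else {
    if (p_hat <= 0) {
      0
    } else if (p_hat >= 1) {
      1
    } else {
      stats::pbinom(n_overlapping - 1, n_query, p_hat, lower.tail = FALSE)
    }
  }
  structure(list(n_query = n_query, n_overlapping = n_overlapping,
                 replicates = counts, p_hat = p_hat,
                 p_value = max(p_value, .Machine$double.xmin)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d / %d query regions (p_hat = %.4f, P = %.3g, %d permutations)\n",
              x$n_overlapping, x$n_query, x$p_hat, x$p_value,
              length(x$replicates)))
  invisible(x)
}

# reference intervals merged per chromosome, sorted by start
.merge_by_chrom <- function(gi) {
  if (!nrow(gi)) return(list())
  gr <- GenomicRanges::reduce(gi_to_granges(gi), ignore.strand = TRUE)
  m <- granges_to_gi(gr)
  split(m[, c("start", "end")], m$chrom)
}

# vectorised half-open overlap test of intervals [s, e) against merged refs
.points_overlap <- function(chrom, s, e, ref_by_chrom) {
  out <- logical(length(s))
  for (ch in unique(chrom)) {
    refs <- ref_by_chrom[[ch]]
    if (is.null(refs) || !nrow(refs)) next
    i <- which(chrom == ch)
    a <- findInterval(s[i], refs$start)            # refs with start <= s
    b <- findInterval(e[i] - 1e-9, refs$start)     # refs with start <  e
    covered <- a >= 1 & refs$end[pmax(a, 1)] > s[i]
    out[i] <- (a >= 1 & covered) | (b > a)
  }
  out
}

#' Binomial co-occurrence test
#'
#' Upper-tail binomial probability that at least `k` of `n` regions carry
#' the second factor, given a per-region null probability `p_hat`
#' (typically estimated by permutation):
#' `p = sum_{j=k..n} C(n,j) p_hat^j (1-p_hat)^(n-j)`.
#'
#' @param n number of regions carrying factor A
#' @param k number of those also carrying factor B
#' @param p_hat per-region null probability, in (0, 1)
#' @return the p-value
#' @export
binomial_cooccurrence_test <- function(n, k, p_hat) {
  if (!(p_hat > 0 && p_hat < 1)) stop("p_hat must lie strictly in (0, 1)")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p_hat, lower.tail = FALSE)
}

#' Detect CpG islands in a DNA sequence
#'
#' Finds maximal regions with length greater than `min_length` bp, GC
#' content of at least `min_gc`, and observed/expected CpG ratio above
#' `min_obs_exp`, where `obs/exp = (#CpG * L) / (#C * #G)`. Candidate
#' regions are built from passing 200-bp sliding windows, merged, and
#' trimmed until the whole region satisfies all three thresholds.
#'
#' @param seq DNA string
#' @param chrom chromosome name attached to the output intervals
#' @param min_length minimum island length in bp (exclusive; default 200)
#' @param min_gc minimum GC fraction (default 0.5)
#' @param min_obs_exp minimum observed/expected CpG ratio (exclusive;
#'   default 0.6)
#' @return a [genomic_intervals()] table of islands (0-based half-open)
#' @export
cpg_islands <- function(seq, chrom = "seq", min_length = 200, min_gc = 0.5,
                        min_obs_exp = 0.6) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  w <- 200L
  if (n < w) return(genomic_intervals())
  isC <- chars == "C"
  isG <- chars == "G"
  cpg <- c(isC[-n] & isG[-1], FALSE)
  cC <- c(0, cumsum(isC))
  cG <- c(0, cumsum(isG))
  cCpG <- c(0, cumsum(cpg))
  stat <- function(s, e) {                      # 0-based half-open [s, e)
    L <- e - s
    nc <- cC[e + 1] - cC[s + 1]
    ng <- cG[e + 1] - cG[s + 1]
    ncpg <- cCpG[min(e, n)] - cCpG[s + 1]       # CpG starting within [s, e-1)
    gc <- (nc + ng) / L
    oe <- if (nc * ng == 0) 0 else ncpg * L / (nc * ng)
    c(gc = gc, oe = oe)
  }
  starts <- 0:(n - w)
  gc_w <- (cC[starts + w + 1] - cC[starts + 1] + cG[starts + w + 1] - cG[starts + 1]) / w
  ncpg_w <- cCpG[starts + w] - cCpG[starts + 1]
  nc_w <- cC[starts + w + 1] - cC[starts + 1]
  ng_w <- cG[starts + w + 1] - cG[starts + 1]
  oe_w <- ifelse(nc_w * ng_w == 0, 0, ncpg_w * w / (nc_w * ng_w))
  pass <- gc_w >= min_gc & oe_w > min_obs_exp
  if (!any(pass)) return(genomic_intervals())
  r <- rle(pass)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  keep <- which(r$values)
  out <- list()
  for (k in keep) {
    s <- starts[starts_idx[k]]
    e <- starts[ends_idx[k]] + w
    repeat {
      st <- stat(s, e)
      if (st["gc"] >= min_gc && st["oe"] > min_obs_exp) break
      if (e - s - 1 <= min_length) { s <- e; break }     # drop: cannot satisfy
      if (chars[s + 1] %in% c("A", "T")) s <- s + 1
      else if (chars[e] %in% c("A", "T")) e <- e - 1
      else s <- s + 1
    }
    if (e - s > min_length) out[[length(out) + 1L]] <- c(s, e)
  }
  if (!length(out)) return(genomic_intervals())
  m <- do.call(rbind, out)
  genomic_intervals(chrom, m[, 1], m[, 2], "*")
}

#' Binding-site or score profile around transcription start sites
#'
#' In `sites` mode, restricts to genes with at least one site inside
#' `[-window, +window)` of their TSS and reports, per bin, the percentage
#' of those genes carrying a site in the bin (a gene tallies in every bin
#' it has a site in). In `track` mode, reports the mean binned coverage at
#' each offset bin across TSSs. Offsets are strand-oriented.
#'
#' @param tss_table data frame with `chrom`, `tss`, `strand` (and `id`)
#' @param sites [genomic_intervals()] of binding sites (sites mode)
#' @param track a [coverage_track()] (track mode)
#' @param window half-window in bp (default 3000)
#' @param bin bin size in bp (default 1000 for sites, the track bin width
#'   for tracks)
#' @return data frame with `bin_start`, `bin_end` (offsets) and
#'   `percent_genes` or `mean_count`; attribute `n_genes` gives the number
#'   of genes included
#' @export
profile_around_tss <- function(tss_table, sites = NULL, track = NULL,
                               window = 3000, bin = 1000) {
  if (!nrow(tss_table)) stop("empty TSS table")
  edges <- seq(-window, window, by = bin)
  if (!is.null(sites)) {
    mids <- (sites$start + sites$end) / 2
    offs_per_gene <- lapply(seq_len(nrow(tss_table)), function(i) {
      g <- tss_table[i, ]
      on_chrom <- which(sites$chrom == g$chrom)
      off <- mids[on_chrom] - g$tss
      if (g$strand == "-") off <- -off
      off[off >= -window & off < window]
    })
    has_site <- lengths(offs_per_gene) > 0
    if (!any(has_site)) {
      warning("no gene carries a site within the window; empty profile")
      out <- data.frame(bin_start = utils::head(edges, -1),
                        bin_end = edges[-1], percent_genes = NA_real_)
      attr(out, "n_genes") <- 0L
      return(out)
    }
    offs_per_gene <- offs_per_gene[has_site]
    n_genes <- length(offs_per_gene)
    pct <- vapply(seq_len(length(edges) - 1), function(b) {
      100 * mean(vapply(offs_per_gene, function(o) {
        any(o >= edges[b] & o < edges[b + 1])
      }, logical(1)))
    }, numeric(1))
    out <- data.frame(bin_start = utils::head(edges, -1), bin_end = edges[-1],
                      percent_genes = pct)
    attr(out, "n_genes") <- n_genes
    return(out)
  }
  if (is.null(track)) stop("provide either `sites` or `track`")
  bw <- track$bin_width
  offs <- window_offsets(c(-window, window), bw)
  acc <- numeric(length(offs))
  used <- 0L
  for (i in seq_len(nrow(tss_table))) {
    g <- tss_table[i, ]
    x <- track$counts[[g$chrom]]
    if (is.null(x)) next
    b0 <- floor(g$tss / bw) + 1
    jrel <- round(offs / bw - 0.5)
    if (g$strand == "-") jrel <- -jrel
    idx <- b0 + jrel
    if (any(idx < 1 | idx > length(x))) next
    acc <- acc + x[idx]
    used <- used + 1L
  }
  if (used == 0) stop("no TSS window fits inside the track")
  out <- data.frame(bin_start = offs - bw / 2, bin_end = offs + bw / 2,
                    mean_count = acc / used)
  attr(out, "n_genes") <- used
  out
}
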