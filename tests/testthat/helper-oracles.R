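# Independent brute-force oracles and small fixture builders shared across
# the test files. These deliberately re-derive results from first
# principles (loops, exhaustive enumeration) rather than calling package
# internals.

tmpfile_with <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

bf_revcomp <- function(s) {
  paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force normalised log-odds PSSM score of a single window
bf_match_score <- function(counts, window, bg = rep(0.25, 4), pc = 0.8) {
  bases <- c("A", "C", "G", "T")
  L <- ncol(counts)
  w <- matrix(0, 4, L)
  for (j in seq_len(L)) {
    tot <- sum(counts[, j]) + 4 * pc
    for (b in 1:4) w[b, j] <- log2(((counts[b, j] + pc) / tot) / bg[b])
  }
  chars <- strsplit(toupper(window), "")[[1]]
  S <- 0
  for (j in seq_len(L)) {
    b <- match(chars[j], bases)
    if (is.na(b)) return(-Inf)
    S <- S + w[b, j]
  }
  smin <- sum(apply(w, 2, min))
  smax <- sum(apply(w, 2, max))
  (S - smin) / (smax - smin)
}

# brute-force AUC: mean concordance over all (pos, neg) pairs, ties = 1/2
bf_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# brute-force overlap count: quadratic all-pairs half-open test
bf_overlap_count <- function(query, reference) {
  cnt <- 0L
  for (i in seq_len(nrow(query))) {
    hit <- FALSE
    for (j in seq_len(nrow(reference))) {
      if (query$chrom[i] == reference$chrom[j] &&
          query$start[i] < reference$end[j] &&
          reference$start[j] < query$end[i]) {
        hit <- TRUE
        break
      }
    }
    cnt <- cnt + hit
  }
  cnt
}

# brute-force seed-site scanner implementing the three patterns by direct
# substring comparison at every UTR offset, with 8mer > 7mer precedence
bf_seed_sites <- function(mature, utr) {
  m <- chartr("uU", "tT", toupper(mature))
  u <- chartr("uU", "tT", toupper(utr))
  rc28 <- bf_revcomp(substr(m, 2, 8))    # 7 nt
  rc27 <- bf_revcomp(substr(m, 2, 7))    # 6 nt
  p8 <- paste0(rc28, "A")
  p7a <- paste0(rc27, "A")
  n <- nchar(u)
  out <- list()
  is8 <- function(p) p + 7 <= n && substr(u, p, p + 7) == p8
  for (p in seq_len(max(n - 6, 0))) {
    if (p + 6 > n) break
    if (substr(u, p, p + 6) == rc28) {
      if (is8(p)) {
        out[[length(out) + 1L]] <- list(p - 1L, "8mer")
      } else {
        out[[length(out) + 1L]] <- list(p - 1L, "7mer-m8")
      }
    }
    if (substr(u, p, p + 6) == p7a && !(p >= 2 && is8(p - 1))) {
      out[[length(out) + 1L]] <- list(p - 1L, "7mer-1A")
    }
  }
  if (!length(out)) {
    return(data.frame(utr_position = integer(), site_type = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(utr_position = vapply(out, `[[`, 0L, 1),
                   site_type = vapply(out, `[[`, "", 2),
                   stringsAsFactors = FALSE)
  df[order(df$utr_position, df$site_type), , drop = FALSE]
}

# deterministic toy PSSM with a strong consensus
toy_pssm <- function(cons, id = "TOY", tf = "TOY_TF", strong = 17) {
  b <- strsplit(cons, "")[[1]]
  m <- matrix(1, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(b)) m[b[j], j] <- strong
  pssm(id, tf, m)
}

rand_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small simulation config used by pipeline unit tests (fast, full-featured)
small_sim_config <- function(seed = 11) {
  simulation_config(seed = seed, n_chrom = 2, chrom_length = 1.2e6,
                    n_coding_genes = 30, n_mirnas = 12)
}

# memoised small bundle shared by pipeline tests
shared_small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "mipronet_small_bundle")
      cache <<- simulate_bundle(small_sim_config(), dir)
    }
    cache
  }
})
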