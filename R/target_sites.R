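# Seed-match microRNA target-site finding.
#
# A site is an exact 3'UTR match (read 5'->3' on the UTR) to the reverse
# complement of the miRNA seed region:
#   8mer    -- reverse complement of miRNA positions 2-8, followed by 'A'
#   7mer-m8 -- reverse complement of miRNA positions 2-8
#   7mer-1A -- reverse complement of miRNA positions 2-7, followed by 'A'
# At a locus where the 8mer holds only the 8mer is emitted; the 7-mer types
# are reported where their pattern holds and the 8mer does not.

.seed_patterns <- function(mature) {
  m <- chartr("uU", "tT", toupper(mature))
  m <- gsub("\\s", "", m)
  if (nchar(m) < 8) stop("mature miRNA must be at least 8 nt")
  if (grepl("[^ACGT]", m)) stop("mature miRNA contains characters outside A/C/G/U")
  seed78 <- revcomp(substr(m, 2, 8))   # 7 nt
  list(seed78 = seed78,
       p8 = paste0(seed78, "A"),
       p7a = paste0(substr(seed78, 2, 7), "A"),
       c8 = substr(seed78, 1, 1))
}

.match_starts <- function(pattern, subject) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(subject))
  IRanges::start(hits)
}

# fast exact scanner over precomputed per-base (`chars`) and 7-mer window
# (`subs7`) decompositions of the UTR; same site logic as find_seed_sites
.scan_seed_sites <- function(pat, chars, subs7) {
  n <- length(chars)
  s78 <- which(subs7 == pat$seed78)
  is8 <- s78 + 7 <= n & chars[pmin(s78 + 7, n)] == "A"
  eight <- s78[is8]
  m8 <- s78[!is8]
  s7a <- which(subs7 == pat$p7a)
  subsumed <- s7a >= 2 & chars[pmax(s7a - 1, 1)] == pat$c8
  oneA <- s7a[!subsumed]
  data.frame(
    utr_position = c(eight, m8, oneA) - 1L,
    site_type = rep(c("8mer", "7mer-m8", "7mer-1A"),
                    times = c(length(eight), length(m8), length(oneA))),
    stringsAsFactors = FALSE)
}

#' Find seed-match target sites of a miRNA in a 3'UTR
#'
#' Reports every occurrence of the three site types with type precedence
#' (an 8mer locus is never double-counted as a 7mer). Matching is
#' case-insensitive and accepts U or T in the miRNA.
#'
#' @param mature mature miRNA sequence (RNA or DNA alphabet), length >= 8
#' @param utr 3'UTR DNA sequence
#' @param mirna_id,gene_id identifiers attached to the output
#' @return data frame with `mirna_id`, `gene_id`, `utr_position` (0-based
#'   start of the site match) and `site_type`
#' @export
find_seed_sites <- function(mature, utr, mirna_id = "mirna", gene_id = "gene") {
  pat <- .seed_patterns(mature)
  u <- chartr("uU", "tT", toupper(utr))
  n <- nchar(u)
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      utr_position = integer(), site_type = character(),
                      stringsAsFactors = FALSE)
  if (n < 7) return(empty)
  s78 <- .match_starts(pat$seed78, u)
  is8 <- s78 + 7 <= n & substr(rep(u, length(s78)), s78 + 7, s78 + 7) == "A"
  eight <- s78[is8]
  m8 <- s78[!is8]
  s7a <- .match_starts(pat$p7a, u)
  # a 7mer-1A whose locus extends an 8mer (preceding base completes the
  # 2-8 match) is subsumed by that 8mer
  subsumed <- s7a >= 2 & substr(rep(u, length(s7a)), s7a - 1, s7a - 1) == pat$c8
  oneA <- s7a[!subsumed]
  if (!length(eight) && !length(m8) && !length(oneA)) return(empty)
  out <- data.frame(
    mirna_id = mirna_id, gene_id = gene_id,
    utr_position = c(eight, m8, oneA) - 1L,
    site_type = rep(c("8mer", "7mer-m8", "7mer-1A"),
                    times = c(length(eight), length(m8), length(oneA))),
    stringsAsFactors = FALSE)
  out[order(out$utr_position), , drop = FALSE]
}

#' Seed-match target table for miRNA and UTR sets
#'
#' An edge (miRNA, gene) is present iff the gene's UTR carries at least one
#' seed site of any type; per-type site counts are attached.
#'
#' @param matures named character vector of mature miRNA sequences
#' @param utrs named character vector of 3'UTR sequences (names = gene ids)
#' @return data frame with `mirna_id`, `gene_id`, `n_8mer`, `n_7mer_m8`,
#'   `n_7mer_1a`, `n_sites`
#' @export
target_table <- function(matures, utrs) {
  rows <- list()
  for (m in names(matures)) {
    for (g in names(utrs)) {
      sites <- find_seed_sites(matures[[m]], utrs[[g]], m, g)
      if (!nrow(sites)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, gene_id = g,
        n_8mer = sum(sites$site_type == "8mer"),
        n_7mer_m8 = sum(sites$site_type == "7mer-m8"),
        n_7mer_1a = sum(sites$site_type == "7mer-1A"),
        n_sites = nrow(sites), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      n_8mer = integer(), n_7mer_m8 = integer(),
                      n_7mer_1a = integer(), n_sites = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
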