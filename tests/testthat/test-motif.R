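# motif_enrichment: PSSM scoring, background promoters, density-ratio FDR
# curves, cutoff selection and instance calling

test_that("normalised match score hits 1 at consensus and 0 at anti-consensus", {
  p <- toy_pssm("TGACTCA")
  expect_equal(match_score(p, "TGACTCA"), 1)
  # per-column argmin: counts are 1 for all non-consensus bases, ties break
  # to the first row; build the anti-consensus explicitly from the weights
  pp <- pssm_prepare(p)
  anti <- paste(rownames(pp$w)[apply(pp$w, 2, which.min)], collapse = "")
  expect_equal(match_score(p, anti), 0)
  expect_error(match_score(p, "ACGT"), "length")
  expect_identical(match_score(p, "TGANTCA"), -Inf)
})

test_that("match_score equals an independent brute-force log-odds computation", {
  set.seed(41)
  p <- pssm("R1", "RTF", matrix(sample(0:9, 48, replace = TRUE), 4))
  for (i in 1:50) {
    w <- rand_dna_str(12)
    expect_equal(match_score(p, w), bf_match_score(p$counts, w),
                 tolerance = 1e-12)
  }
})

test_that("best_match_in_region scans both strands and breaks ties leftmost/+", {
  p <- toy_pssm("TGACTCA")
  reg <- paste0("CCCCCCCC", "TGACTCA", "CCCCCCCC")
  b <- best_match_in_region(p, reg)
  expect_equal(b$score, 1)
  expect_equal(b$start, 9)
  expect_equal(b$strand, "+")
  # reverse complement of the consensus is found on the minus strand
  rc <- paste0("CCCCCCCC", bf_revcomp("TGACTCA"), "CCCCCCCC")
  b2 <- best_match_in_region(p, rc)
  expect_equal(b2$score, 1)
  expect_equal(b2$strand, "-")
  expect_equal(b2$start, 9)
  expect_error(best_match_in_region(p, "ACG"), "shorter")
})

test_that("best match equals the exhaustive per-window maximum", {
  set.seed(42)
  p <- pssm("R1", "RTF", matrix(sample(0:9, 32, replace = TRUE), 4))
  pp <- pssm_prepare(p)
  for (rep in 1:10) {
    reg <- rand_dna_str(100)
    b <- best_match_in_region(pp, reg)
    L <- ncol(p$counts)
    wins <- substring(reg, 1:(100 - L + 1), L:100)
    rcwins <- substring(bf_revcomp(reg), 1:(100 - L + 1), L:100)
    brute <- max(c(vapply(wins, match_score, 0, p = pp),
                   vapply(rcwins, match_score, 0, p = pp)))
    expect_equal(b$score, brute, tolerance = 1e-12)
  }
})

test_that("background promoters exclude ChIP-overlapping genes and honour strand", {
  genome <- list(chr1 = rand_dna_str(10000))
  genes <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                      tss = c(3000, 5000, 8000),
                      strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  chip <- genomic_intervals("chr1", 2500, 2600)   # inside a's upstream window
  bg <- build_background_promoters(genes, chip, genome)
  expect_identical(sort(names(bg)), c("b", "c"))
  expect_equal(nchar(bg[["b"]]), 1000)
  # minus strand: reverse complement of [tss+1, tss+1001)
  expect_identical(bg[["b"]],
                   bf_revcomp(substr(genome$chr1, 5002, 6001)))
  expect_identical(bg[["c"]], substr(genome$chr1, 7001, 8000))
  # truncation at the chromosome start warns
  g0 <- data.frame(id = "d", chrom = "chr1", tss = 300, strand = "+",
                   stringsAsFactors = FALSE)
  expect_warning(bg0 <- build_background_promoters(g0, chip[0, ], genome),
                 "truncated")
  expect_equal(nchar(bg0[["d"]]), 300)
})

test_that("an exact 5:1 hit-density ratio reports FDR 0.2 and select_cutoff applies the rule", {
  p <- toy_pssm("GGGGGGGGGGAC")
  L <- 12
  chip <- character(10)
  bg <- character(10)
  for (i in 1:10) {
    s <- paste(rep("A", 1000 + L - 1), collapse = "")
    substr(s, 400, 400 + L - 1) <- "GGGGGGGGGGAC"
    chip[i] <- s
    bg[i] <- if (i <= 2) s else paste(rep("A", 1000 + L - 1), collapse = "")
  }
  cur <- density_fdr_curve(p, chip, bg)
  at1 <- cur[cur$cutoff == 1, ]
  expect_equal(at1$chip_hits, 10)
  expect_equal(at1$bg_hits, 2)
  expect_equal(at1$fdr, 0.2)
  # select_cutoff equals a linear scan over the grid
  lin <- cur$cutoff[which(cur$fdr <= 0.2 & cur$chip_hits >= 5)]
  expect_equal(select_cutoff(cur, fdr_max = 0.2, min_chip_hits = 5), min(lin))
  # never enriched when fdr stays above the threshold
  cur2 <- density_fdr_curve(p, bg, bg)
  expect_true(is.na(select_cutoff(cur2)))
})

test_that("identical ChIP and background sets give FDR ~ 1 wherever there are hits", {
  set.seed(5)
  p <- toy_pssm("TGACTCA")
  seqs <- replicate(30, rand_dna_str(500))
  cur <- density_fdr_curve(p, seqs, seqs)
  hits <- cur$chip_hits > 0
  expect_true(all(abs(cur$fdr[hits] - 1) < 1e-12))
  expect_true(all(cur$fdr[!hits] == 1))
})

test_that("scanning is strand-symmetric: reverse-complementing inputs preserves densities", {
  set.seed(6)
  p <- toy_pssm("TTGCGCAA", id = "C1")
  chip <- replicate(20, rand_dna_str(300))
  bg <- replicate(20, rand_dna_str(300))
  cur <- density_fdr_curve(p, chip, bg)
  cur_rc <- density_fdr_curve(p, vapply(chip, bf_revcomp, ""),
                              vapply(bg, bf_revcomp, ""))
  expect_equal(cur$chip_density, cur_rc$chip_density)
  expect_equal(cur$bg_density, cur_rc$bg_density)
})

test_that("enriched_factors finds the planted matrix, not the decoy, and flags twins", {
  set.seed(9)
  planted <- toy_pssm("TTCCGGGAA", id = "P1", tf = "STAT1")
  decoy <- toy_pssm("CATGGTAC", id = "D1", tf = "DECOY")
  chip <- vapply(1:60, function(i) {
    s <- rand_dna_str(400)
    substr(s, 100, 108) <- "TTCCGGGAA"
    if (i %% 3 == 0) substr(s, 300, 308) <- "TTCCGGGAA"
    s
  }, "")
  bg <- replicate(80, rand_dna_str(400))
  res <- enriched_factors(list(planted, decoy), chip, bg)
  expect_true(res$report$enriched[res$report$pssm_id == "P1"])
  expect_false(res$report$enriched[res$report$pssm_id == "D1"])
  expect_equal(res$tf_report$tf, "STAT1")
  # two identical matrices under different factor names: both enriched,
  # similarity flagged
  twin <- toy_pssm("TTCCGGGAA", id = "P2", tf = "STAT1_TWIN")
  res2 <- enriched_factors(list(planted, twin), chip, bg)
  expect_true(all(res2$report$enriched))
  expect_equal(nrow(res2$similar_pairs), 1)
  expect_error(enriched_factors(list(planted), character(), bg), "empty ChIP")
})

test_that("call_instances preserves multiplicity and equals brute-force enumeration", {
  p <- toy_pssm("TGACTCA")
  genome <- list(chr1 = paste0(strrep("C", 50), "TGACTCA", strrep("C", 20),
                               "TGACTCA", strrep("C", 50)))
  reg <- genomic_intervals("chr1", 0, nchar(genome$chr1))
  inst <- call_instances(p, 0.99, reg, genome)
  expect_equal(nrow(inst), 2)
  expect_equal(inst$start, c(50, 77))
  expect_equal(inst$end - inst$start, c(7, 7))
  # cutoff above the maximum: nothing
  expect_equal(nrow(call_instances(p, 1 + 1e-9, reg, genome)), 0)
  # brute force on random sequence at a permissive cutoff
  set.seed(10)
  genome2 <- list(chr1 = rand_dna_str(300))
  reg2 <- genomic_intervals("chr1", 20, 280)
  got <- call_instances(p, 0.7, reg2, genome2)
  pp <- pssm_prepare(p)
  sq <- substr(genome2$chr1, 21, 280)
  nw <- nchar(sq) - 7 + 1
  brute <- 0L
  for (i in seq_len(nw)) {
    if (match_score(pp, substr(sq, i, i + 6)) >= 0.7) brute <- brute + 1L
    if (match_score(pp, bf_revcomp(substr(sq, i, i + 6))) >= 0.7) brute <- brute + 1L
  }
  expect_equal(nrow(got), brute)
})

test_that("planted-simulation FDR curves are non-increasing after isotonic smoothing", {
  set.seed(14)
  p <- toy_pssm("TTCCGGGAA", id = "P1", tf = "STAT1")
  chip <- vapply(1:220, function(i) {
    s <- rand_dna_str(400)
    pos <- sample(380, 1)
    substr(s, pos, pos + 8) <- sample_pssm_site(p)
    s
  }, "")
  bg <- vapply(1:220, function(i) {
    s <- rand_dna_str(400)
    if (i %% 5 == 0) {
      pos <- sample(380, 1)
      substr(s, pos, pos + 8) <- sample_pssm_site(p)
    }
    s
  }, "")
  cur <- density_fdr_curve(p, chip, bg)
  f <- pmin(cur$fdr, 1)
  smoothed <- -stats::isoreg(cur$cutoff, -f)$yf
  expect_true(all(diff(smoothed) <= 1e-9))
  expect_lt(utils::tail(smoothed, 1), smoothed[1])
})
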