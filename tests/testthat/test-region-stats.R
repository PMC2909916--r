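# region_stats: overlap counting, permutation and binomial null models,
# CpG islands and TSS-distance profiles

test_that("overlap_count uses half-open semantics and matches brute force", {
  q <- genomic_intervals("chr1", 10, 20)
  expect_equal(overlap_count(q, genomic_intervals("chr1", 19, 30)), 1)
  expect_equal(overlap_count(q, genomic_intervals("chr1", 20, 30)), 0)
  # containment counts
  expect_equal(overlap_count(q, genomic_intervals("chr1", 0, 100)), 1)
  set.seed(2)
  rq <- genomic_intervals(sample(c("chr1", "chr2"), 40, TRUE),
                          s <- sample(1000, 40), s + sample(50, 40, TRUE))
  rr <- genomic_intervals(sample(c("chr1", "chr2"), 30, TRUE),
                          s2 <- sample(1000, 30), s2 + sample(80, 30, TRUE))
  expect_equal(overlap_count(rq, rr), bf_overlap_count(rq, rr))
})

test_that("permutation test handles the saturated and empty-reference limits", {
  elig <- genomic_intervals("chr1", 0, 10000)
  q <- genomic_intervals("chr1", c(100, 5000), c(200, 5100))
  # reference covers everything eligible
  full <- permutation_overlap_test(q, elig, elig, n_perm = 50, seed = 1)
  expect_equal(full$p_hat, 1)
  expect_equal(full$p_value, 1)
  # empty reference: no overlap, p = 1
  none <- permutation_overlap_test(q, genomic_intervals(), elig,
                                   n_perm = 50, seed = 1)
  expect_equal(none$n_overlapping, 0)
  expect_equal(none$p_value, 1)
  # an over-long query interval is rejected
  expect_error(permutation_overlap_test(
    genomic_intervals("chr1", 0, 20000), elig, elig, n_perm = 5), "longer")
})

test_that("placement probability matches the analytic value on a toy universe", {
  # eligible [0, 100): a length-1 interval overlaps ref [0, 50) with
  # probability exactly 50/100
  elig <- genomic_intervals("chr1", 0, 100)
  ref <- genomic_intervals("chr1", 0, 50)
  q <- genomic_intervals("chr1", 10, 11)
  res <- permutation_overlap_test(q, ref, elig, n_perm = 4000, seed = 3)
  se <- sqrt(0.5 * 0.5 / 4000)
  expect_lt(abs(res$p_hat - 0.5), 3 * se)
  # binomial tail equals direct summation at the estimated p_hat
  direct <- sum(vapply(res$n_overlapping:res$n_query, function(j) {
    exp(lchoose(res$n_query, j) + j * log(res$p_hat) +
          (res$n_query - j) * log1p(-res$p_hat))
  }, numeric(1)))
  expect_equal(res$p_value, direct, tolerance = 1e-12)
})

test_that("permutation test is bit-exactly seed-reproducible", {
  elig <- genomic_intervals(c("chr1", "chr2"), 0, c(5e4, 3e4))
  ref <- genomic_intervals("chr1", seq(0, 4e4, 5000), seq(0, 4e4, 5000) + 800)
  q <- genomic_intervals("chr1", c(100, 9000, 22000), c(600, 9400, 22700))
  a <- permutation_overlap_test(q, ref, elig, n_perm = 500, seed = 99)
  b <- permutation_overlap_test(q, ref, elig, n_perm = 500, seed = 99)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$p_value, b$p_value)
})

test_that("query inside the reference is detected as enrichment", {
  elig <- genomic_intervals("chr1", 0, 1e5)
  ref <- genomic_intervals("chr1", seq(0, 9e4, 1e4), seq(0, 9e4, 1e4) + 1000)
  q <- genomic_intervals("chr1", seq(0, 9e4, 1e4) + 100,
                         seq(0, 9e4, 1e4) + 400)   # all inside ref blocks
  res <- permutation_overlap_test(q, ref, elig, n_perm = 1000, seed = 5)
  expect_equal(res$n_overlapping, 10)
  expect_lt(res$p_value, 1e-6)
})

test_that("binomial co-occurrence test matches direct summation to 1e-12", {
  expect_equal(binomial_cooccurrence_test(37, 0, 0.3), 1)
  direct <- sum(vapply(19:37, function(j) {
    exp(lchoose(37, j) + j * log(0.3) + (37 - j) * log1p(-0.3))
  }, numeric(1)))
  expect_equal(binomial_cooccurrence_test(37, 19, 0.3), direct,
               tolerance = 1e-12)
  # monotone decreasing in k
  ps <- vapply(0:37, binomial_cooccurrence_test, numeric(1), n = 37,
               p_hat = 0.3)
  expect_true(all(diff(ps) <= 0))
  expect_error(binomial_cooccurrence_test(10, 2, 1), "p_hat")
  expect_error(binomial_cooccurrence_test(10, 11, 0.5), "0 <= k <= n")
})

test_that("CpG islands require all three thresholds", {
  # poly-AT: nothing
  expect_equal(nrow(cpg_islands(strrep("AT", 500))), 0)
  # a 150-bp CpG-rich segment in AT-rich flanks fails the length rule:
  # no 200-bp window can reach 50% GC
  set.seed(19)
  at_rich <- function(n) paste(sample(c("A", "T", "C", "G"), n, TRUE,
                                      prob = c(0.45, 0.45, 0.05, 0.05)),
                               collapse = "")
  short <- paste0(at_rich(600), mipronet:::.gen_cpg_segment(150), at_rich(600))
  expect_equal(nrow(cpg_islands(short)), 0)
})

test_that("a planted GC=60%, obs/exp~0.8 segment is recovered as one island", {
  set.seed(20)
  at_rich <- function(n) paste(sample(c("A", "T", "C", "G"), n, TRUE,
                                      prob = c(0.4, 0.4, 0.1, 0.1)),
                               collapse = "")
  seg <- mipronet:::.gen_cpg_segment(400)
  seq <- paste0(at_rich(800), seg, at_rich(800))
  isl <- cpg_islands(seq, chrom = "chrT")
  expect_gte(nrow(isl), 1)
  cover <- sum(pmax(0, pmin(isl$end, 1200) - pmax(isl$start, 800)))
  expect_gte(cover / 400, 0.8)
  # every reported island satisfies the printed thresholds post hoc
  for (i in seq_len(nrow(isl))) {
    sub <- substr(seq, isl$start[i] + 1, isl$end[i])
    ch <- strsplit(sub, "")[[1]]
    L <- length(ch)
    nc <- sum(ch == "C"); ng <- sum(ch == "G")
    ncpg <- sum(ch[-L] == "C" & ch[-1] == "G")
    expect_gt(L, 200)
    expect_gte((nc + ng) / L, 0.5)
    expect_gt(ncpg * L / (nc * ng), 0.6)
  }
})

test_that("TSS profiles tally genes per bin with strand-aware offsets", {
  tss <- data.frame(id = paste0("g", 1:4), chrom = "chr1",
                    tss = c(10000, 20000, 30000, 40000),
                    strand = c("+", "+", "-", "-"), stringsAsFactors = FALSE)
  # every gene gets one site 100 bp downstream of its TSS (strand-aware)
  sites <- genomic_intervals("chr1",
                             c(10100, 20100, 29850, 39850),
                             c(10110, 20110, 29860, 39860))
  prof <- profile_around_tss(tss, sites = sites)
  expect_equal(attr(prof, "n_genes"), 4)
  central <- prof$percent_genes[prof$bin_start == 0]
  expect_equal(central, 100)
  expect_equal(sum(prof$percent_genes), 100)   # one in-window site per gene
  # genes without any in-window site are excluded with a warning
  far <- genomic_intervals("chr1", 90000, 90010)
  expect_warning(p0 <- profile_around_tss(tss, sites = far), "empty profile")
  expect_equal(attr(p0, "n_genes"), 0)
})

test_that("track-mode profiles average binned coverage across TSSs", {
  x <- rep(2L, 2000)
  x[100:120] <- 50L   # bump downstream of the + TSS at bin 100
  tr <- coverage_track(list(chr1 = x), 50)
  tss <- data.frame(id = "g1", chrom = "chr1", tss = 99 * 50, strand = "+",
                    stringsAsFactors = FALSE)
  prof <- profile_around_tss(tss, track = tr, window = 1000)
  expect_equal(nrow(prof), 40)
  expect_gt(max(prof$mean_count[prof$bin_start >= 0]), 40)
})
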