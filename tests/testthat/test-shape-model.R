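# promoter_model: the TSS shape profile, ML fitting, candidate scoring,
# upstream scanning, empirical FDR and ROC evaluation

REF_PARAMS <- shape_params(h_p = 2.0, h_b = 0.1, h_t = 0.6,
                           lambda_p = 0.01, lambda_t = 0.002)

test_that("expected_profile peaks at the TSS and decays to its flank levels", {
  expect_equal(expected_profile(REF_PARAMS, 0), 2.0)
  expect_equal(expected_profile(REF_PARAMS, -1e6), 0.1, tolerance = 1e-9)
  expect_equal(expected_profile(REF_PARAMS, 1e6), 0.6, tolerance = 1e-9)
  # strictly between the named levels everywhere
  x <- seq(-5000, 5000, by = 10)
  mu <- expected_profile(REF_PARAMS, x)
  expect_true(all(mu <= 2.0 & mu >= 0.1))
})

test_that("shape_params enforces positivity and the peak ordering", {
  expect_error(shape_params(2, -0.1, 0.6, 0.01, 0.002), "positive")
  expect_error(shape_params(0.5, 0.1, 0.6, 0.01, 0.002), "h_p")
  expect_error(shape_params(2, 0.1, 0.6, 0, 0.002), "positive")
})

test_that("simulate-and-refit recovers all five parameters within 10%", {
  w <- simulate_tss_windows(REF_PARAMS, 500, seed = 42)
  fit <- fit_shape_params(w, 50)
  est <- unlist(fit$params)
  truth <- unlist(REF_PARAMS)
  expect_true(all(abs(est - truth) / truth <= 0.10),
              info = paste(names(truth), round(est, 5), collapse = "; "))
})

test_that("flat windows force the three level parameters together", {
  w <- simulate_tss_windows(REF_PARAMS, 200, background_only = TRUE, seed = 7)
  fit <- fit_shape_params(w, 50)
  p <- fit$params
  expect_equal(p$h_p / p$h_b, 1, tolerance = 0.1)
  expect_equal(p$h_t / p$h_b, 1, tolerance = 0.1)
  expect_equal(p$h_b, 0.1, tolerance = 0.05)
})

test_that("the fitted likelihood is at least the truth's on the same data", {
  w <- simulate_tss_windows(REF_PARAMS, 100, seed = 3)
  fit <- fit_shape_params(w, 50)
  ll_true <- shape_loglik(w, REF_PARAMS, 50)
  expect_gte(fit$logLik, ll_true - 1e-6)
})

test_that("degenerate all-zero coverage is rejected", {
  w <- matrix(0L, 20, 260)
  expect_error(fit_shape_params(w, 50), "degenerate")
  expect_error(fit_shape_params(w[1:5, ], 50), "10 training windows")
})

test_that("candidate scores separate background from shaped windows and are deterministic", {
  null_w <- simulate_tss_windows(REF_PARAMS, 500, background_only = TRUE,
                                 seed = 5)
  alt_w <- simulate_tss_windows(REF_PARAMS, 500, seed = 6)
  s_null <- apply(null_w, 1, score_candidate_tss, REF_PARAMS, 50)
  s_alt <- apply(alt_w, 1, score_candidate_tss, REF_PARAMS, 50)
  expect_lt(mean(s_null), 0)
  expect_gt(mean(s_alt), 0)
  # score increases with the peak intensity
  strong <- shape_params(4, 0.1, 0.6, 0.01, 0.002)
  s_strong <- apply(simulate_tss_windows(strong, 500, seed = 6), 1,
                    score_candidate_tss, strong, 50)
  expect_gt(mean(s_strong), mean(s_alt))
  # deterministic
  expect_identical(score_candidate_tss(alt_w[1, ], REF_PARAMS, 50),
                   score_candidate_tss(alt_w[1, ], REF_PARAMS, 50))
})

test_that("scan scores are invariant under chromosome relabeling and strand mirroring", {
  set.seed(9)
  x <- rpois(1200, 5)
  x[580:620] <- rpois(41, 60)                 # a peak near bp 30000
  L <- 1200 * 50
  m_plus <- list(id = "m", chrom = "chr1", start = 30000, end = 30080,
                 strand = "+")
  tr <- coverage_track(list(chr1 = x), 50)
  fwd <- scan_mirna_upstream(tr, m_plus, REF_PARAMS, max_distance = 2000)
  # relabel the chromosome: identical scores
  tr2 <- coverage_track(list(chrX = x), 50)
  m2 <- m_plus; m2$chrom <- "chrX"
  expect_identical(scan_mirna_upstream(tr2, m2, REF_PARAMS,
                                       max_distance = 2000)$score, fwd$score)
  # mirror the whole chromosome and scan the minus-strand image: the
  # 5' end maps bp p -> L - 1 - p
  tr_rev <- coverage_track(list(chr1 = rev(x)), 50)
  m_minus <- list(id = "m", chrom = "chr1", start = L - 30080,
                  end = L - 30000, strand = "-")
  rev_scan <- scan_mirna_upstream(tr_rev, m_minus, REF_PARAMS,
                                  max_distance = 2000)
  expect_equal(rev_scan$score, fwd$score, tolerance = 1e-9)
  expect_equal(rev_scan$distance, fwd$distance)
})

test_that("upstream scanning recovers planted miRNA TSSs within one bin", {
  for (dist in c(200, 3600, 10000)) {
    cfg <- simulation_config(seed = 13, n_chrom = 1, chrom_length = 3e5,
                             n_coding_genes = 0, n_mirnas = 2,
                             mirna_active_fraction = 1,
                             mirna_jitter_sdlog = 1e-6,
                             tss_distance_range = c(dist, dist),
                             emit_sequences = FALSE)
    ann <- simulate_genome(cfg)
    track <- simulate_rpol2_coverage(ann, cfg)
    params <- tier_params <- shape_params(0.9, 0.1, 0.18, 0.01, 0.002)
    for (i in seq_len(nrow(ann$mirnas))) {
      m <- ann$mirnas[i, ]
      hit <- scan_mirna_upstream(track, m, params)
      # one bin of scan resolution plus one bin of grid snap
      expect_lte(abs(hit$tss - m$tss), 100,
                 label = sprintf("distance %d, %s strand", dist, m$strand))
    }
  }
})

test_that("scanning an absent chromosome errors; ties break toward the miRNA", {
  track <- coverage_track(list(chr1 = rep(5L, 1000)), 50)
  m <- list(id = "m", chrom = "chrX", start = 3e4, end = 3e4 + 80,
            strand = "+")
  expect_error(scan_mirna_upstream(track, m, REF_PARAMS), "absent")
  # perfectly flat coverage: every candidate ties; closest wins
  m$chrom <- "chr1"
  hit <- scan_mirna_upstream(track, m, REF_PARAMS)
  expect_equal(hit$distance, 0)
})

test_that("promoter regions contain the TSS and degrade to a single bin on background", {
  cfg <- simulation_config(seed = 17, n_chrom = 1, chrom_length = 3e5,
                           n_coding_genes = 0, n_mirnas = 1,
                           mirna_active_fraction = 1,
                           mirna_jitter_sdlog = 1e-6,
                           emit_sequences = FALSE)
  ann <- simulate_genome(cfg)
  track <- simulate_rpol2_coverage(ann, cfg)
  m <- ann$mirnas[1, ]
  params <- shape_params(0.9, 0.1, 0.18, 0.01, 0.002)
  r <- call_promoter_region(track, m$chrom, m$tss, params)
  expect_true(r$start <= m$tss && m$tss < r$end)
  expect_lte(r$end - r$start, 5000)
  # background-only position: single TSS bin
  flat <- coverage_track(list(chr1 = rep(5L, 6000)), 50)
  r0 <- call_promoter_region(flat, "chr1", 150000, params)
  expect_equal(r0$end - r0$start, 50)
  expect_true(r0$start <= 150000 && 150000 < r0$end)
})

test_that("stronger peaks never shrink the called region (paired simulation)", {
  widths <- vapply(c(0.5, 4), function(hp) {
    p <- shape_params(hp, 0.1, min(0.3, hp), 0.01, 0.002)
    w <- simulate_tss_windows(p, 1, window = c(-10000, 10000), seed = 21)[1, ]
    tr <- coverage_track(list(chr1 = w), 50)
    r <- call_promoter_region(tr, "chr1", 10000, p)
    r$end - r$start
  }, numeric(1))
  expect_gte(widths[2], widths[1])
})

test_that("empirical FDR: exceedance ratio, clipping and monotonization", {
  null <- c(1, 2, 3, 4, 5)
  expect_equal(empirical_fdr(10, null), 0)              # above max(null)
  fdr <- empirical_fdr(c(10, 4.5, 0), null)
  expect_equal(fdr, c(0, 1 / 5 / (2 / 3), 1))
  # monotone non-increasing in score
  set.seed(8)
  cand <- rnorm(200)
  fdr2 <- empirical_fdr(cand, rnorm(1000))
  o <- order(cand, decreasing = TRUE)
  expect_true(all(diff(fdr2[o]) >= -1e-12))
  expect_error(empirical_fdr(1, numeric(0)), "empty null")
})

test_that("empirical FDR is conservative-or-accurate on signal/null mixtures", {
  q <- 0.2
  viol <- 0L
  set.seed(33)
  for (rep in 1:20) {
    null <- rnorm(2000)
    cand_null <- rnorm(150)
    cand_sig <- rnorm(150, mean = 6)
    fdr <- empirical_fdr(c(cand_sig, cand_null), null)
    accepted <- fdr <= q
    if (!any(accepted)) next
    false_frac <- sum(accepted[151:300]) / sum(accepted)
    se <- sqrt(q * (1 - q) / sum(accepted))
    if (false_frac > q + 2 * se) viol <- viol + 1L
  }
  expect_lte(viol, 2)   # allow rare 2-s.e. exceedances across 20 replicates
})

test_that("AUC matches exhaustive pair counting and behaves at the extremes", {
  set.seed(12)
  pos <- sample(1:10, 12, replace = TRUE)   # include ties
  neg <- sample(1:10, 8, replace = TRUE)
  got <- evaluate_roc(c(pos, neg), rep(c(TRUE, FALSE), c(12, 8)))$auc
  expect_equal(got, bf_auc(pos, neg))
  # perfect separation
  expect_equal(evaluate_roc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # label-independent scores: AUC ~ 0.5 within 3 s.e.
  set.seed(13)
  sc <- rnorm(600)
  lab <- rep(c(TRUE, FALSE), 300)
  auc <- evaluate_roc(sc, lab)$auc
  se <- sqrt((300 + 300 + 1) / (12 * 300 * 300))
  expect_lt(abs(auc - 0.5), 3 * se)
  expect_error(evaluate_roc(1:5, rep(TRUE, 5)), "both")
})
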