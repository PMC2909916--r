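# synthetic_data: determinism, placement constraints, coverage model,
# density-ratio planting and UTR ground truth

test_that("identical seeds give identical bundles; different seeds differ", {
  cfg <- simulation_config(seed = 5, n_chrom = 1, chrom_length = 6e5,
                           n_coding_genes = 6, n_mirnas = 4)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- simulate_bundle(cfg, d1)$manifest
  m2 <- simulate_bundle(cfg, d2)$manifest
  expect_identical(m1$md5, m2$md5)
  cfg2 <- simulation_config(seed = 6, n_chrom = 1, chrom_length = 6e5,
                            n_coding_genes = 6, n_mirnas = 4)
  d3 <- file.path(tempdir(), "det3")
  unlink(d3, recursive = TRUE)
  m3 <- simulate_bundle(cfg2, d3)$manifest
  expect_false(all(m1$md5 == m3$md5))
})

test_that("a genome without coding genes carries only miRNAs", {
  cfg <- simulation_config(seed = 2, n_chrom = 1, chrom_length = 4e5,
                           n_coding_genes = 0, n_mirnas = 5,
                           emit_sequences = FALSE)
  ann <- simulate_genome(cfg)
  expect_equal(nrow(ann$genes), 0)
  expect_equal(nrow(ann$mirnas), 5)
})

test_that("pairwise feature TSS distances respect the isolation filter", {
  cfg <- simulation_config(seed = 3, emit_sequences = FALSE)
  ann <- simulate_genome(cfg)
  tss <- c(ann$genes$tss, ann$mirnas$tss[!is.na(ann$mirnas$tss)])
  chrom <- c(ann$genes$chrom, ann$mirnas$chrom[!is.na(ann$mirnas$tss)])
  for (ch in unique(chrom)) {
    v <- sort(tss[chrom == ch])
    if (length(v) > 1) expect_gte(min(diff(v)), 10000)
  }
  # too-small genome errors
  expect_error(simulate_genome(
    simulation_config(seed = 3, n_chrom = 1, chrom_length = 1e5,
                      n_coding_genes = 10, n_mirnas = 0,
                      emit_sequences = FALSE)), "too small")
})

test_that("all-inactive annotations give pure background coverage", {
  cfg <- simulation_config(
    seed = 4, n_chrom = 1, chrom_length = 5e5, n_coding_genes = 6,
    n_mirnas = 3, mirna_active_fraction = 0,
    tier_fractions = c(unexpressed = 1, low = 0, medium = 0, high = 0),
    emit_sequences = FALSE)
  ann <- simulate_genome(cfg)
  track <- simulate_rpol2_coverage(ann, cfg)
  x <- track$counts[[1]]
  mu <- cfg$base_shape$h_b * cfg$bin_width
  se <- sqrt(mu / length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
})

test_that("the TSS-bin count matches its closed-form Poisson mean", {
  params <- shape_params(2.0, 0.1, 0.6, 0.01, 0.002)
  w <- simulate_tss_windows(params, 5000, seed = 10)
  offs <- seq(-3000 + 25, 10000 - 25, by = 50)
  tss_bin <- which(offs == 25)
  m_expect <- 50 * expected_profile(params, 25)     # ~ 96.7, i.e. ~ 100
  m_obs <- mean(w[, tss_bin])
  expect_lt(abs(m_obs - m_expect), 3 * sqrt(m_expect / 5000))
  # doubling h_p doubles the above-background TSS-bin intensity
  params2 <- shape_params(4.0, 0.1, 0.6, 0.01, 0.002)
  w2 <- simulate_tss_windows(params2, 5000, seed = 10)
  m2_expect <- 50 * expected_profile(params2, 25)
  expect_lt(abs(mean(w2[, tss_bin]) - m2_expect), 3 * sqrt(m2_expect / 5000))
  expect_equal(m2_expect / m_expect, 2, tolerance = 0.02)
})

test_that("rate planting reproduces the configured ChIP/background density ratio", {
  cfg <- simulation_config(seed = 21, n_chrom = 3, chrom_length = 2.6e6,
                           n_coding_genes = 120, n_mirnas = 0,
                           chip_gene_fraction = 0, n_random_chip_regions = 250,
                           density_ratio = 5, bg_motif_rate = 2)
  ann <- simulate_genome(cfg)
  res <- plant_chip_regions(ann, cfg)
  inst <- res$instances[res$instances$pssm_id == "STAT1_01", ]
  chip_kb <- sum(gi_width(res$chip_regions)) / 1000
  bg_kb <- sum(!ann$genes$id %in% res$tf_bound_genes)   # 1 kb per promoter
  ratio <- (sum(inst$where == "chip") / chip_kb) /
    (sum(inst$where == "background") / bg_kb)
  expect_gte(nrow(res$chip_regions), 200)
  expect_lt(abs(ratio - 5) / 5, 0.2)
})

test_that("r = 1 planting carries no enrichment signal", {
  cfg <- simulation_config(seed = 22, n_chrom = 2, chrom_length = 2.6e6,
                           n_coding_genes = 30, n_mirnas = 0,
                           chip_gene_fraction = 0, n_random_chip_regions = 100,
                           density_ratio = 1, bg_motif_rate = 2)
  ann <- simulate_genome(cfg)
  res <- plant_chip_regions(ann, cfg)
  inst <- res$instances[res$instances$pssm_id == "STAT1_01", ]
  chip_kb <- sum(gi_width(res$chip_regions)) / 1000
  bg_kb <- sum(!ann$genes$id %in% res$tf_bound_genes)
  ratio <- (sum(inst$where == "chip") / chip_kb) /
    (sum(inst$where == "background") / bg_kb)
  expect_lt(abs(ratio - 1) / 1, 0.45)
})

test_that("planted ChIP instances are written into the sequences verbatim", {
  cfg <- simulation_config(seed = 23, n_chrom = 1, chrom_length = 8e5,
                           n_coding_genes = 8, n_mirnas = 4)
  ann <- simulate_genome(cfg)
  res <- plant_chip_regions(ann, cfg)
  inst <- res$instances
  for (i in sample(nrow(inst), min(40, nrow(inst)))) {
    found <- substr(res$sequences[[inst$chrom[i]]], inst$start[i] + 1,
                    inst$end[i])
    want <- if (inst$strand[i] == "-") bf_revcomp(inst$site[i]) else
      inst$site[i]
    expect_identical(found, want)
  }
})

test_that("UTR planting yields exactly the recorded sites and nothing else", {
  cfg <- simulation_config(seed = 24, n_chrom = 1, chrom_length = 8e5,
                           n_coding_genes = 8, n_mirnas = 6,
                           mirna_active_fraction = 1)
  ann <- simulate_genome(cfg)
  plant <- data.frame(
    mirna_id = ann$mirnas$id[1:3],
    gene_id = c("gene_001", "gene_002", "IFNG"),
    site_type = c("8mer", "7mer-m8", "7mer-1A"), stringsAsFactors = FALSE)
  res <- simulate_utrs(ann, cfg, plant_table = plant)
  matures <- stats::setNames(ann$mirnas$mature, ann$mirnas$id)
  for (m in names(matures)) {
    for (g in names(res$utrs)) {
      found <- find_seed_sites(matures[[m]], res$utrs[[g]], m, g)
      want <- res$sites[res$sites$mirna_id == m & res$sites$gene_id == g, ]
      expect_equal(nrow(found), nrow(want))
      if (nrow(want)) {
        expect_setequal(paste(found$utr_position, found$site_type),
                        paste(want$utr_position, want$site_type))
      }
    }
  }
  # a planted 7mer-m8 is never an 8mer: verified by the exactness above,
  # and the recorded type matches the request
  expect_identical(res$sites$site_type[match(plant$mirna_id,
                                             res$sites$mirna_id)],
                   plant$site_type)
  expect_error(simulate_utrs(ann, cfg, plant_table = data.frame(
    mirna_id = ann$mirnas$id[1], gene_id = "gene_001",
    site_type = "6mer", stringsAsFactors = FALSE)), "unknown site_type")
})
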