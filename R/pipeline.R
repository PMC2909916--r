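# End-to-end orchestration: a single configuration drives simulation and
# the five analysis stages (promoter calling -> motif enrichment -> region
# statistics -> target prediction -> network assembly), with deterministic
# per-stage seeding derived from one master seed and a config/seed stamp on
# every output table.

#' Pipeline configuration
#'
#' Paths default to the standard file names written by [run_simulate()]
#' inside `input_dir`. Thresholds and windows carry the pipeline's standard
#' constants: promoter and motif FDR 0.2, 10,000 permutations, feed-forward
#' window -1000..+500 bp, upstream scan limit 10,000 bp.
#'
#' @param input_dir directory holding the input bundle
#' @param out_dir output directory (default `<input_dir>/results`)
#' @param coverage,annotations,tiers,genome,chip_regions,pssms,matures,utrs
#'   input file paths
#' @param bin_width coverage bin width (bp)
#' @param promoter_fdr acceptance threshold for promoter calls, in (0, 1]
#' @param motif_fdr density-ratio FDR threshold for motif enrichment
#' @param cutoff_grid ascending normalised-score cutoff grid
#' @param n_perm permutation count for overlap tests
#' @param ff_window feed-forward regulatory window around gene TSSs (bp)
#' @param max_upstream maximum miRNA upstream scan distance (bp)
#' @param scan_window scoring window around each candidate TSS (bp)
#' @param train_fraction fraction of eligible expressed genes used to train
#'   the shape model
#' @param min_transcript_length,min_tss_isolation training-gene filters (bp)
#' @param n_null_anchors random intergenic anchors scanned for the null
#'   score distribution
#' @param min_chip_hits minimum ChIP hits behind a selected motif cutoff
#' @param region_k,max_region_width promoter-region growing parameters
#' @param tf_name the ChIP-assayed factor
#' @param focal_genes focal gene set for feedback motifs
#' @param seed master seed
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(
    input_dir,
    out_dir = file.path(input_dir, "results"),
    coverage = file.path(input_dir, "rpol2_coverage.bedGraph"),
    annotations = file.path(input_dir, "annotations.gff3"),
    tiers = file.path(input_dir, "expression_tiers.tsv"),
    genome = file.path(input_dir, "genome.fa"),
    chip_regions = file.path(input_dir, "chip_regions.bed"),
    pssms = file.path(input_dir, "pssm_library.txt"),
    matures = file.path(input_dir, "mature_mirnas.fa"),
    utrs = file.path(input_dir, "utrs_3p.fa"),
    bin_width = 50,
    promoter_fdr = 0.2,
    motif_fdr = 0.2,
    cutoff_grid = seq(0.60, 1.00, by = 0.01),
    n_perm = 10000,
    ff_window = c(-1000, 500),
    max_upstream = 10000,
    scan_window = c(-3000, 10000),
    train_fraction = 0.25,
    min_transcript_length = 10000,
    min_tss_isolation = 10000,
    n_null_anchors = 300,
    min_chip_hits = 5,
    region_k = 2,
    max_region_width = 5000,
    tf_name = "STAT1",
    focal_genes = c("IFNG", "STAT1", "JUN", "FOS"),
    seed = 1) {
  cfg <- as.list(environment())
  for (f in c("promoter_fdr", "motif_fdr")) {
    if (!(cfg[[f]] > 0 && cfg[[f]] <= 1)) {
      stop(sprintf("%s must lie in (0, 1]", f))
    }
  }
  if (ff_window[1] >= ff_window[2]) stop("ff_window must be well-ordered")
  if (!(scan_window[1] < 0 && scan_window[2] > 0)) {
    stop("scan_window must straddle the TSS")
  }
  if (n_perm < 1 || max_upstream <= 0 || bin_width <= 0) {
    stop("n_perm, max_upstream and bin_width must be positive")
  }
  if (is.unsorted(cutoff_grid)) stop("cutoff_grid must be ascending")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML file override [pipeline_config()] defaults.
#' @param path YAML file with an `input_dir` entry
#' @param seed optional master-seed override
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, y[intersect(names(y), known)])
}

# stamped TSV writers: every result table carries the config digest + seed;
# the digest covers the analytic parameters, not the output location
write_result_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  key <- unclass(cfg)
  key$out_dir <- NULL
  writeLines(sprintf("# mipronet config=%s seed=%d",
                     config_digest(key), as.integer(cfg$seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a synthetic input bundle with ground truth
#'
#' Runs the full generator (genome, ChIP regions with planted instances,
#' UTRs with planted seed sites, RPol II coverage) and writes every input
#' file the pipeline consumes plus ground-truth tables and a checksum
#' manifest under `out_dir`.
#'
#' @param config a [simulation_config()]
#' @param out_dir output directory (created if missing)
#' @return invisibly, the in-memory bundle (annotations, chip, utr, track,
#'   expected motif tables, manifest)
#' @export
simulate_bundle <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gt_dir <- file.path(out_dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  ann <- simulate_genome(config)
  chip <- plant_chip_regions(ann, config)
  utr <- simulate_utrs(ann, config, tf_bound_genes = chip$tf_bound_genes)
  track <- simulate_rpol2_coverage(ann, config)

  write_fasta(chip$sequences, file.path(out_dir, "genome.fa"))
  gff <- rbind(
    data.frame(id = ann$genes$id, chrom = ann$genes$chrom,
               start = ann$genes$start, end = ann$genes$end,
               strand = ann$genes$strand, kind = "coding", type = "gene",
               stringsAsFactors = FALSE),
    data.frame(id = ann$mirnas$id, chrom = ann$mirnas$chrom,
               start = ann$mirnas$start, end = ann$mirnas$end,
               strand = ann$mirnas$strand, kind = "mirna", type = "pre_miRNA",
               stringsAsFactors = FALSE))
  write_gff3(gff, file.path(out_dir, "annotations.gff3"))
  utils::write.table(ann$genes[, c("id", "tier")],
                     file.path(out_dir, "expression_tiers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bedgraph(track, file.path(out_dir, "rpol2_coverage.bedGraph"))
  write_bed(chip$chip_regions, file.path(out_dir, "chip_regions.bed"))
  write_pssm_library(synthetic_pssm_library(),
                     file.path(out_dir, "pssm_library.txt"))
  write_fasta(stats::setNames(ann$mirnas$mature, ann$mirnas$id),
              file.path(out_dir, "mature_mirnas.fa"))
  write_fasta(utr$utrs, file.path(out_dir, "utrs_3p.fa"))

  act <- ann$mirnas[ann$mirnas$active %in% TRUE, , drop = FALSE]
  focal <- config$focal_utr_ids
  fb_expected <- utr$plant_table[utr$plant_table$gene_id %in% focal &
                                   utr$plant_table$mirna_id %in% act$id, ,
                                 drop = FALSE]
  fb_expected <- if (nrow(fb_expected)) data.frame(
    mirna = fb_expected$mirna_id, target_gene = fb_expected$gene_id,
    stringsAsFactors = FALSE) else
    data.frame(mirna = character(), target_gene = character())
  ff_expected <- utr$plant_table[utr$plant_table$gene_id %in%
                                   chip$tf_bound_genes &
                                   utr$plant_table$mirna_id %in% act$id, ,
                                 drop = FALSE]
  ff_expected <- if (nrow(ff_expected)) data.frame(
    tf = "STAT1", mirna = ff_expected$mirna_id, gene = ff_expected$gene_id,
    stringsAsFactors = FALSE) else
    data.frame(tf = character(), mirna = character(), gene = character())

  wt <- function(df, name) {
    utils::write.table(df, file.path(gt_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(act[, c("id", "chrom", "strand", "tss", "distance", "signal_scale")],
     "active_mirnas.tsv")
  wt(ann$genes, "genes.tsv")
  wt(chip$instances, "planted_instances.tsv")
  wt(utr$sites, "planted_sites.tsv")
  wt(fb_expected, "expected_feedback.tsv")
  wt(unique(ff_expected), "expected_feedforward.tsv")
  wt(data.frame(gene_id = chip$tf_bound_genes), "tf_bound_genes.tsv")
  wt(data.frame(mirna_id = chip$cofactor_mirnas), "cofactor_mirnas.tsv")
  write_bed(ann$cpg_truth, file.path(gt_dir, "cpg_islands_planted.bed"))

  cfg_plain <- unclass(config)
  cfg_plain$base_shape <- unclass(cfg_plain$base_shape)
  yaml::write_yaml(cfg_plain, file.path(out_dir, "sim_config.yaml"))

  files <- sort(c(list.files(out_dir, recursive = TRUE, full.names = FALSE)))
  files <- setdiff(files, "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(annotations = ann, chip = chip, utr = utr, track = track,
                 expected_feedback = fb_expected,
                 expected_feedforward = unique(ff_expected),
                 manifest = manifest, out_dir = out_dir))
}

#' Generate the synthetic dataset for a pipeline run
#' @param sim_config a [simulation_config()]
#' @param out_dir bundle directory
#' @return see [simulate_bundle()]
#' @export
run_simulate <- function(sim_config, out_dir) {
  simulate_bundle(sim_config, out_dir)
}

# ---- stage: promoter calling -------------------------------------------

#' Stage 1: fit the shape model and call miRNA promoters
#'
#' Trains on a seeded random fraction of expressed genes passing the
#' training filter (transcript length and TSS isolation), evaluates ROC on
#' the held-out genes, scans every miRNA upstream region, and assigns
#' empirical FDRs against a null built from the same max-over-scan
#' statistic at random intergenic anchors pooled with unexpressed-gene TSS
#' scans.
#'
#' @param cfg a [pipeline_config()]
#' @return list with `params`, `calls`, `roc`, `gene_scores`, `null_scores`
#' @export
stage_call_promoters <- function(cfg) {
  track <- read_coverage(cfg$coverage, cfg$bin_width)
  ann <- read_gff3(cfg$annotations)
  genes <- ann[ann$kind == "coding", , drop = FALSE]
  mirnas <- ann[ann$kind == "mirna", , drop = FALSE]
  tiers <- utils::read.delim(cfg$tiers, stringsAsFactors = FALSE)
  genes$tier <- tiers$tier[match(genes$id, tiers[[1]])]
  if (anyNA(genes$tier)) stop("expression tier missing for some genes")

  # training filter: long transcripts with no neighbouring gene TSS nearby
  iso <- vapply(seq_len(nrow(genes)), function(i) {
    same <- genes$chrom == genes$chrom[i]
    d <- abs(genes$tss[same] - genes$tss[i])
    min(d[d > 0], Inf)
  }, numeric(1))
  eligible <- genes$end - genes$start > cfg$min_transcript_length &
    iso >= cfg$min_tss_isolation
  expressed <- genes$tier != "unexpressed"
  pool <- which(eligible & expressed)
  n_train <- max(10L, round(cfg$train_fraction * length(pool)))
  if (length(pool) < 10) stop("fewer than 10 eligible training genes")
  train_idx <- with_seed(derive_seed(cfg$seed, "train_split"),
                         sort(sample(pool, min(n_train, length(pool)))))

  bw <- track$bin_width
  get_window <- function(chrom, tss, strand) {
    offs <- window_offsets(cfg$scan_window, bw)
    jrel <- round(offs / bw - 0.5)
    if (strand == "-") jrel <- -jrel
    x <- track$counts[[chrom]]
    idx <- floor(tss / bw) + 1 + jrel
    if (is.null(x) || any(idx < 1 | idx > length(x))) return(NULL)
    x[idx]
  }
  train_windows <- Filter(Negate(is.null), lapply(train_idx, function(i) {
    get_window(genes$chrom[i], genes$tss[i], genes$strand[i])
  }))
  fit <- fit_shape_params(train_windows, bw, cfg$scan_window)

  # held-out ROC
  test_idx <- setdiff(seq_len(nrow(genes)), train_idx)
  gene_scores <- data.frame(gene_id = genes$id, tier = genes$tier,
                            train = seq_len(nrow(genes)) %in% train_idx,
                            score = NA_real_, stringsAsFactors = FALSE)
  for (i in test_idx) {
    w <- get_window(genes$chrom[i], genes$tss[i], genes$strand[i])
    if (is.null(w)) next
    gene_scores$score[i] <- score_candidate_tss(w, fit$params, bw,
                                                cfg$scan_window)
  }
  ev <- gene_scores[!gene_scores$train & !is.na(gene_scores$score), ]
  roc <- evaluate_roc(ev$score, ev$tier != "unexpressed",
                      tiers = ev$tier)

  # candidate scans
  calls <- lapply(seq_len(nrow(mirnas)), function(i) {
    scan_mirna_upstream(track, mirnas[i, ], fit$params, cfg$max_upstream,
                        cfg$scan_window)
  })
  cand_scores <- vapply(calls, `[[`, numeric(1), "score")

  # null: same statistic at random intergenic anchors + unexpressed TSSs.
  # Anchors are kept clear of every annotated feature by the full reach of
  # the scan (max_upstream + scoring window), so they measure pure
  # background behaviour of the max-over-scan statistic.
  chrom_bins <- lengths(track$counts)
  pad_up <- cfg$max_upstream - cfg$scan_window[1] + 2 * bw
  pad_down <- cfg$scan_window[2] + 2 * bw
  pad <- max(pad_up, pad_down)
  null_anchor <- with_seed(derive_seed(cfg$seed, "null_anchors"), {
    out <- list()
    tries <- 0L
    while (length(out) < cfg$n_null_anchors &&
           tries < 200L * cfg$n_null_anchors) {
      tries <- tries + 1L
      ch <- sample(names(track$counts), 1)
      lim <- chrom_bins[[ch]] * bw
      pos <- floor(stats::runif(1, pad, lim - pad))
      near <- ann$chrom == ch & ann$start - pad < pos & ann$end + pad > pos
      if (any(near)) next
      out[[length(out) + 1L]] <- list(chrom = ch, start = pos, end = pos + 1,
                                      strand = sample(c("+", "-"), 1),
                                      id = sprintf("null_%d", length(out) + 1L))
    }
    if (length(out) < cfg$n_null_anchors) {
      warning("could not place all null anchors clear of annotation; using ",
              length(out))
    }
    out
  })
  null_scores <- vapply(null_anchor, function(a) {
    scan_mirna_upstream(track, a, fit$params, cfg$max_upstream,
                        cfg$scan_window)$score
  }, numeric(1))
  unexpr <- which(genes$tier == "unexpressed")
  null_unexpr <- vapply(unexpr, function(i) {
    a <- list(chrom = genes$chrom[i], start = genes$start[i],
              end = genes$end[i], strand = genes$strand[i],
              id = genes$id[i])
    scan_mirna_upstream(track, a, fit$params, cfg$max_upstream,
                        cfg$scan_window)$score
  }, numeric(1))
  null_scores <- c(null_scores, null_unexpr)

  fdr <- empirical_fdr(cand_scores, null_scores)
  call_df <- data.frame(
    mirna_id = vapply(calls, `[[`, "", "mirna_id"),
    chrom = mirnas$chrom, strand = mirnas$strand,
    tss = vapply(calls, `[[`, numeric(1), "tss"),
    distance = vapply(calls, `[[`, numeric(1), "distance"),
    score = cand_scores, fdr = fdr,
    accepted = fdr <= cfg$promoter_fdr,
    region_start = NA_real_, region_end = NA_real_,
    stringsAsFactors = FALSE)
  for (i in which(call_df$accepted)) {
    r <- call_promoter_region(track, call_df$chrom[i], call_df$tss[i],
                              fit$params, cfg$region_k, cfg$max_region_width)
    call_df$region_start[i] <- r$start
    call_df$region_end[i] <- r$end
  }
  list(params = fit$params, logLik = fit$logLik, calls = call_df, roc = roc,
       gene_scores = gene_scores, null_scores = null_scores)
}

# ---- stage: motif enrichment -------------------------------------------

#' Stage 2: collaborating-factor motif enrichment and instance calling
#' @param cfg a [pipeline_config()]
#' @return list with `enrichment` (see [enriched_factors()]), `instances`,
#'   `chip_regions`, `chip_seqs`, `bg_seqs`, `genome`
#' @export
stage_enrich_motifs <- function(cfg) {
  genome <- read_fasta(cfg$genome)
  chip <- read_bed(cfg$chip_regions)
  pssms <- read_pssm_library(cfg$pssms)
  ann <- read_gff3(cfg$annotations)
  genes <- ann[ann$kind == "coding", , drop = FALSE]
  chip_seqs <- vapply(seq_len(nrow(chip)), function(i) {
    substr(genome[[chip$chrom[i]]], chip$start[i] + 1, chip$end[i])
  }, "")
  bg_seqs <- build_background_promoters(genes, chip, genome)
  enr <- enriched_factors(pssms, chip_seqs, bg_seqs, cfg$cutoff_grid,
                          cfg$motif_fdr, cfg$min_chip_hits)
  bgf <- base_frequencies(bg_seqs)
  inst <- list()
  rep_enr <- enr$report[enr$report$enriched, , drop = FALSE]
  for (i in seq_len(nrow(rep_enr))) {
    p <- pssms[[match(rep_enr$pssm_id[i],
                      vapply(pssms, `[[`, "", "id"))]]
    p <- pssm_prepare(p, background = bgf)
    inst[[i]] <- call_instances(p, rep_enr$cutoff[i], chip, genome)
  }
  instances <- if (length(inst)) do.call(rbind, inst) else
    call_instances(pssm_prepare(pssms[[1]]), 2, chip[0, , drop = FALSE], genome)
  list(enrichment = enr, instances = instances, chip_regions = chip,
       chip_seqs = chip_seqs, bg_seqs = bg_seqs, genome = genome)
}

# ---- stage: region statistics ------------------------------------------

#' Stage 3: overlap, co-occurrence, CpG-island and TSS-profile statistics
#'
#' @param cfg a [pipeline_config()]
#' @param promoters result of [stage_call_promoters()]
#' @param motifs result of [stage_enrich_motifs()]
#' @return list with `overlap` ([permutation_overlap_test()] result),
#'   `cooccurrence`, `cpg` (islands + promoter overlap count), `profile`
#' @export
stage_region_stats <- function(cfg, promoters, motifs) {
  acc <- promoters$calls[promoters$calls$accepted, , drop = FALSE]
  chip <- motifs$chip_regions
  genome <- motifs$genome
  eligible <- genomic_intervals(names(genome), 0, nchar(genome), "*")
  overlap <- NULL
  if (nrow(acc)) {
    query <- genomic_intervals(acc$chrom, acc$region_start, acc$region_end, "*")
    overlap <- permutation_overlap_test(
      query, chip, eligible, n_perm = cfg$n_perm,
      seed = derive_seed(cfg$seed, "overlap_perm"))
  }

  # co-occurrence of the assay factor with its top cofactor inside
  # promoter-overlapping ChIP regions
  cooc <- NULL
  inst <- motifs$instances
  if (nrow(acc) && nrow(inst)) {
    ov_regions <- unique(unlist(lapply(seq_len(nrow(acc)), function(i) {
      which(chip$chrom == acc$chrom[i] & chip$start < acc$region_end[i] &
              chip$end > acc$region_start[i])
    })))
    tf_regions <- intersect(ov_regions,
                            inst$region_idx[inst$tf == cfg$tf_name])
    others <- setdiff(unique(inst$tf), cfg$tf_name)
    if (length(tf_regions) && length(others)) {
      cof <- others[1]
      k <- length(intersect(tf_regions, inst$region_idx[inst$tf == cof]))
      # per-window null probability: cofactor hit rate in background
      # promoter windows of the same width as the ChIP regions
      cof_rows <- motifs$enrichment$report
      cof_cut <- suppressWarnings(
        min(cof_rows$cutoff[cof_rows$tf == cof & cof_rows$enriched],
            na.rm = TRUE))
      if (!is.finite(cof_cut)) cof_cut <- NA_real_
      p_hit <- .window_hit_probability(motifs, cof, cof_cut,
                                       mean(gi_width(chip)))
      cooc <- list(tf = cfg$tf_name, cofactor = cof, n = length(tf_regions),
                   k = k, p_hat = p_hit,
                   p_value = if (p_hit > 0 && p_hit < 1)
                     binomial_cooccurrence_test(length(tf_regions), k, p_hit)
                   else NA_real_)
    }
  }

  islands <- do.call(rbind, lapply(names(genome), function(ch) {
    cpg_islands(genome[[ch]], chrom = ch)
  }))
  if (!is.null(islands)) class(islands) <- c("genomic_intervals", "data.frame")
  n_cpg_overlap <- if (nrow(acc) && !is.null(islands) && nrow(islands)) {
    overlap_count(genomic_intervals(acc$chrom, acc$region_start,
                                    acc$region_end, "*"), islands)
  } else 0L

  ann <- read_gff3(cfg$annotations)
  genes <- ann[ann$kind == "coding", , drop = FALSE]
  tf_sites <- inst[inst$tf == cfg$tf_name, , drop = FALSE]
  profile <- if (nrow(tf_sites)) {
    profile_around_tss(genes[, c("id", "chrom", "tss", "strand")],
                       sites = genomic_intervals(tf_sites$chrom,
                                                 tf_sites$start,
                                                 tf_sites$end, "*"))
  } else NULL
  list(overlap = overlap, cooccurrence = cooc,
       cpg = list(islands = islands, n_promoter_overlap = n_cpg_overlap,
                  n_promoters = nrow(acc)),
       profile = profile)
}

# fraction of background promoter windows (trimmed to `width` bp) carrying
# at least one cofactor hit at its selected cutoff
.window_hit_probability <- function(motifs, tf, cutoff, width) {
  if (is.na(cutoff)) return(NA_real_)
  rep_df <- motifs$enrichment$report
  ids <- rep_df$pssm_id[rep_df$tf == tf & rep_df$enriched]
  bg <- motifs$bg_seqs
  if (!length(bg) || !length(ids)) return(NA_real_)
  bgf <- base_frequencies(bg)
  bg_trim <- substr(bg, 1, pmin(nchar(bg), max(width, 50)))
  curves <- motifs$enrichment$curves
  hit <- rep(FALSE, length(bg_trim))
  for (id in ids) {
    p <- NULL
    # rebuild the matrix from the stored curve attribute is not possible;
    # rescan with the library entry
    p <- attr(curves[[id]], "pssm")
    if (is.null(p)) next
    for (s in seq_along(bg_trim)) {
      if (hit[s]) next
      sc <- c(.window_scores(p, bg_trim[s]),
              .window_scores(p, revcomp(bg_trim[s])))
      if (length(sc) && max(sc) >= cutoff) hit[s] <- TRUE
    }
  }
  mean(hit)
}

# ---- stage: targets and network ----------------------------------------

#' Stage 4: seed-match target table
#' @param cfg a [pipeline_config()]
#' @return the [target_table()] data frame
#' @export
stage_find_targets <- function(cfg) {
  matures <- read_fasta(cfg$matures)
  utrs <- read_fasta(cfg$utrs)
  target_table(matures, utrs)
}

#' Stage 5: regulatory edges and network motifs
#' @param cfg a [pipeline_config()]
#' @param promoters result of [stage_call_promoters()]
#' @param motifs result of [stage_enrich_motifs()]
#' @param targets result of [stage_find_targets()]
#' @return list with `edges`, `feedback`, `feedforward`
#' @export
stage_build_network <- function(cfg, promoters, motifs, targets) {
  acc <- promoters$calls[promoters$calls$accepted, , drop = FALSE]
  prom <- data.frame(mirna_id = acc$mirna_id, chrom = acc$chrom,
                     region_start = acc$region_start,
                     region_end = acc$region_end, stringsAsFactors = FALSE)
  ann <- read_gff3(cfg$annotations)
  genes <- ann[ann$kind == "coding", , drop = FALSE]
  tf_mirna <- tf_to_mirna_edges(prom, motifs$chip_regions, motifs$instances)
  tf_gene <- tf_to_gene_edges(genes, motifs$chip_regions, cfg$tf_name,
                              cfg$ff_window)
  m2g <- mirna_to_gene_edges(targets)
  fb <- find_feedback(tf_mirna, targets, cfg$focal_genes)
  ff <- find_feedforward(tf_gene, tf_mirna, targets)
  edges <- rbind(tf_mirna, tf_gene, m2g)
  list(edges = edges, feedback = fb, feedforward = ff)
}

# ---- run-all ------------------------------------------------------------

#' Run the full pipeline
#'
#' Executes the stages in order (promoters -> enrichment -> statistics ->
#' targets -> network); any stage failure aborts with the stage name.
#' Every output table under `out_dir` is stamped with the config digest
#' and master seed, so a rerun with the same config is byte-identical.
#'
#' @param cfg a [pipeline_config()]
#' @return invisibly, a list with every stage result
#' @export
run_all <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  promoters <- st("call-promoters", stage_call_promoters(cfg))
  write_result_tsv(promoters$calls,
                   file.path(cfg$out_dir, "promoter_calls.tsv"), cfg)
  acc <- promoters$calls[promoters$calls$accepted, , drop = FALSE]
  if (nrow(acc)) {
    write_bed(genomic_intervals(acc$chrom, acc$region_start, acc$region_end,
                                acc$strand, name = acc$mirna_id),
              file.path(cfg$out_dir, "promoter_regions.bed"),
              score = pmin(1000, pmax(0, acc$score)))
  }
  write_result_tsv(promoters$gene_scores,
                   file.path(cfg$out_dir, "gene_scores.tsv"), cfg)
  roc_df <- data.frame(set = c("all", names(promoters$roc$auc_by_tier)),
                       auc = c(promoters$roc$auc, promoters$roc$auc_by_tier))
  write_result_tsv(roc_df, file.path(cfg$out_dir, "roc_auc.tsv"), cfg)

  motifs <- st("enrich-motifs", stage_enrich_motifs(cfg))
  write_result_tsv(motifs$enrichment$report,
                   file.path(cfg$out_dir, "enrichment.tsv"), cfg)
  if (nrow(motifs$instances)) {
    write_bed(genomic_intervals(motifs$instances$chrom,
                                motifs$instances$start,
                                motifs$instances$end,
                                motifs$instances$strand,
                                name = motifs$instances$pssm_id),
              file.path(cfg$out_dir, "instances.bed"),
              score = motifs$instances$score * 1000)
  }
  write_result_tsv(motifs$instances,
                   file.path(cfg$out_dir, "instances.tsv"), cfg)

  stats_res <- st("region-stats", stage_region_stats(cfg, promoters, motifs))
  ostats <- data.frame(
    metric = c("n_promoters", "n_overlapping_chip", "overlap_p_hat",
               "overlap_p_value", "n_cpg_overlap",
               "cooccurrence_n", "cooccurrence_k", "cooccurrence_p"),
    value = c(nrow(acc),
              stats_res$overlap$n_overlapping %||% NA,
              stats_res$overlap$p_hat %||% NA,
              stats_res$overlap$p_value %||% NA,
              stats_res$cpg$n_promoter_overlap,
              stats_res$cooccurrence$n %||% NA,
              stats_res$cooccurrence$k %||% NA,
              stats_res$cooccurrence$p_value %||% NA))
  write_result_tsv(ostats, file.path(cfg$out_dir, "overlap_stats.tsv"), cfg)
  if (!is.null(stats_res$cpg$islands) && nrow(stats_res$cpg$islands)) {
    write_bed(stats_res$cpg$islands,
              file.path(cfg$out_dir, "cpg_islands.bed"))
  }
  if (!is.null(stats_res$profile)) {
    write_result_tsv(stats_res$profile,
                     file.path(cfg$out_dir, "tss_profile.tsv"), cfg)
  }

  targets <- st("find-targets", stage_find_targets(cfg))
  write_result_tsv(targets, file.path(cfg$out_dir, "target_table.tsv"), cfg)

  network <- st("build-network", stage_build_network(cfg, promoters, motifs,
                                                     targets))
  write_result_tsv(network$edges, file.path(cfg$out_dir, "edges.tsv"), cfg)
  write_result_tsv(network$feedback,
                   file.path(cfg$out_dir, "feedback_motifs.tsv"), cfg)
  write_result_tsv(network$feedforward,
                   file.path(cfg$out_dir, "feedforward_motifs.tsv"), cfg)
  ff_sum <- attr(network$feedforward, "summary")
  write_result_tsv(ff_sum, file.path(cfg$out_dir, "feedforward_summary.tsv"),
                   cfg)
  export_graphml(network$edges, file.path(cfg$out_dir, "network.graphml"))

  message(sprintf(
    "mipronet run complete: %d promoter calls, %d enriched PSSMs, %d feedback and %d feed-forward motifs",
    nrow(acc), sum(motifs$enrichment$report$enriched),
    nrow(network$feedback), nrow(network$feedforward)))
  invisible(list(promoters = promoters, motifs = motifs, stats = stats_res,
                 targets = targets, network = network))
}
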