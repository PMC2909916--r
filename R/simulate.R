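# Synthetic-data generator with planted ground truth.
#
# Emulates every input the pipeline consumes: a genome of non-overlapping
# coding genes (neighbouring TSSs >= 10 kb apart) and intergenic miRNAs;
# Poisson RPol II coverage with the TSS shape profile at expressed-gene and
# active-miRNA promoters over three expression tiers; ChIP-enriched regions
# enclosing planted PSSM instances at a controlled ChIP/background density
# ratio; background promoter sequence; and 3'UTRs with planted seed sites.
# All randomness flows from the single config seed through fixed per-stage
# derived seeds, so identical seeds give byte-identical outputs.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: a 60/40
#' expressed/unexpressed split with three equal expressed tiers whose peak
#' and transcript increments scale 1x/2x/4x over the low tier; lognormal
#' within-tier signal jitter; active miRNA promoters drawn from the high
#' tier with mild jitter at TSS-to-pre-miRNA distances lognormal around
#' 3,600 bp truncated to 200..10,000 bp; ChIP regions carrying planted
#' motif instances at 5x the background per-bp rate.
#'
#' @param seed master integer seed
#' @param n_chrom,chrom_length number and length (bp) of chromosomes
#' @param bin_width coverage bin width in bp
#' @param n_coding_genes,n_mirnas feature counts
#' @param tier_fractions named fractions (unexpressed/low/medium/high)
#'   summing to 1
#' @param base_shape [shape_params()] of the low tier
#' @param tier_multipliers multipliers applied to the (h_p - h_b) and
#'   (h_t - h_b) increments per tier
#' @param gene_jitter_sdlog lognormal sd of per-gene signal scale
#' @param mirna_active_fraction fraction of miRNAs with an active promoter
#' @param mirna_tier,mirna_jitter_sdlog tier and jitter for active miRNAs
#' @param tss_distance_meanlog,tss_distance_sdlog,tss_distance_range
#'   lognormal distance (bp) of the miRNA TSS upstream of the pre-miRNA
#' @param gene_length_range transcript length range (bp)
#' @param min_tss_spacing minimum spacing between neighbouring feature
#'   footprints (bp)
#' @param mirna_upstream_reserve upstream space reserved per miRNA (bp)
#' @param pre_mirna_length pre-miRNA hairpin length (bp)
#' @param chip_region_length ChIP-enriched region length (bp)
#' @param n_random_chip_regions extra ChIP regions at random intergenic
#'   positions
#' @param chip_gene_fraction fraction of expressed genes designated
#'   TF-bound (ChIP region at their TSS)
#' @param density_ratio ChIP/background planted-instance density ratio
#' @param bg_motif_rate background planting rate (instances per kb)
#' @param cofactor_fraction fraction of active-miRNA ChIP regions also
#'   carrying a planted cofactor (AP-1) site
#' @param cebp_fraction fraction of cofactor regions also carrying a C/EBP
#'   site
#' @param utr_length_range 3'UTR length range (bp)
#' @param focal_utr_ids focal genes carried as UTR-only nodes
#' @param feedback_fraction fraction of active miRNAs targeting a focal
#'   gene
#' @param targets_per_mirna range of feed-forward targets per active miRNA
#' @param cpg_island_fraction fraction of active miRNA promoters with a
#'   planted CpG island
#' @param emit_sequences generate chromosome sequences (needed for motif /
#'   CpG stages; coverage-only studies can skip them)
#' @return a validated `simulation_config` list
#' @export
simulation_config <- function(
    seed = 1,
    n_chrom = 2,
    chrom_length = 2.6e6,
    bin_width = 50,
    n_coding_genes = 60,
    n_mirnas = 40,
    tier_fractions = c(unexpressed = 0.4, low = 0.2, medium = 0.2, high = 0.2),
    base_shape = shape_params(h_p = 0.3, h_b = 0.1, h_t = 0.12,
                              lambda_p = 0.01, lambda_t = 0.002),
    tier_multipliers = c(low = 1, medium = 2, high = 4),
    gene_jitter_sdlog = 1.5,
    mirna_active_fraction = 0.5,
    mirna_tier = "high",
    mirna_jitter_sdlog = 0.25,
    tss_distance_meanlog = log(3600),
    tss_distance_sdlog = 1,
    tss_distance_range = c(200, 10000),
    gene_length_range = c(12000, 20000),
    min_tss_spacing = 35000,
    mirna_upstream_reserve = 10000,
    pre_mirna_length = 80,
    chip_region_length = 500,
    n_random_chip_regions = 20,
    chip_gene_fraction = 0.4,
    density_ratio = 5,
    bg_motif_rate = 1,
    cofactor_fraction = 0.5,
    cebp_fraction = 0.2,
    utr_length_range = c(600, 1500),
    focal_utr_ids = c("IFNG", "STAT1", "JUN", "FOS"),
    feedback_fraction = 0.4,
    targets_per_mirna = c(1, 3),
    cpg_island_fraction = 0.7,
    emit_sequences = TRUE) {
  cfg <- as.list(environment())
  if (abs(sum(tier_fractions) - 1) > 1e-8) stop("tier_fractions must sum to 1")
  if (!all(c("unexpressed", "low", "medium", "high") %in% names(tier_fractions))) {
    stop("tier_fractions must name unexpressed, low, medium, high")
  }
  if (density_ratio <= 0) stop("density_ratio must be > 0")
  if (any(c(n_chrom, chrom_length, bin_width, pre_mirna_length,
            chip_region_length, mirna_upstream_reserve) <= 0)) {
    stop("all lengths must be positive")
  }
  if (n_coding_genes < 0 || n_mirnas < 0) stop("feature counts must be >= 0")
  if (!mirna_tier %in% names(tier_multipliers)) stop("unknown mirna_tier")
  stopifnot(inherits(base_shape, "shape_params"))
  class(cfg) <- c("simulation_config", "list")
  cfg
}

# tier-level shape parameters: increments over background scale with the
# tier multiplier and optionally a per-feature signal scale
tier_shape <- function(config, tier, scale = 1) {
  b <- config$base_shape
  m <- config$tier_multipliers[[tier]] * scale
  shape_params(h_p = b$h_b + (b$h_p - b$h_b) * m,
               h_b = b$h_b,
               h_t = b$h_b + (b$h_t - b$h_b) * m,
               lambda_p = b$lambda_p, lambda_t = b$lambda_t)
}

#' Simulate genome annotations and sequences
#'
#' Places non-overlapping coding genes (neighbouring TSSs at least
#' `min_tss_spacing` apart) and intergenic miRNAs with a reserved upstream
#' promoter space; assigns expression tiers, per-feature signal scales,
#' active-miRNA TSSs, and random mature sequences; generates uniform
#' background chromosome sequences with CpG-island segments planted at a
#' fraction of active miRNA promoters.
#'
#' @param config a [simulation_config()]
#' @return list with `genes`, `mirnas` (annotation data frames),
#'   `sequences` (named chromosome sequences or `NULL`), `cpg_truth`
#'   ([genomic_intervals()] of planted islands) and `config`
#' @export
simulate_genome <- function(config) {
  with_seed(derive_seed(config$seed, "genome"), {
    n_feat <- config$n_coding_genes + config$n_mirnas
    kind <- sample(rep(c("gene", "mirna"),
                       c(config$n_coding_genes, config$n_mirnas)))
    chroms <- paste0("chr", seq_len(config$n_chrom))
    assign_chrom <- if (n_feat) rep_len(chroms, n_feat)[sample.int(n_feat)] else character()
    margin <- 15000
    cursor <- stats::setNames(rep(margin, config$n_chrom), chroms)
    genes <- list(); mirnas <- list()
    for (i in seq_len(n_feat)) {
      ch <- assign_chrom[i]
      strand <- sample(c("+", "-"), 1)
      if (kind[i] == "gene") {
        len <- round(stats::runif(1, config$gene_length_range[1],
                                  config$gene_length_range[2]))
        s <- cursor[[ch]]; e <- s + len
        if (e + margin > config$chrom_length) {
          stop("genome too small to place requested features")
        }
        genes[[length(genes) + 1L]] <- data.frame(
          id = sprintf("gene_%03d", length(genes) + 1L), chrom = ch,
          start = s, end = e, strand = strand,
          tss = if (strand == "-") e - 1 else s, stringsAsFactors = FALSE)
        cursor[[ch]] <- e + config$min_tss_spacing
      } else {
        slot <- config$mirna_upstream_reserve + config$pre_mirna_length
        s <- cursor[[ch]]; e <- s + slot
        if (e + margin > config$chrom_length) {
          stop("genome too small to place requested features")
        }
        if (strand == "-") {
          ps <- s; pe <- s + config$pre_mirna_length
        } else {
          ps <- e - config$pre_mirna_length; pe <- e
        }
        mirnas[[length(mirnas) + 1L]] <- data.frame(
          id = sprintf("mir_%03d", length(mirnas) + 1L), chrom = ch,
          start = ps, end = pe, strand = strand, stringsAsFactors = FALSE)
        cursor[[ch]] <- e + config$min_tss_spacing
      }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(), tss = numeric(),
                 stringsAsFactors = FALSE)
    mirnas <- if (length(mirnas)) do.call(rbind, mirnas) else
      data.frame(id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(), stringsAsFactors = FALSE)

    # expression tiers with exact counts by fraction
    if (nrow(genes)) {
      fr <- config$tier_fractions
      n_by <- floor(fr * nrow(genes))
      rem <- nrow(genes) - sum(n_by)
      if (rem > 0) {
        top <- order(fr * nrow(genes) - n_by, decreasing = TRUE)
        n_by[top[seq_len(rem)]] <- n_by[top[seq_len(rem)]] + 1
      }
      genes$tier <- sample(rep(names(fr), n_by))
      expressed <- genes$tier != "unexpressed"
      genes$signal_scale <- NA_real_
      genes$signal_scale[expressed] <-
        stats::rlnorm(sum(expressed), 0, config$gene_jitter_sdlog)
      genes$length <- genes$end - genes$start
    } else {
      genes$tier <- character(); genes$signal_scale <- numeric()
      genes$length <- numeric()
    }

    # active miRNAs: TSS planted upstream of the pre-miRNA 5' end
    if (nrow(mirnas)) {
      n_active <- round(config$mirna_active_fraction * nrow(mirnas))
      active_idx <- sort(sample.int(nrow(mirnas), n_active))
      mirnas$active <- seq_len(nrow(mirnas)) %in% active_idx
      d <- pmin(pmax(round(stats::rlnorm(nrow(mirnas),
                                         config$tss_distance_meanlog,
                                         config$tss_distance_sdlog)),
                     config$tss_distance_range[1]),
                min(config$tss_distance_range[2], config$mirna_upstream_reserve))
      mirnas$distance <- ifelse(mirnas$active, d, NA_real_)
      five_prime <- ifelse(mirnas$strand == "-", mirnas$end - 1, mirnas$start)
      mirnas$tss <- ifelse(mirnas$active,
                           ifelse(mirnas$strand == "-", five_prime + d,
                                  five_prime - d), NA_real_)
      mirnas$signal_scale <- ifelse(mirnas$active,
                                    stats::rlnorm(nrow(mirnas), 0,
                                                  config$mirna_jitter_sdlog),
                                    NA_real_)
      mirnas$mature <- .random_matures(nrow(mirnas))
    } else {
      mirnas$active <- logical(); mirnas$distance <- numeric()
      mirnas$tss <- numeric(); mirnas$signal_scale <- numeric()
      mirnas$mature <- character()
    }

    sequences <- NULL
    cpg_truth <- genomic_intervals()
    if (config$emit_sequences) {
      sequences <- stats::setNames(
        vapply(chroms, function(ch) rand_dna(config$chrom_length), ""),
        chroms)
      act <- mirnas[mirnas$active %in% TRUE, , drop = FALSE]
      if (nrow(act)) {
        n_cpg <- round(config$cpg_island_fraction * nrow(act))
        pick <- sort(sample.int(nrow(act), n_cpg))
        isl <- list()
        for (j in pick) {
          s <- max(0, round(act$tss[j]) - 200)
          seg <- .gen_cpg_segment(400)
          substr(sequences[[act$chrom[j]]], s + 1, s + 400) <- seg
          isl[[length(isl) + 1L]] <- data.frame(chrom = act$chrom[j],
                                                start = s, end = s + 400)
        }
        if (length(isl)) {
          m <- do.call(rbind, isl)
          cpg_truth <- genomic_intervals(m$chrom, m$start, m$end, "*")
        }
      }
    }
    list(genes = genes, mirnas = mirnas, sequences = sequences,
         cpg_truth = cpg_truth, config = config)
  })
}

# random 22-nt mature miRNA sequences whose seed-derived site patterns are
# pairwise non-nested: no miRNA's 7-mer pattern occurs inside another's
# planted site string, so planting one miRNA's site can never create a
# second miRNA's site at the same locus
.random_matures <- function(n) {
  out <- character(n)
  pats <- list()
  collides <- function(a, b) {
    any(vapply(c(b$seed78, b$p7a), function(q) {
      grepl(q, a$p8, fixed = TRUE) || grepl(q, a$seed78, fixed = TRUE) ||
        grepl(q, a$p7a, fixed = TRUE)
    }, logical(1)))
  }
  for (i in seq_len(n)) {
    for (try in 1:200) {
      m <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                 collapse = "")
      cand <- .seed_patterns(m)
      ok <- !any(vapply(pats, function(q) {
        collides(cand, q) || collides(q, cand)
      }, logical(1)))
      if (ok) break
    }
    pats[[i]] <- cand
    out[i] <- m
  }
  out
}

# GC-rich (60%) segment with CpG obs/exp lowered toward 0.8 by CG -> GC
# swaps (composition-preserving)
.gen_cpg_segment <- function(len) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c(0.2, 0.3, 0.3, 0.2))
  oe <- function(x) {
    ncpg <- sum(x[-length(x)] == "C" & x[-1] == "G")
    nc <- sum(x == "C"); ng <- sum(x == "G")
    if (nc * ng == 0) 0 else ncpg * length(x) / (nc * ng)
  }
  for (it in 1:200) {
    if (oe(chars) <= 0.8) break
    pos <- which(chars[-len] == "C" & chars[-1] == "G")
    if (!length(pos)) break
    p <- sample(pos, 1)
    chars[c(p, p + 1)] <- c("G", "C")
  }
  paste(chars, collapse = "")
}

#' Simulate binned TSS-aligned count windows from the shape model
#'
#' Draws Poisson counts with mean `bin_width * mu(x)` at the bin-centre
#' offsets of `window`; optional per-window lognormal scaling of the
#' above-background increments emulates within-tier expression spread.
#'
#' @param params [shape_params()]
#' @param n number of windows
#' @param window strand-oriented window `c(upstream, downstream)` in bp
#' @param bin_width bin width in bp
#' @param jitter_sdlog lognormal sd of the per-window signal scale (0 = none)
#' @param background_only draw from the constant-background model instead
#' @param seed optional integer seed
#' @return integer matrix (`n` x bins)
#' @export
simulate_tss_windows <- function(params, n, window = c(-3000, 10000),
                                 bin_width = 50, jitter_sdlog = 0,
                                 background_only = FALSE, seed = NULL) {
  with_seed(seed, {
    offs <- window_offsets(window, bin_width)
    if (background_only) {
      lam <- matrix(params$h_b * bin_width, n, length(offs))
    } else {
      mu <- expected_profile(params, offs)
      s <- if (jitter_sdlog > 0) stats::rlnorm(n, 0, jitter_sdlog) else rep(1, n)
      lam <- bin_width * (params$h_b + outer(s, mu - params$h_b))
    }
    matrix(stats::rpois(length(lam), lam), nrow = n)
  })
}

#' Simulate the RPol II coverage track
#'
#' Bin counts are Poisson with mean `bin_width * mu(x)` where `mu` is the
#' TSS shape profile centred at each active TSS (expressed genes over their
#' transcript span, active miRNAs over the pri-miRNA span) on top of the
#' constant background `h_b`; contributions from overlapping features sum.
#' Unexpressed genes and inactive miRNAs contribute background only.
#'
#' @param annotations list from [simulate_genome()]
#' @param config the [simulation_config()]
#' @return a [coverage_track()]
#' @export
simulate_rpol2_coverage <- function(annotations, config) {
  with_seed(derive_seed(config$seed, "coverage"), {
    bw <- config$bin_width
    nb <- as.integer(ceiling(config$chrom_length / bw))
    chroms <- paste0("chr", seq_len(config$n_chrom))
    lam <- stats::setNames(lapply(chroms, function(ch) {
      rep(config$base_shape$h_b * bw, nb)
    }), chroms)
    add_feature <- function(ch, tss, strand, params, down_limit) {
      sgn <- if (strand == "-") -1 else 1
      lo <- tss + sgn * -3000; hi <- tss + sgn * down_limit
      b0 <- max(1L, floor(min(lo, hi) / bw) + 1L)
      b1 <- min(nb, floor(max(lo, hi) / bw) + 1L)
      if (b1 < b0) return(invisible())
      centers <- ((b0:b1) - 0.5) * bw
      x <- sgn * (centers - tss)
      keep <- x >= -3000 & x <= down_limit
      if (!any(keep)) return(invisible())
      mu <- expected_profile(params, x[keep])
      lam[[ch]][(b0:b1)[keep]] <<- lam[[ch]][(b0:b1)[keep]] +
        bw * (mu - params$h_b)
    }
    g <- annotations$genes
    for (i in seq_len(nrow(g))) {
      if (g$tier[i] == "unexpressed") next
      p <- tier_shape(config, g$tier[i], g$signal_scale[i])
      add_feature(g$chrom[i], g$tss[i], g$strand[i], p, g$length[i])
    }
    m <- annotations$mirnas
    for (i in seq_len(nrow(m))) {
      if (!isTRUE(m$active[i])) next
      p <- tier_shape(config, config$mirna_tier, m$signal_scale[i])
      add_feature(m$chrom[i], m$tss[i], m$strand[i], p,
                  m$distance[i] + config$pre_mirna_length)
    }
    counts <- lapply(lam, function(v) stats::rpois(length(v), v))
    coverage_track(counts, bw)
  })
}

#' Built-in synthetic PSSM library
#'
#' Small fixed library used by the generator: two STAT1-like matrices (GAS
#' element), an AP-1-like TRE matrix, a C/EBP-like matrix and two decoys.
#' All matrices are synthetic constructions, not TRANSFAC entries.
#'
#' @return list of [pssm()] objects
#' @export
synthetic_pssm_library <- function() {
  from_consensus <- function(id, tf, cons, degenerate = integer()) {
    b <- strsplit(cons, "")[[1]]
    m <- matrix(1, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(b)) m[b[j], j] <- 17
    for (j in degenerate) m[, j] <- 5
    pssm(id, tf, m)
  }
  list(
    from_consensus("STAT1_01", "STAT1", "TTCCGGGAA"),
    from_consensus("STAT1_02", "STAT1", "TTCCGGGAA", degenerate = 5L),
    from_consensus("AP1_01", "AP1", "TGACTCA"),
    from_consensus("CEBP_01", "CEBP", "TTGCGCAA"),
    from_consensus("DECOY_01", "DECOY1", "CATGGTAC"),
    from_consensus("DECOY_02", "DECOY2", "GTCTAGAC")
  )
}

#' Plant ChIP-enriched regions and motif instances
#'
#' Places ChIP regions over every active miRNA promoter, over a designated
#' subset of expressed-gene promoters, and at random intergenic positions;
#' writes PSSM instances into the sequences so that the planted matrices
#' reach `density_ratio` times the background per-bp rate inside ChIP
#' regions. Loop-anchoring instances (the assayed factor in every promoter
#' region, the cofactor in a designated subset) are consensus sites; bulk
#' density instances are sampled from the PSSM column distributions.
#' Ground-truth instance positions are recorded.
#'
#' @param annotations list from [simulate_genome()] (sequences required)
#' @param config the [simulation_config()]
#' @param pssm_library PSSM list (default [synthetic_pssm_library()])
#' @return list with `chip_regions` (with `name` and `type` columns),
#'   `sequences` (mutated), `instances` (ground-truth data frame),
#'   `tf_bound_genes`, `cofactor_mirnas`
#' @export
plant_chip_regions <- function(annotations, config,
                               pssm_library = synthetic_pssm_library()) {
  if (is.null(annotations$sequences)) {
    stop("plant_chip_regions needs sequences (emit_sequences = TRUE)")
  }
  with_seed(derive_seed(config$seed, "chip"), {
    seqs <- annotations$sequences
    seqv <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    genes <- annotations$genes
    mir <- annotations$mirnas
    L_reg <- config$chip_region_length
    half <- floor(L_reg / 2)
    regions <- list()
    add_region <- function(ch, center, type, anchor) {
      s <- max(0, round(center) - half)
      regions[[length(regions) + 1L]] <<- data.frame(
        chrom = ch, start = s, end = s + L_reg, type = type,
        anchor = anchor, stringsAsFactors = FALSE)
    }
    act <- mir[mir$active %in% TRUE, , drop = FALSE]
    for (i in seq_len(nrow(act))) {
      add_region(act$chrom[i], act$tss[i], "mirna_promoter", act$id[i])
    }
    expressed <- genes[genes$tier != "unexpressed", , drop = FALSE]
    n_bound <- round(config$chip_gene_fraction * nrow(expressed))
    bound_idx <- if (n_bound) sort(sample.int(nrow(expressed), n_bound)) else integer()
    tf_bound_genes <- expressed$id[bound_idx]
    for (i in bound_idx) {
      add_region(expressed$chrom[i], expressed$tss[i], "gene_promoter",
                 expressed$id[i])
    }
    # random intergenic regions: keep clear of feature footprints
    occupied <- rbind(
      if (nrow(genes)) data.frame(chrom = genes$chrom,
                                  start = genes$start - 12000,
                                  end = genes$end + 2000),
      if (nrow(mir)) data.frame(chrom = mir$chrom,
                                start = mir$start - 12000,
                                end = mir$end + 12000))
    chroms <- names(seqs)
    placed <- 0L
    tries <- 0L
    while (placed < config$n_random_chip_regions && tries < 10000L) {
      tries <- tries + 1L
      ch <- sample(chroms, 1)
      s <- floor(stats::runif(1, 2000, nchar(seqs[[ch]]) - L_reg - 2000))
      clash <- !is.null(occupied) && any(occupied$chrom == ch &
                                           occupied$start < s + L_reg &
                                           occupied$end > s)
      prev <- length(regions) && any(vapply(regions, function(r) {
        r$chrom == ch && r$start < s + L_reg && r$end > s
      }, logical(1)))
      if (clash || prev) next
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + L_reg, type = "random",
        anchor = NA_character_, stringsAsFactors = FALSE)
      placed <- placed + 1L
    }
    reg <- do.call(rbind, regions)
    lib <- stats::setNames(pssm_library,
                           vapply(pssm_library, `[[`, "", "id"))

    instances <- list()
    placed_sites <- list()  # per chrom: matrix of [start, end) to avoid overlap
    can_place <- function(ch, s, e) {
      m <- placed_sites[[ch]]
      is.null(m) || !any(m[, 1] < e & m[, 2] > s)
    }
    note_site <- function(ch, s, e) {
      placed_sites[[ch]] <<- rbind(placed_sites[[ch]], c(s, e))
    }
    write_site <- function(p, ch, pos0, site = NULL, where, region_idx) {
      L <- ncol(p$counts)
      if (is.null(site)) site <- sample_pssm_site(p)
      strand <- sample(c("+", "-"), 1)
      written <- if (strand == "-") revcomp(site) else site
      seqv[[ch]][(pos0 + 1):(pos0 + L)] <<- strsplit(written, "",
                                                     fixed = TRUE)[[1]]
      note_site(ch, pos0, pos0 + L)
      instances[[length(instances) + 1L]] <<- data.frame(
        pssm_id = p$id, tf = p$tf_name, chrom = ch, start = pos0,
        end = pos0 + L, strand = strand, where = where,
        region_idx = region_idx, site = site, stringsAsFactors = FALSE)
    }
    consensus_at_center <- function(p, region_idx) {
      r <- reg[region_idx, ]
      L <- ncol(p$counts)
      if (r$end - r$start < L) {
        warning(sprintf("ChIP region %d shorter than motif %s: skipped",
                        region_idx, p$id))
        return(invisible())
      }
      pos0 <- r$start + floor((r$end - r$start - L) / 2)
      for (sh in c(0, -L, L, -2 * L, 2 * L)) {     # dodge earlier plants
        if (can_place(r$chrom, pos0 + sh, pos0 + sh + L) &&
            pos0 + sh >= r$start && pos0 + sh + L <= r$end) {
          write_site(p, r$chrom, pos0 + sh, pssm_consensus(p), "chip",
                     region_idx)
          return(invisible())
        }
      }
    }
    mirna_region_idx <- which(reg$type == "mirna_promoter")
    gene_region_idx <- which(reg$type == "gene_promoter")
    if ("STAT1_01" %in% names(lib)) {
      for (i in c(mirna_region_idx, gene_region_idx)) {
        consensus_at_center(lib[["STAT1_01"]], i)
      }
    }
    cofactor_mirnas <- character(0)
    if ("AP1_01" %in% names(lib) && length(mirna_region_idx)) {
      n_cof <- round(config$cofactor_fraction * length(mirna_region_idx))
      cof <- sort(sample(mirna_region_idx, n_cof))
      cofactor_mirnas <- reg$anchor[cof]
      for (i in cof) consensus_at_center(lib[["AP1_01"]], i)
      if ("CEBP_01" %in% names(lib) && length(cof)) {
        n_ceb <- round(config$cebp_fraction * length(cof))
        for (i in utils::head(cof, n_ceb)) consensus_at_center(lib[["CEBP_01"]], i)
      }
    }

    # rate planting: chip at density_ratio x the background per-bp rate
    chip_kb <- sum(reg$end - reg$start) / 1000
    bg_prom <- genes[!genes$id %in% tf_bound_genes, , drop = FALSE]
    bg_windows <- if (nrow(bg_prom)) data.frame(
      chrom = bg_prom$chrom,
      start = ifelse(bg_prom$strand == "-", bg_prom$tss + 1,
                     bg_prom$tss - 1000),
      end = ifelse(bg_prom$strand == "-", bg_prom$tss + 1001,
                   bg_prom$tss + 1)) else
      data.frame(chrom = character(), start = numeric(), end = numeric())
    bg_windows$start <- pmax(bg_windows$start, 0)
    bg_kb <- sum(bg_windows$end - bg_windows$start) / 1000
    planted_ids <- intersect(c("STAT1_01", "AP1_01"), names(lib))
    plant_at_rate <- function(p, windows, rate_kb, where) {
      if (!nrow(windows) || rate_kb <= 0) return(invisible())
      L <- ncol(p$counts)
      w <- windows$end - windows$start
      n <- stats::rpois(1, rate_kb * sum(w) / 1000)
      for (k in seq_len(n)) {
        for (try in 1:50) {
          i <- sample.int(nrow(windows), 1, prob = w)
          if (w[i] < L) next
          pos0 <- windows$start[i] +
            floor(stats::runif(1) * (w[i] - L + 1))
          if (can_place(windows$chrom[i], pos0, pos0 + L)) {
            write_site(p, windows$chrom[i], pos0, NULL, where,
                       if (where == "chip") i else NA_integer_)
            break
          }
        }
      }
    }
    for (id in planted_ids) {
      plant_at_rate(lib[[id]], reg[, c("chrom", "start", "end")],
                    config$density_ratio * config$bg_motif_rate, "chip")
      plant_at_rate(lib[[id]], bg_windows, config$bg_motif_rate, "background")
    }
    inst <- if (length(instances)) do.call(rbind, instances) else
      data.frame(pssm_id = character(), tf = character(), chrom = character(),
                 start = numeric(), end = numeric(), strand = character(),
                 where = character(), region_idx = integer(),
                 site = character(), stringsAsFactors = FALSE)
    chip_gi <- genomic_intervals(reg$chrom, reg$start, reg$end, "*",
                                 name = sprintf("chip_%03d", seq_len(nrow(reg))))
    chip_gi$type <- reg$type
    chip_gi$anchor <- reg$anchor
    seqs <- vapply(seqv, paste, "", collapse = "")
    list(chip_regions = chip_gi, sequences = seqs, instances = inst,
         tf_bound_genes = tf_bound_genes, cofactor_mirnas = cofactor_mirnas)
  })
}

#' Simulate 3'UTRs with planted seed sites
#'
#' Each planting-table entry yields exactly one site of the requested type
#' at a recorded position; flanking sequence is random, and accidental seed
#' matches of any simulated miRNA are scrubbed by point mutation (never
#' touching a planted site), so the planted table is the exact ground
#' truth. Planting a 7mer-m8 forces the following base away from `A`
#' (never an 8mer); planting a 7mer-1A forces the preceding base away from
#' the position-8 complement.
#'
#' @param annotations list from [simulate_genome()]
#' @param config the [simulation_config()]
#' @param plant_table optional data frame (`mirna_id`, `gene_id`,
#'   `site_type`); defaults to a random design targeting focal genes and
#'   TF-bound genes
#' @param tf_bound_genes gene ids preferred as feed-forward targets
#' @return list with `utrs` (named sequences), `sites` (ground-truth data
#'   frame with `utr_position`) and `plant_table`
#' @export
simulate_utrs <- function(annotations, config, plant_table = NULL,
                          tf_bound_genes = NULL) {
  with_seed(derive_seed(config$seed, "utrs"), {
    mir <- annotations$mirnas
    act <- mir[mir$active %in% TRUE, , drop = FALSE]
    matures <- stats::setNames(mir$mature, mir$id)   # scrub against all miRNAs
    gene_ids <- annotations$genes$id
    utr_ids <- c(gene_ids, config$focal_utr_ids)
    site_types <- c("8mer", "7mer-m8", "7mer-1A")
    if (is.null(plant_table)) {
      rows <- list()
      pool <- if (length(tf_bound_genes)) tf_bound_genes else gene_ids
      for (m in act$id) {
        if (stats::runif(1) < config$feedback_fraction &&
            length(config$focal_utr_ids)) {
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = m, gene_id = sample(config$focal_utr_ids, 1),
            site_type = sample(site_types, 1), stringsAsFactors = FALSE)
        }
        if (length(pool)) {
          ks <- seq(config$targets_per_mirna[1], config$targets_per_mirna[2])
          k <- ks[sample.int(length(ks), 1)]
          for (g in sample(pool, min(k, length(pool)))) {
            rows[[length(rows) + 1L]] <- data.frame(
              mirna_id = m, gene_id = g,
              site_type = sample(site_types, 1), stringsAsFactors = FALSE)
          }
        }
      }
      plant_table <- if (length(rows)) do.call(rbind, rows) else
        data.frame(mirna_id = character(), gene_id = character(),
                   site_type = character(), stringsAsFactors = FALSE)
      plant_table <- unique(plant_table)
    }
    if (nrow(plant_table) && !all(plant_table$site_type %in% site_types)) {
      stop(sprintf("unknown site_type: %s",
                   paste(setdiff(plant_table$site_type, site_types),
                         collapse = ", ")))
    }
    if (nrow(plant_table) && !all(plant_table$mirna_id %in% names(matures))) {
      stop("plant_table names a miRNA without an active mature sequence")
    }
    utrs <- character(0)
    sites <- list()
    for (g in utr_ids) {
      entries <- plant_table[plant_table$gene_id == g, , drop = FALSE]
      len <- round(stats::runif(1, config$utr_length_range[1],
                                config$utr_length_range[2]))
      res <- .build_utr(len, entries, matures)
      utrs[[g]] <- res$seq
      if (nrow(res$sites)) sites[[length(sites) + 1L]] <- res$sites
    }
    sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(mirna_id = character(), gene_id = character(),
                 utr_position = integer(), site_type = character(),
                 stringsAsFactors = FALSE)
    list(utrs = utrs, sites = sites, plant_table = plant_table)
  })
}

# one UTR with the requested sites planted exactly; accidental seed matches
# of any simulated miRNA are removed by point mutations outside the planted
# spans
.build_utr <- function(len, entries, matures) {
  non_a <- c("C", "G", "T")
  bases <- c("A", "C", "G", "T")
  for (attempt in 1:10) {
    s <- rand_dna(len)
    planted <- list()
    used <- matrix(numeric(0), ncol = 2)       # 1-based [start, end) spans
    ok <- TRUE
    for (i in seq_len(nrow(entries))) {
      e <- entries[i, ]
      pat <- .seed_patterns(matures[[e$mirna_id]])
      site <- switch(e$site_type,
                     "8mer" = pat$p8,
                     "7mer-m8" = pat$seed78,
                     "7mer-1A" = pat$p7a)
      L <- nchar(site)
      pos <- NA
      for (t2 in 1:50) {
        p <- sample.int(len - L - 2, 1) + 1L   # keep 1-bp margins
        # keep a 1-bp buffer so the forced flanking bases never collide
        if (!any(used[, 1] < p + L + 1 & used[, 2] > p - 1)) { pos <- p; break }
      }
      if (is.na(pos)) { ok <- FALSE; break }
      substr(s, pos, pos + L - 1) <- site
      span <- c(pos, pos + L)
      if (e$site_type == "7mer-m8" && pos + L <= len) {
        substr(s, pos + L, pos + L) <- sample(non_a, 1)
        span[2] <- pos + L + 1
      }
      if (e$site_type == "7mer-1A" && pos > 1) {
        prev <- setdiff(bases, pat$c8)
        substr(s, pos - 1, pos - 1) <- sample(prev, 1)
        span[1] <- pos - 1
      }
      used <- rbind(used, span)
      planted[[length(planted) + 1L]] <- data.frame(
        mirna_id = e$mirna_id, gene_id = e$gene_id,
        utr_position = pos - 1L, site_type = e$site_type,
        stringsAsFactors = FALSE)
    }
    if (!ok) next
    want <- if (length(planted)) do.call(rbind, planted) else
      data.frame(mirna_id = character(), gene_id = character(),
                 utr_position = integer(), site_type = character(),
                 stringsAsFactors = FALSE)
    clean <- FALSE
    pats <- lapply(matures, .seed_patterns)
    for (round in 1:30) {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      n <- length(chars)
      subs7 <- substring(s, 1:(n - 6), 7:n)
      extras <- list()
      for (m in names(matures)) {
        found <- .scan_seed_sites(pats[[m]], chars, subs7)
        w <- want[want$mirna_id == m, , drop = FALSE]
        key_w <- paste(w$utr_position, w$site_type)
        key_f <- paste(found$utr_position, found$site_type)
        if (any(!key_w %in% key_f)) { extras <- NULL; break }  # planted site lost
        ex <- found[!key_f %in% key_w, , drop = FALSE]
        if (nrow(ex)) extras[[length(extras) + 1L]] <- ex
      }
      if (is.null(extras)) break                 # unrecoverable; regenerate
      if (!length(extras)) { clean <- TRUE; break }
      mutated <- FALSE
      for (ex in extras) {
        for (j in seq_len(nrow(ex))) {
          span_len <- switch(ex$site_type[j], "8mer" = 8L, "7mer-m8" = 7L,
                             "7mer-1A" = 7L)
          q <- ex$utr_position[j] + 1L             # 1-based start
          cand <- setdiff(q:(q + span_len - 1L), unlist(lapply(
            seq_len(nrow(used)), function(r) seq(used[r, 1], used[r, 2] - 1))))
          if (!length(cand)) next
          at <- cand[sample.int(length(cand), 1)]
          cur <- substr(s, at, at)
          substr(s, at, at) <- sample(setdiff(bases, cur), 1)
          mutated <- TRUE
        }
      }
      if (!mutated) break                         # nothing mutable; regenerate
    }
    if (clean) return(list(seq = s, sites = want))
  }
  stop("could not build a UTR free of accidental seed sites")
}
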