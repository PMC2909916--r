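# RPol II TSS binding-shape model.
#
# RNA polymerase II occupancy around an active transcription start site is
# summarised by five features: the peak intensity at the TSS (h_p), the
# steady background intensity (h_b), the steady transcript-region intensity
# (h_t) and the two decay rates of the signal in the promoter (lambda_p)
# and transcript (lambda_t) regions. The expected per-bp intensity at a
# strand-oriented offset x from the TSS is piecewise exponential,
#
#   mu(x) = h_b + (h_p - h_b) * exp( lambda_p * x)   for x <= 0
#   mu(x) = h_t + (h_p - h_t) * exp(-lambda_t * x)   for x >  0,
#
# continuous at the TSS with mu(0) = h_p. Binned read counts are modelled
# as independent Poisson draws with mean bin_width * mu(x); the five
# parameters are fitted by maximum likelihood on TSS-aligned windows of
# expressed protein-coding genes, then used to scan microRNA upstream
# regions for statistically similar binding patterns.

#' Construct TSS shape parameters
#'
#' @param h_p peak intensity at the TSS (expected reads/bp)
#' @param h_b steady background intensity (reads/bp)
#' @param h_t steady transcript-region intensity (reads/bp)
#' @param lambda_p upstream (promoter-side) decay rate (1/bp)
#' @param lambda_t downstream (transcript-side) decay rate (1/bp)
#' @return a `shape_params` object
#' @export
shape_params <- function(h_p, h_b, h_t, lambda_p, lambda_t) {
  vals <- c(h_p = h_p, h_b = h_b, h_t = h_t,
            lambda_p = lambda_p, lambda_t = lambda_t)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all five shape parameters must be positive and finite")
  }
  tol <- 1 + 1e-9
  if (h_p * tol < h_t || h_p * tol < h_b) {
    stop("peak intensity h_p must be >= h_t and >= h_b")
  }
  structure(as.list(vals), class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf(
    "TSS shape: h_p=%.4g h_b=%.4g h_t=%.4g reads/bp; lambda_p=%.4g lambda_t=%.4g /bp\n",
    x$h_p, x$h_b, x$h_t, x$lambda_p, x$lambda_t))
  invisible(x)
}

#' Expected RPol II intensity at an offset from the TSS
#'
#' @param params a [shape_params()] object
#' @param offset signed strand-oriented distance from the TSS in bp
#'   (negative = upstream); vectorised
#' @return expected intensity in reads/bp
#' @export
expected_profile <- function(params, offset) {
  ifelse(offset <= 0,
         params$h_b + (params$h_p - params$h_b) * exp(params$lambda_p * offset),
         params$h_t + (params$h_p - params$h_t) * exp(-params$lambda_t * offset))
}

# strand-oriented bin-centre offsets for a window [window[1], window[2])
window_offsets <- function(window, bin_width) {
  nb <- round((window[2] - window[1]) / bin_width)
  window[1] + (seq_len(nb) - 0.5) * bin_width
}

#' Fit the TSS shape model by maximum likelihood
#'
#' Maximises the Poisson log-likelihood of TSS-aligned binned count windows
#' over the five shape parameters, using bounded quasi-Newton (L-BFGS-B on
#' log-parameters) from a 3x3x3 multi-start grid over (h_p, lambda_p,
#' lambda_t) with h_b and h_t initialised from the window flanks. The fit
#' is deterministic for fixed input.
#'
#' @param windows matrix (windows x bins) or list of equal-length binned
#'   count vectors, each aligned on the TSS
#' @param bin_width bin width in bp
#' @param window strand-oriented window `c(upstream, downstream)` spanned by
#'   each count vector, in bp relative to the TSS (default `c(-3000, 10000)`)
#' @return list with elements `params` ([shape_params()]) and `logLik`
#'   (full Poisson log-likelihood of the data at the fit)
#' @export
fit_shape_params <- function(windows, bin_width, window = c(-3000, 10000)) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  if (is.null(dim(windows))) windows <- matrix(windows, nrow = 1)
  if (nrow(windows) < 10) stop("need at least 10 training windows")
  offs <- window_offsets(window, bin_width)
  if (length(offs) != ncol(windows)) {
    stop(sprintf("windows have %d bins but window/bin_width implies %d",
                 ncol(windows), length(offs)))
  }
  S <- colSums(windows)
  N <- nrow(windows)
  if (sum(S) == 0) stop("degenerate coverage: all training windows are zero")

  negll <- function(theta) {
    p <- exp(theta)
    mu <- ifelse(offs <= 0,
                 p[2] + (p[1] - p[2]) * exp(p[4] * offs),
                 p[3] + (p[1] - p[3]) * exp(-p[5] * offs))
    m <- bin_width * mu
    -(sum(S * log(m)) - N * sum(m))
  }

  up <- offs <= min(offs) + 0.1 * diff(window)       # far upstream flank
  down <- offs >= max(offs) - 0.2 * diff(window)     # far downstream flank
  h_b0 <- max(mean(S[up]) / (N * bin_width), 1e-4)
  h_t0 <- max(mean(S[down]) / (N * bin_width), 1e-4)
  peak <- max(stats::filter(S, rep(1 / 3, 3), sides = 2), na.rm = TRUE) /
    (N * bin_width)
  peak <- max(peak, h_b0, h_t0)

  lower <- log(c(1e-5, 1e-5, 1e-5, 1e-6, 1e-6))
  upper <- log(c(1e4, 1e4, 1e4, 1, 1))
  best <- NULL
  for (hp0 in peak * c(0.5, 1, 2)) {
    for (lp0 in c(0.003, 0.01, 0.03)) {
      for (lt0 in c(5e-4, 2e-3, 8e-3)) {
        th0 <- pmin(pmax(log(c(hp0, h_b0, h_t0, lp0, lt0)), lower), upper)
        fit <- tryCatch(
          stats::optim(th0, negll, method = "L-BFGS-B", lower = lower,
                       upper = upper, control = list(factr = 1e4, maxit = 500)),
          error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value - 1e-9)) {
          best <- fit
        }
      }
    }
  }
  if (is.null(best)) stop("shape-model fit failed from every start")
  p <- exp(best$par)
  # flat data leaves h_p unidentified up to the level parameters; nudge
  # within-noise violations of the peak ordering onto the boundary
  top <- max(p[2], p[3])
  if (p[1] < top) {
    if (p[1] < 0.95 * top) stop("no TSS peak in training windows (h_p < background)")
    p[1] <- top
  }
  params <- shape_params(p[1], p[2], p[3], p[4], p[5])
  list(params = params,
       logLik = shape_loglik(windows, params, bin_width, window))
}

#' Poisson log-likelihood of count windows under the shape model
#' @param windows matrix or list of binned count vectors aligned on the TSS
#' @param params a [shape_params()] object
#' @param bin_width bin width in bp
#' @param window strand-oriented window spanned by each vector
#' @return total log-likelihood (including factorial terms)
#' @export
shape_loglik <- function(windows, params, bin_width, window = c(-3000, 10000)) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  if (is.null(dim(windows))) windows <- matrix(windows, nrow = 1)
  offs <- window_offsets(window, bin_width)
  m <- bin_width * expected_profile(params, offs)
  sum(stats::dpois(windows, rep(m, each = nrow(windows)), log = TRUE))
}

#' Log-likelihood-ratio score for a candidate TSS
#'
#' Score of a binned count window under the shape model centred at
#' `candidate_offset`, relative to the background-only model with constant
#' intensity `h_b`. Higher scores are more TSS-like; a pure-background
#' window scores near or below zero.
#'
#' @param counts binned count vector spanning `window` around the candidate
#' @param params fitted [shape_params()]
#' @param bin_width bin width in bp
#' @param window strand-oriented window spanned by `counts`, relative to the
#'   position the window was extracted around
#' @param candidate_offset offset of the candidate TSS within the window
#'   (default 0: the window is already centred on the candidate)
#' @return log-likelihood ratio (natural log)
#' @export
score_candidate_tss <- function(counts, params, bin_width,
                                window = c(-3000, 10000), candidate_offset = 0) {
  offs <- window_offsets(window, bin_width) - candidate_offset
  m1 <- bin_width * expected_profile(params, offs)
  m0 <- bin_width * params$h_b
  sum(counts * (log(m1) - log(m0)) - (m1 - m0))
}

# internal: LLR scores for candidate TSSs at genomic bin positions.
# anchors: integer bin indices (1-based) of candidate TSS bins on `chrom`.
# Returns NA for candidates whose window leaves the stored track.
.scan_scores_at_bins <- function(track, chrom, anchor_bins, strand, params,
                                 window = c(-3000, 10000)) {
  x <- track$counts[[chrom]]
  if (is.null(x)) stop(sprintf("chromosome '%s' absent from coverage track", chrom))
  bw <- track$bin_width
  offs <- window_offsets(window, bw)
  jrel <- round((offs / bw) - 0.5)              # bin offsets relative to anchor bin
  if (strand == "-") jrel <- -jrel
  w <- log(bw * expected_profile(params, offs)) - log(bw * params$h_b)
  const <- sum(bw * expected_profile(params, offs) - bw * params$h_b)
  vapply(anchor_bins, function(b) {
    idx <- b + jrel
    if (any(idx < 1 | idx > length(x))) return(NA_real_)
    sum(x[idx] * w) - const
  }, numeric(1))
}

#' Scan the upstream region of an intergenic miRNA for a TSS-like pattern
#'
#' Evaluates every bin-aligned candidate TSS from the pre-miRNA 5' end to
#' `max_distance` bp upstream (strand-aware) with the log-likelihood-ratio
#' score, and returns the best candidate; exact ties are broken toward the
#' candidate closest to the pre-miRNA.
#'
#' @param track a [coverage_track()] of RPol II signal
#' @param mirna a one-row data frame (or list) with `chrom`, `start`, `end`,
#'   `strand` of the pre-miRNA and an `id`
#' @param params fitted [shape_params()]
#' @param max_distance maximum scan distance upstream of the pre-miRNA 5'
#'   end, in bp (default 10000)
#' @param window scoring window around each candidate (default
#'   `c(-3000, 10000)`)
#' @return list with `mirna_id`, `tss` (genomic bp of the best candidate
#'   bin start), `distance` (bp upstream of the pre-miRNA 5' end), `score`,
#'   and `candidates` (data frame of every evaluated candidate)
#' @export
scan_mirna_upstream <- function(track, mirna, params, max_distance = 10000,
                                window = c(-3000, 10000)) {
  bw <- track$bin_width
  strand <- as.character(mirna$strand)
  five_prime <- if (strand == "-") mirna$end - 1 else mirna$start
  d <- seq(0, max_distance, by = bw)
  pos <- if (strand == "-") five_prime + d else five_prime - d
  keep <- pos >= 0
  d <- d[keep]; pos <- pos[keep]
  anchor_bins <- floor(pos / bw) + 1
  sc <- .scan_scores_at_bins(track, as.character(mirna$chrom), anchor_bins,
                             strand, params, window)
  cand <- data.frame(distance = d, tss = floor(pos / bw) * bw, score = sc)
  ok <- which(!is.na(sc))
  if (!length(ok)) stop(sprintf("no scorable candidate for miRNA '%s'", mirna$id))
  best <- ok[which.max(sc[ok])]   # candidates ordered by increasing distance,
                                  # so ties resolve closest to the miRNA
  list(mirna_id = as.character(mirna$id), tss = cand$tss[best],
       distance = cand$distance[best], score = cand$score[best],
       candidates = cand)
}

#' Call the promoter regulatory region around an accepted TSS
#'
#' Returns the maximal contiguous run of bins around the TSS whose observed
#' count exceeds the background threshold
#' `h_b * bin_width + k * sqrt(h_b * bin_width)`, clipped to
#' `[1 bin, max_width]`. The TSS bin is always included.
#'
#' @param track a [coverage_track()]
#' @param chrom chromosome of the TSS
#' @param tss genomic position (bp) of the accepted TSS
#' @param params fitted [shape_params()]
#' @param k threshold multiplier in background s.d. units (default 2)
#' @param max_width maximum region width in bp (default 5000)
#' @return a one-row [genomic_intervals()] table containing the TSS
#' @export
call_promoter_region <- function(track, chrom, tss, params, k = 2,
                                 max_width = 5000) {
  x <- track$counts[[chrom]]
  if (is.null(x)) stop(sprintf("chromosome '%s' absent from coverage track", chrom))
  bw <- track$bin_width
  thr <- params$h_b * bw + k * sqrt(params$h_b * bw)
  b0 <- floor(tss / bw) + 1
  b0 <- min(max(b0, 1L), length(x))
  left <- right <- b0
  max_bins <- max(1L, floor(max_width / bw))
  repeat {
    if (right - left + 1 >= max_bins) break
    lval <- if (left > 1 && x[left - 1] > thr) x[left - 1] else -Inf
    rval <- if (right < length(x) && x[right + 1] > thr) x[right + 1] else -Inf
    if (!is.finite(lval) && !is.finite(rval)) break
    if (lval >= rval) left <- left - 1 else right <- right + 1
  }
  genomic_intervals(chrom, (left - 1) * bw, right * bw, "*")
}

#' Empirical false discovery rate for candidate scores
#'
#' For each candidate score `s`, the raw estimate is
#' `FDR(s) = (fraction of null scores >= s) / (fraction of candidate scores
#' >= s)`, clipped to `[0, 1]` and then monotonized so the FDR is
#' non-increasing in the score (each candidate receives the smallest
#' estimate achievable at any threshold at or below its score).
#'
#' @param candidate_scores numeric candidate scores
#' @param null_scores numeric null scores (e.g. best-of-scan scores at
#'   random intergenic anchors and unexpressed-gene TSS windows)
#' @return numeric FDR per candidate, aligned with `candidate_scores`
#' @export
empirical_fdr <- function(candidate_scores, null_scores) {
  if (!length(null_scores)) stop("empty null score set")
  if (!length(candidate_scores)) return(numeric(0))
  ord <- order(candidate_scores, decreasing = TRUE)
  s <- candidate_scores[ord]
  sn <- sort(null_scores)
  n_null <- length(sn)
  n_cand <- length(candidate_scores)
  frac_null <- (n_null - findInterval(s - 1e-12, sn)) / n_null
  sc <- sort(candidate_scores)
  frac_cand <- (n_cand - findInterval(s - 1e-12, sc)) / n_cand
  raw <- pmin(1, pmax(0, frac_null / frac_cand))
  mono <- rev(cummin(rev(raw)))
  out <- numeric(n_cand)
  out[ord] <- mono
  out
}

#' ROC evaluation of TSS scores against expression labels
#'
#' AUC is the Mann-Whitney statistic divided by `n_pos * n_neg` (ties count
#' one half). Per-tier AUCs use that tier's genes as positives against all
#' unexpressed genes.
#'
#' @param scores numeric scores, one per gene
#' @param labels logical (or coercible): `TRUE` = expressed (positive)
#' @param tiers optional character tier per gene (`"low"`, `"medium"`,
#'   `"high"`; ignored for unexpressed genes)
#' @return list with `auc` and, when `tiers` is given, `auc_by_tier`
#' @export
evaluate_roc <- function(scores, labels, tiers = NULL) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("need both positive and negative labels")
  auc <- .auc_mw(scores[labels], scores[!labels])
  out <- list(auc = auc)
  if (!is.null(tiers)) {
    neg <- scores[!labels]
    lev <- intersect(c("low", "medium", "high"), unique(tiers[labels]))
    out$auc_by_tier <- vapply(lev, function(tr) {
      .auc_mw(scores[labels & tiers == tr], neg)
    }, numeric(1))
  }
  out
}

.auc_mw <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("need both positive and negative scores")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
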