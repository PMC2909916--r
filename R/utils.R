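# shared internal helpers

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` on exit so seeded sections do not
#' perturb the global RNG stream. A `NULL` seed evaluates the code as-is.
#' @param seed integer seed or `NULL`
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-stage seed from a master seed; stays below 2^31 so it is a
# valid R integer seed.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  b <- utf8ToInt(stage)
  h <- sum(b * seq_along(b)) %% 100003
  as.integer((abs(as.numeric(master)) * 48271 + h * 7919 + 17) %% 2147483587)
}

revcomp <- function(x) {
  if (!length(x)) return(character(0))
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgtUu", "TGCAtgcaAa", s), "",
                       fixed = TRUE)[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

rand_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# md5-based digest of an arbitrary R object (used to stamp output tables)
config_digest <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f), add = TRUE)
  writeLines(paste(deparse(x), collapse = "\n"), f)
  substr(unname(tools::md5sum(f)), 1L, 12L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
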