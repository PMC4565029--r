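# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical, order-independent key of a regulatory program; used for
# deterministic lexicographic tie-breaking everywhere a choice is made.
program_key <- function(activators, repressors) {
  paste0(paste(sort(activators), collapse = ","), "|",
         paste(sort(repressors), collapse = ","))
}

join_ids <- function(ids) paste(sort(ids), collapse = ";")

split_ids <- function(s) {
  if (length(s) != 1L || is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, ";", fixed = TRUE)[[1L]]
}

# Scores are compared at 1e-12 granularity so that tie-breaking is stable
# across algebraically equivalent ways of computing the same quantity.
round12 <- function(x) round(x, 12L)

# Population standard deviation (normalized by n).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Uniform draw of one element from a vector (length-1 safe, unlike sample()).
resample1 <- function(x) x[sample.int(length(x), 1L)]

# Pearson correlation that returns NA (without a warning) for degenerate rows.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
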