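# Internal helpers shared across modules.

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage substream seeds derived from one master seed, so
# pipeline stages can be re-run independently yet reproducibly.  Kept within
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  stages <- c("repeats", "phenotypes", "missingness", "replicates")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage, call. = FALSE)
  as.integer((as.double(seed) + 1000003 * i) %% .Machine$integer.max)
}

# round() half-away-from-zero, matching how epidemiological tables are
# conventionally printed (base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
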