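# Internal utilities: seed handling, fast row statistics, logging.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library calls never perturb a user's stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible substream seed < 2^31 from a master seed and a
# stream name, so one pipeline seed drives map/truth/pools/... streams.
deriveSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(as.character(stream))) h <- (h * 131 + c) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m)
}

rowVarsFast <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  pmax((rowSums(x * x) - n * m * m) / (n - 1), 0)
}

pcInfo <- function(...) message("INFO  [poolConverge] ", ...)
pcWarn <- function(...) message("WARN  [poolConverge] ", ...)
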