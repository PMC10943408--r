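# Internal helpers: seed derivation, seeded evaluation, small assertions.

# Deterministically derive a 31-bit seed from a base seed and a label path.
# Uses a splitmix-style integer hash in double arithmetic (exact below 2^53).
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483629  # prime < 2^31
  h <- (as.numeric(seed) %% m)
  for (part in list(...)) {
    for (tok in as.character(part)) {
      for (cc in utf8ToInt(tok)) {
        h <- (h * 31 + cc) %% m
      }
      h <- (h * 131071 + 17) %% m
    }
  }
  as.integer(h %% 2147483647) + 1L
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

# Age-band boundaries in days ("6-10" means ages [6, 11) etc.).
age_band_days <- function(band) {
  switch(band,
    "6-10"  = c(AGE_MIN_DAYS, floor(11 * DAYS_PER_YEAR) - 1L),
    "11-13" = c(floor(11 * DAYS_PER_YEAR), floor(14 * DAYS_PER_YEAR) - 1L),
    "14-17" = c(floor(14 * DAYS_PER_YEAR), AGE_MAX_DAYS - 1L),
    stop("unknown age band: ", band)
  )
}
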