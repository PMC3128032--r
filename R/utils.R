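# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  seed = NULL means "use the ambient RNG".
with_local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
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
  force(code)
}

# Spawn n reproducible sub-seeds from one master seed (kept below 2^31 so they
# are valid R integer seeds).  With seed = NULL the ambient RNG is consumed.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(2147483646L, n))
}

# sample() treats a length-1 numeric as 1:x; these wrappers never do.
shuffle <- function(x) {
  if (length(x) <= 1L) x else x[sample.int(length(x))]
}

sample1 <- function(x) {
  if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
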