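# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

hlca_message <- function(...) {
  if (!isTRUE(getOption("hlca.quiet", FALSE))) message(...)
}

# Canonical string key for a node-index set; used for deduplication and
# deterministic ordering of hyperedges / cliques / complexes.
set_key <- function(idx) paste(sort(idx), collapse = "\r")
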