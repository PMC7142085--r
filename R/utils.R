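# Run code with a temporarily fixed RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Split one cohort seed into n reproducible per-unit seeds (kept below 2^31).
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]
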