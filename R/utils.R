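# Run code under a temporary RNG state so that seeded package functions do
# not clobber the caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for (stream i, substream j) derived from a master
# seed; keeps every derived seed a valid 32-bit integer.
child_seed <- function(seed, i, j = 0L) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed %% 100003L) * 7919 +
              as.double(i) * 104729 + as.double(j) * 1299709) %% 2147483647)
}
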