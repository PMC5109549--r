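# evaluate code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

col_sds <- function(v) {
  n <- nrow(v)
  m <- colMeans(v)
  sqrt(pmax(colSums(v^2) - n * m^2, 0) / (n - 1))
}

# derive n child seeds from one master seed (counter scheme: reproducible and
# independent of evaluation order); values stay below 2^31
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
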