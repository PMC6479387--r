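# Seed handling: evaluate code under a given seed and restore the caller's
# RNG state afterwards, so library calls never clobber user reproducibility.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive n child seeds from the current RNG stream (call inside with_seed).
# Kept below 2^31 so they are valid R integer seeds.
child_seeds <- function(n) sample.int(.Machine$integer.max, n)
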