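# Lightweight RNG stream handling on top of base R's global generator.
#
# A session derives independent child streams (weights, stimulus sequence,
# per-trial simulation) from one master seed, so that e.g. two noise
# conditions with the same master seed see identical stimulus sequences and
# initial weights while their noise draws differ.

# Evaluate fun() under a temporary seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, fun) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fun()
}

# A stream is an environment holding a saved .Random.seed state.
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- with_preserved_seed(seed, function() {
    get(".Random.seed", globalenv(), inherits = FALSE)
  })
  e
}

# Evaluate fun() with the stream's RNG state active; advance the stream and
# restore the caller's state afterwards.
stream_eval <- function(stream, fun) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  res <- fun()
  stream$state <- get(".Random.seed", globalenv(), inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  res
}

# Child seeds derived from a master seed (kept below 2^31).
derive_child_seeds <- function(master, n = 3L) {
  with_preserved_seed(master, function() sample.int(2147483646L, n))
}
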