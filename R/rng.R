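# Seed-substream derivation.
#
# One master seed drives a simulation; every stochastic stage derives its own
# substream seed from (master seed, stage key). Stages therefore never share a
# stream, and inserting a new stage does not perturb draws made by existing
# ones. The key hash is a 31-ary polynomial over the character codes reduced
# mod the Mersenne prime 2^31 - 1, computed in doubles (max intermediate
# 2^31 * 31 < 2^53, so arithmetic is exact).
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(key))
  mod <- 2147483647
  acc <- (abs(master) %% mod)
  for (code in utf8ToInt(paste(key, collapse = "/"))) {
    acc <- (acc * 31 + code) %% mod
  }
  as.integer(acc)
}

# Evaluate `expr` under a seeded local RNG without disturbing the caller's
# RNG state.
with_substream <- function(master, key, expr) {
  seed <- derive_seed(master, key)
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
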