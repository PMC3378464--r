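# Deterministic per-stream seeding: every randomised operation derives a
# 31-bit sub-seed from (master seed, stream key), so chromosomes can be
# simulated independently and reproducibly regardless of evaluation order.
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 1000003 + h) %% 2147483647)
}

# Evaluate `code` under the derived seed, restoring the caller's RNG state.
with_seed_stream <- function(seed, key, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, key))
  code
}
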