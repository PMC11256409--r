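# Internal helpers shared across modules.

# Deterministic 31-bit hash of a character key. Used to fan a single global
# seed out to independent child seeds so that generation of any one sample is
# independent of the order in which samples are visited.
stable_hash <- function(key) {
  codes <- utf8ToInt(key)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  h
}

child_seed <- function(seed, key) {
  base <- ((seed %% 2147483647) * 48271) %% 2147483647
  (base + stable_hash(key)) %% 2147483646 + 1
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}
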