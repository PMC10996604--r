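# Internal RNG plumbing. All generators take one top-level seed; independent
# substreams for named components (one per contig, per replicate, ...) are
# derived by hashing the label, so adding a contig never perturbs the draws
# made for the others.

# deterministic 31-bit hash of a label string combined with a base seed
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (c in utf8ToInt(as.character(label))) {
    h <- (h * 131 + c) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 + h * 7919) %% 2147483647)
}

# evaluate `code` under set.seed(seed), restoring the caller's RNG state
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# uniform random DNA string of length n (character scalar)
random_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
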