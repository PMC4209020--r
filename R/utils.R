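# Internal helpers: seeded RNG scoping and deterministic per-stream seeds.

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  expr
}

# Deterministic 31-bit stream seed from a string label and a root seed, so
# per-species streams are stable under addition/removal of other species.
deriveSeed <- function(label, rootSeed) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  as.integer((h + (as.numeric(rootSeed) %% 2147483647) * 48271) %% 2147483647)
}

# Reverse complement on plain character vectors (A/C/G/T/N).
revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stopIfNot <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
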