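# Internal helpers shared across modules.

# Canonicalize gene identifiers: trim surrounding whitespace and case-fold.
# Matching is exact-string after canonicalization; no alias resolution.
canonicalize_ids <- function(x) {
  tolower(trimws(as.character(x)))
}

# Unordered pair key: endpoints sorted lexicographically.
pair_key <- function(a, b) {
  swap <- b < a
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "\r")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`
# (NULL = use the current RNG stream untouched).
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
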