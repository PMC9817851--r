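# Internal helpers shared across modules.

# Canonical unordered-dyad key "a|b" with a < b lexicographically.
dyad_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

split_dyad_key <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  list(a = vapply(parts, `[`, character(1), 1L),
       b = vapply(parts, `[`, character(1), 2L))
}

# Run `fun()` under a given seed without disturbing the caller's RNG stream.
# A NULL seed uses (and advances) the current stream.
with_rng <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  fun()
}

# Deterministic child seed from a master seed and a string tag, kept well
# inside the 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587) + 1L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}
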