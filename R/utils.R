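# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  All user-facing randomness in the package flows through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic 31-bit polynomial hash of a string; used to derive
# independent sub-seeds (e.g. one per pre-amplification batch label).
string_seed <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Combine a base seed with a stream label into a derived 31-bit seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + string_seed(stream)) %%
               2147483647)
}

# One multivariate hypergeometric draw: sample `k` items without
# replacement from categories with sizes `counts`.  Sequential
# conditional draws via stats::rhyper.
rmvhyper <- function(counts, k) {
  n <- length(counts)
  out <- integer(n)
  remaining <- sum(counts)
  for (i in seq_len(n)) {
    if (k <= 0L) break
    ci <- counts[i]
    x <- stats::rhyper(1L, ci, remaining - ci, k)
    out[i] <- x
    k <- k - x
    remaining <- remaining - ci
  }
  out
}

# Sample-convention (n-1) standard deviation that tolerates length-1 input.
sdev <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
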