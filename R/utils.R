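# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a child seed from a parent seed and an offset;
# result always fits in a 32-bit signed integer. Exact in double arithmetic
# because all intermediates stay far below 2^53.
derive_seed <- function(seed, offset) {
  as.integer((abs(seed) %% 94906265 * 48271 + offset * 16807 + 12345) %%
               2147483647)
}

# All residue pairs i < j of an L-residue chain, as a 2-column matrix.
upper_pairs <- function(L) {
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  cbind(i = idx[, "row"], j = idx[, "col"])
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "_")

`%||%` <- function(a, b) if (is.null(a)) b else a
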