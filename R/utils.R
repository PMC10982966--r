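# Internal helpers shared across modules.

# Derive a reproducible 32-bit child seed from a root seed and an index.
# Plain affine hash; collisions are irrelevant at cohort scale, determinism is
# the only requirement.
child_seed <- function(root, index) {
  (as.integer(root) %% 2147483562L + 97561L * as.integer(index)) %% 2147483562L + 1L
}

# Evaluate `expr` with a local RNG state seeded by `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
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
  expr
}

# Integer apportionment by largest remainder: returns non-negative integers
# summing to `total`, proportional to `weights`.
apportion <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Clamp numeric vector into [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
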