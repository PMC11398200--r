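# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-item seed from a master seed, kept inside 32-bit integer range.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

# floor() guarded against representation error (0.7 * 40110 = 28076.999...).
floor_eps <- function(x, eps = 1e-9) floor(x + eps)

# Round half away from zero (R's round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Allocate `round_total` integer counts across groups proportionally to
# `sizes` by floor-plus-largest-remainder.
largest_remainder <- function(sizes, frac, total = NULL) {
  exact <- frac * sizes
  base <- floor_eps(exact)
  if (is.null(total)) total <- floor_eps(frac * sum(sizes))
  short <- total - sum(base)
  if (short > 0) {
    rem <- exact - base
    order_idx <- order(rem, decreasing = TRUE)
    take <- order_idx[seq_len(short)]
    base[take] <- base[take] + 1L
  } else if (short < 0) {
    rem <- exact - base
    order_idx <- order(rem)
    drop_idx <- order_idx[seq_len(-short)]
    base[drop_idx] <- base[drop_idx] - 1L
  }
  as.integer(base)
}

# Stratified fold ids (1..k), balanced per class, deterministic given seed.
stratified_folds <- function(labels, k, seed) {
  if (k < 2) abort_config("number of folds must be >= 2, got %d", k)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        abort_config("class %s has %d rows, fewer than k = %d folds",
                     format(cl), length(idx), k)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

is_count <- function(x) is.numeric(x) && length(x) == 1 &&
  is.finite(x) && x == as.integer(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
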