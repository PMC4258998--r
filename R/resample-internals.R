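# Internal resampling machinery shared by the three procedures.
#
# Resampling m values with replacement from a pool of n values is drawn as a
# multinomial count vector over the *sorted* pool: counts ~ Multinomial(m,
# uniform over the n values), and rep(sorted_pool, counts) is the resample,
# already sorted. This is distributionally identical to sample(pool, m,
# replace = TRUE) followed by sort(), but needs no per-iteration sort and
# lets whole iteration batches be drawn in one rmultinom() call.

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state
# afterwards. seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit hash of a character key (polynomial rolling hash).
# Used to derive per-participant RNG substreams that are invariant to input
# row order: the substream depends only on (master seed, participant id).
hash_key <- function(key) {
  p <- 2147483647 # 2^31 - 1
  h <- 0
  for (cp in utf8ToInt(as.character(key))) h <- (h * 131 + cp) %% p
  as.integer(h)
}

substream_seed <- function(master_seed, key) {
  p <- 2147483647
  as.integer((as.numeric(master_seed %% p) * 48271 + hash_key(key)) %% p)
}

# One resample of size m from a sorted pool; returns the sorted resample.
resample_sorted <- function(pool_sorted, m) {
  n <- length(pool_sorted)
  counts <- rmultinom(1L, m, rep.int(1, n))[, 1L]
  rep.int(pool_sorted, counts)
}

# Batched bootstrap survival curves for one cell: n_iter resamples of
# size n from the sorted pool, evaluated on bins 0..t_max.
# Returns a (t_max + 1) x n_iter matrix of survival percents.
boot_survival_matrix <- function(pool_sorted, n_iter, t_max) {
  n <- length(pool_sorted)
  bins <- 0L:t_max
  # row index per bin into the zero-padded cumulative count matrix
  idx <- findInterval(bins, pool_sorted) + 1L
  counts <- rmultinom(n_iter, n, rep.int(1, n))
  if (n > 1) {
    for (i in 2:n) counts[i, ] <- counts[i, ] + counts[i - 1L, ]
  }
  cum0 <- rbind(0L, counts) # (n+1) x n_iter; row j+1 = count of resamples <= pool[j]
  (n - cum0[idx, , drop = FALSE]) * (100 / n)
}

# Bootstrap group difference curves: for each iteration, per-participant
# survival curves are averaged within condition and the fast group curve is
# subtracted from the slow. Returns a (t_max + 1) x n_iter matrix.
boot_group_diff_matrix <- function(pools, n_iter, t_max) {
  n_part <- length(pools)
  acc_slow <- matrix(0, t_max + 1L, n_iter)
  acc_fast <- matrix(0, t_max + 1L, n_iter)
  for (pp in pools) {
    acc_slow <- acc_slow + boot_survival_matrix(pp$slow, n_iter, t_max)
    acc_fast <- acc_fast + boot_survival_matrix(pp$fast, n_iter, t_max)
  }
  (acc_slow - acc_fast) / n_part
}

# First index starting a run of at least run_length consecutive TRUEs;
# NA_integer_ if none. Runs truncated by the end of the vector (length <
# run_length) do not qualify.
first_run_start <- function(x, run_length) {
  r <- rle(x)
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) == 0) return(NA_integer_)
  ends <- cumsum(r$lengths)
  as.integer(ends[hit[1L]] - r$lengths[hit[1L]] + 1L)
}
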