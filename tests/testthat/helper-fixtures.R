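# Shared fixture builders. All data are generated in code; nothing on disk.

# A table where every participant's slow cell is a point mass at `slow_ms`
# and the fast cell a point mass at `fast_ms`.
point_mass_table <- function(n_participants = 4, n_obs = 10,
                             slow_ms = 300, fast_ms = 100) {
  ids <- sprintf("p%02d", seq_len(n_participants))
  latency_table(
    participant = rep(ids, each = 2 * n_obs),
    condition = rep(rep(c("slow", "fast"), each = n_obs), n_participants),
    latency_ms = rep(c(rep(slow_ms, n_obs), rep(fast_ms, n_obs)),
                     n_participants),
    slow_label = "slow", fast_label = "fast"
  )
}

# Slow and fast cells drawn identically (shared pool per participant).
identical_pools_table <- function(n_participants = 6, n_obs = 40,
                                  seed = 1) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n_participants))
  rows <- lapply(ids, function(id) {
    pool <- sample_exgaussian(n_obs)
    data.frame(participant = id,
               condition = rep(c("slow", "fast"), each = n_obs),
               latency_ms = rep(pool, 2))
  })
  df <- do.call(rbind, rows)
  latency_table(df$participant, df$condition, df$latency_ms,
                slow_label = "slow", fast_label = "fast")
}

# Build a difference_curve container directly (for rule-level tests where
# constructing matching survival curves would be noise).
make_diff_curve <- function(t_ms, diff_pct) {
  structure(data.frame(t_ms = as.integer(t_ms), diff_pct = diff_pct),
            class = c("difference_curve", "data.frame"))
}

# Build a paired_order_statistics container directly.
make_pairs <- function(s, f) {
  structure(list(slow_sorted = s, fast_sorted = f, diff = s - f,
                 survival_pct = 100 - seq_along(s) / length(s) * 100),
            class = "paired_order_statistics")
}

# The strong-effect scenario used for oracle cross-checks: participants
# share an injected divergence at `d` with every eligible latency
# lengthened (proportion 1 makes the effect maximally consistent).
strong_effect_table <- function(n_participants = 8, n_obs = 40, d = 160,
                                delta = 50, proportion = 1, seed = 1) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n_participants))
  rows <- lapply(ids, function(id) {
    fast <- sample_exgaussian(n_obs)
    slow <- make_artificial_slow(fast, d, delta = delta,
                                 proportion = proportion)
    data.frame(participant = id,
               condition = rep(c("slow", "fast"), each = n_obs),
               latency_ms = c(slow, fast))
  })
  df <- do.call(rbind, rows)
  latency_table(df$participant, df$condition, df$latency_ms,
                slow_label = "slow", fast_label = "fast")
}

table_pools <- function(table) {
  slow_lab <- attr(table, "slow_label")
  fast_lab <- attr(table, "fast_label")
  lapply(split(seq_len(nrow(table)), table$participant), function(idx) {
    cond <- table$condition[idx]
    list(slow = table$latency_ms[idx][cond == slow_lab],
         fast = table$latency_ms[idx][cond == fast_lab])
  })
}
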