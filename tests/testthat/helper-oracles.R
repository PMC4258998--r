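# Independent naive re-implementations used as oracles. These deliberately
# share no code with the package: survival by double loop, resampling by
# sample(..., replace = TRUE) + sort(), run detection by explicit scan.

naive_survival <- function(latencies, t_max) {
  vapply(0:t_max, function(t) 100 * sum(latencies > t) / length(latencies),
         numeric(1))
}

naive_first_run <- function(qualifies, k) {
  n <- length(qualifies)
  for (i in seq_len(n - k + 1)) {
    if (all(qualifies[i:(i + k - 1)])) return(i)
  }
  NA_integer_
}

# pools: list per participant of list(slow =, fast =)
naive_group_diff <- function(pools, t_max, resample = TRUE) {
  per_cond <- function(which_cond) {
    curves <- sapply(pools, function(pp) {
      pool <- pp[[which_cond]]
      x <- if (resample) sample(pool, length(pool), replace = TRUE) else pool
      naive_survival(x, t_max)
    })
    rowMeans(curves)
  }
  per_cond("slow") - per_cond("fast")
}

naive_original_dpa <- function(pools, n_iter, t_max, rank_lo, run_len) {
  diffs <- replicate(n_iter, naive_group_diff(pools, t_max))
  lower <- apply(diffs, 1, function(v) sort(v)[rank_lo])
  start <- naive_first_run(lower > 0, run_len)
  if (is.na(start)) NA_real_ else start - 1 # bins begin at t = 0
}

naive_ci_dpa <- function(pools, n_iter, t_max, threshold, run_len) {
  ests <- replicate(n_iter, {
    d <- naive_group_diff(pools, t_max)
    start <- naive_first_run(d >= threshold, run_len)
    if (is.na(start)) NA_real_ else start - 1
  })
  found <- ests[!is.na(ests)]
  list(estimate = median(found), detection_rate = length(found) / n_iter)
}

naive_ip_participant <- function(slow_pool, fast_pool, n_iter, resample_n,
                                 run_len) {
  vals <- replicate(n_iter, {
    s <- sort(sample(slow_pool, resample_n, replace = TRUE))
    f <- sort(sample(fast_pool, resample_n, replace = TRUE))
    i <- naive_first_run(s > f, run_len)
    if (is.na(i)) NA_real_ else (s[i] + f[i]) / 2
  })
  found <- vals[!is.na(vals)]
  list(estimate = if (length(found)) median(found) else NA_real_,
       detection_rate = length(found) / n_iter)
}
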