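#' Paired order statistics for one bootstrap iteration
#'
#' Draws `resample_n` (default 1,200) latencies with replacement from the
#' slow pool and from the fast pool, sorts each resample ascending and pairs
#' them index-wise: `(s_1, f_1), ..., (s_n, f_n)`. The sorted order is the
#' order in which responses terminate, so each "death" lowers the survival
#' percent by the minimum possible decrement `1/resample_n * 100`; the
#' survival percent attached to pair `i` is `100 - i/resample_n * 100`.
#'
#' @param slow_pool,fast_pool non-empty numeric latency pools (ms).
#' @param resample_n resamples drawn from each pool (default 1200).
#' @param cell optional label used in error messages for empty pools.
#' @return a list of class `"paired_order_statistics"` with elements
#'   `slow_sorted`, `fast_sorted`, `diff` (`slow_sorted - fast_sorted`) and
#'   `survival_pct`.
#' @export
pair_iteration <- function(slow_pool, fast_pool, resample_n = 1200L,
                           cell = NULL) {
  where <- if (is.null(cell)) "" else paste0(" for ", cell)
  if (length(slow_pool) == 0) stop("empty slow pool", where, call. = FALSE)
  if (length(fast_pool) == 0) stop("empty fast pool", where, call. = FALSE)
  resample_n <- as.integer(resample_n)
  stopifnot(resample_n >= 1)
  s <- resample_sorted(sort(slow_pool), resample_n)
  f <- resample_sorted(sort(fast_pool), resample_n)
  structure(
    list(slow_sorted = s, fast_sorted = f, diff = s - f,
         survival_pct = 100 - seq_len(resample_n) / resample_n * 100),
    class = "paired_order_statistics"
  )
}

#' Divergence point of one paired-order-statistics iteration
#'
#' Finds the first pair index `i` opening a run of `run_length` (default
#' 100) consecutive pairs with a strictly positive difference
#' (`s_i > f_i`; ties break a run). The divergence point value of the
#' iteration is the average duration of that first pair,
#' `(s_i + f_i) / 2`.
#'
#' @param pairs a [pair_iteration()] result.
#' @param run_length required run of consecutive strictly positive pairs.
#' @return the divergence value in ms, or `NA_real_` if no qualifying run.
#' @export
iteration_individual_divergence <- function(pairs, run_length = 100L) {
  stopifnot(inherits(pairs, "paired_order_statistics"))
  run_length <- as.integer(run_length)
  stopifnot(run_length >= 1, run_length <= length(pairs$diff))
  i <- first_run_start(pairs$diff > 0, run_length)
  if (is.na(i)) return(NA_real_)
  (pairs$slow_sorted[i] + pairs$fast_sorted[i]) / 2
}

# Fast path: all iterations for one participant in one batch.
# Returns the numeric vector of detected divergence values (possibly empty).
ip_iteration_values <- function(slow_sorted, fast_sorted, config) {
  n_iter <- config$n_iterations
  m <- config$resample_n
  k <- config$run_length
  cs <- rmultinom(n_iter, m, rep.int(1, length(slow_sorted)))
  cf <- rmultinom(n_iter, m, rep.int(1, length(fast_sorted)))
  vals <- numeric(n_iter)
  n_found <- 0L
  for (j in seq_len(n_iter)) {
    s <- rep.int(slow_sorted, cs[, j])
    f <- rep.int(fast_sorted, cf[, j])
    i <- first_run_start(s > f, k)
    if (!is.na(i)) {
      n_found <- n_found + 1L
      vals[n_found] <- (s[i] + f[i]) / 2
    }
  }
  vals[seq_len(n_found)]
}

#' Individual-Participant DPA for a single participant
#'
#' Repeats [pair_iteration()] plus [iteration_individual_divergence()]
#' `n_iterations` times on one participant's two latency pools. Iterations
#' with no detected divergence are discarded; the participant's estimate is
#' the median of the remaining values. A participant whose detection rate
#' falls below 50\% is flagged unreliable (exactly 50\% counts as reliable).
#'
#' @param slow_pool,fast_pool the participant's latency pools (ms).
#' @param config a [dpa_config()] (procedure `"ip"`).
#' @param participant_id optional identifier carried into the result.
#' @return a list of class `"participant_divergence"` with elements
#'   `participant_id`, `estimate` (ms, `NA` if nothing detected),
#'   `detection_rate`, `reliable` and `iteration_values`.
#' @export
ip_dpa_participant <- function(slow_pool, fast_pool,
                               config = dpa_config("ip"),
                               participant_id = NA_character_) {
  stopifnot(identical(config$procedure, "ip"))
  if (length(slow_pool) == 0 || length(fast_pool) == 0) {
    stop("empty latency pool for participant ", participant_id,
         call. = FALSE)
  }
  stopifnot(config$run_length <= config$resample_n)
  vals <- with_seed(config$seed,
                    ip_iteration_values(sort(slow_pool), sort(fast_pool),
                                        config))
  rate <- length(vals) / config$n_iterations
  structure(
    list(participant_id = participant_id,
         estimate = if (length(vals) == 0) NA_real_ else median(vals),
         detection_rate = rate,
         reliable = rate >= 0.5,
         iteration_values = vals),
    class = "participant_divergence"
  )
}

#' @export
print.participant_divergence <- function(x, ...) {
  est <- if (is.na(x$estimate)) "none" else sprintf("%g ms", x$estimate)
  cat(sprintf(
    "<participant_divergence> %s: estimate %s (detection rate %.3f, %s)\n",
    x$participant_id, est, x$detection_rate,
    if (x$reliable) "reliable" else "unreliable"))
  invisible(x)
}

#' Individual-Participant DPA across a sample
#'
#' Runs [ip_dpa_participant()] for every participant in the table. Each
#' participant gets an independent RNG substream derived deterministically
#' from the master seed and the participant identifier, so results do not
#' depend on input row order. Group divergence summaries (mean, SD) are
#' computed over reliable participants only; the number excluded as
#' unreliable is reported.
#'
#' @param table a [latency_table()].
#' @param config a [dpa_config()] (procedure `"ip"`); `config$seed` is the
#'   master seed for the substreams.
#' @return a list of class `"ip_dpa_result"`: `participants` (a data.frame
#'   with columns `participant`, `estimate_ms`, `detection_rate`,
#'   `reliable`), `group_mean`, `group_sd`, `n_excluded`, `config`.
#' @export
ip_dpa_group <- function(table, config = dpa_config("ip")) {
  stopifnot(inherits(table, "latency_table"),
            identical(config$procedure, "ip"))
  pools <- cell_pools(table)
  ids <- names(pools)
  res <- lapply(ids, function(id) {
    sub <- config
    sub$seed <- if (is.null(config$seed)) NULL else
      substream_seed(config$seed, id)
    ip_dpa_participant(pools[[id]]$slow, pools[[id]]$fast, sub,
                       participant_id = id)
  })
  df <- data.frame(
    participant = ids,
    estimate_ms = vapply(res, function(r) r$estimate, numeric(1)),
    detection_rate = vapply(res, function(r) r$detection_rate, numeric(1)),
    reliable = vapply(res, function(r) r$reliable, logical(1)),
    stringsAsFactors = FALSE
  )
  keep <- df$reliable & !is.na(df$estimate_ms)
  if (!any(keep)) {
    warning("ip_dpa_group: no reliable participants; group summary is NA",
            call. = FALSE)
    gm <- NA_real_
    gs <- NA_real_
  } else {
    gm <- mean(df$estimate_ms[keep])
    gs <- sd(df$estimate_ms[keep])
  }
  structure(
    list(participants = df, group_mean = gm, group_sd = gs,
         n_excluded = sum(!keep), config = config),
    class = "ip_dpa_result"
  )
}

#' @export
print.ip_dpa_result <- function(x, ...) {
  cat(sprintf(
    "<ip_dpa_result> %d participants: group mean %s ms (SD %s), %d excluded as unreliable\n",
    nrow(x$participants),
    if (is.na(x$group_mean)) "NA" else sprintf("%.1f", x$group_mean),
    if (is.na(x$group_sd)) "NA" else sprintf("%.1f", x$group_sd),
    x$n_excluded))
  invisible(x)
}

#' Compare per-participant divergence estimates between two conditions
#'
#' A paired (default) or Welch two-sample t test on the vectors of
#' individual divergence point estimates, the standard follow-up for asking
#' whether an experimental manipulation shifted the onset. For the paired
#' test, named vectors are aligned by participant id; incomplete pairs
#' (either estimate `NA`) are dropped.
#'
#' @param a,b numeric vectors of per-participant estimates (ms), optionally
#'   named by participant.
#' @param paired paired test (default) or Welch two-sample.
#' @return a list with `t`, `df`, `p_value`, `mean_difference` and `n`.
#' @export
compare_individual_estimates <- function(a, b, paired = TRUE) {
  if (paired) {
    if (!is.null(names(a)) && !is.null(names(b))) {
      common <- intersect(names(a), names(b))
      a <- a[common]
      b <- b[common]
    } else if (length(a) != length(b)) {
      stop("paired comparison needs equal-length (or named) vectors",
           call. = FALSE)
    }
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]
    b <- b[ok]
    if (length(a) < 2) {
      stop("fewer than 2 complete pairs of estimates", call. = FALSE)
    }
    n <- length(a)
    if (sd(a - b) == 0) {
      # degenerate pairs (constant difference): t.test would return NaN
      d <- mean(a - b)
      tt <- if (d == 0) 0 else sign(d) * Inf
      return(list(t = tt, df = n - 1, p_value = if (d == 0) 1 else 0,
                  mean_difference = d, n = n))
    }
    ht <- t.test(a, b, paired = TRUE)
  } else {
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      stop("fewer than 2 estimates in a group", call. = FALSE)
    }
    ht <- t.test(a, b, paired = FALSE, var.equal = FALSE)
    n <- c(length(a), length(b))
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = mean(a) - mean(b), n = n)
}
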