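#' One bootstrap iteration of group survival curves
#'
#' For each participant and condition, resamples with replacement as many
#' latencies as that cell holds, builds the per-participant survival curves,
#' and averages them (unweighted) across participants within condition.
#' This is the elementary step both group procedures repeat.
#'
#' @param table a [latency_table()].
#' @param config a [dpa_config()]; only `t_max` and `seed` are used here.
#' @return `list(slow = , fast = )` of [survival_curve()] objects.
#' @export
bootstrap_group_curves <- function(table, config = dpa_config("ci")) {
  stopifnot(inherits(table, "latency_table"))
  pools <- cell_pools(table)
  with_seed(config$seed, {
    one <- function(which_cond) {
      curves <- lapply(pools, function(pp) {
        pool <- pp[[which_cond]]
        survival_curve(resample_sorted(pool, length(pool)),
                       t_max = config$t_max)
      })
      group_average_curve(curves)
    }
    list(slow = one("slow"), fast = one("fast"))
  })
}

new_divergence_result <- function(procedure, estimate, ci_low, ci_high,
                                  iteration_estimates, detection_rate,
                                  config, per_bin_significant = NULL) {
  structure(
    list(procedure = procedure,
         estimate = estimate,
         ci_low = ci_low,
         ci_high = ci_high,
         iteration_estimates = iteration_estimates,
         detection_rate = detection_rate,
         per_bin_significant = per_bin_significant,
         n_iterations = config$n_iterations,
         config = config),
    class = "divergence_result"
  )
}

#' @export
print.divergence_result <- function(x, ...) {
  est <- if (is.na(x$estimate)) "none" else sprintf("%g ms", x$estimate)
  ci <- if (is.na(x$ci_low) || is.na(x$ci_high)) "" else
    sprintf(", 95%% CI [%g, %g] ms", x$ci_low, x$ci_high)
  cat(sprintf(
    "<divergence_result> %s DPA: estimate %s%s (detection rate %.3f, %d iterations)\n",
    x$procedure, est, ci, x$detection_rate, x$n_iterations))
  invisible(x)
}

#' Original group-level divergence point analysis
#'
#' Runs `n_iterations` bootstrap iterations of the group survival curves.
#' For every 1-ms bin the slow-minus-fast group differences across
#' iterations are sorted and the value at rank `ci_lower_index` (default
#' rank 5 of 10,000, i.e. the lower bound of a 99.9\% interval) is taken as
#' the lower confidence bound of the difference at that bin. A bin is
#' significant when this lower bound is strictly greater than zero, and the
#' divergence point is the first significant bin opening a run of
#' `run_length` (default 5) consecutive significant bins.
#'
#' This procedure yields a single onset estimate and no confidence interval
#' for it; `detection_rate` is 1 if an onset was found and 0 otherwise.
#' See [ci_dpa()] for the variant that attaches a CI to the estimate.
#'
#' @param table a [latency_table()].
#' @param config a [dpa_config()] (procedure `"original"`).
#' @return a `divergence_result` whose `per_bin_significant` element holds
#'   the per-bin logical significance vector (bins `0:t_max`).
#' @export
original_dpa <- function(table, config = dpa_config("original")) {
  stopifnot(inherits(table, "latency_table"),
            identical(config$procedure, "original"))
  pools <- cell_pools(table)
  with_seed(config$seed, {
    diffs <- boot_group_diff_matrix(pools, config$n_iterations, config$t_max)
    r <- config$ci_lower_index
    lower <- apply(diffs, 1L, function(v) sort.int(v, partial = r)[r])
    significant <- lower > 0
    start <- first_run_start(significant, config$run_length)
    estimate <- if (is.na(start)) NA_real_ else as.numeric(start - 1L) # bin 0 at index 1
    new_divergence_result(
      procedure = "original",
      estimate = estimate,
      ci_low = NA_real_, ci_high = NA_real_,
      iteration_estimates = numeric(0),
      detection_rate = if (is.na(start)) 0 else 1,
      config = config,
      per_bin_significant = significant
    )
  })
}

#' Divergence point of a single difference curve
#'
#' The within-iteration onset rule of the Confidence-Interval procedure:
#' the first 1-ms bin opening a run of `run_length` consecutive bins in
#' which the slow survival percent exceeds the fast by at least `threshold`
#' percentage points ("at least" means the comparison is `>=`).
#'
#' @param diff a [difference_curve()].
#' @param threshold qualifying difference in percentage points (default 1.5).
#' @param run_length required run of consecutive qualifying bins (default 5).
#' @return the onset bin in ms, or `NA_real_` if no qualifying run exists.
#' @export
iteration_divergence <- function(diff, threshold = 1.5, run_length = 5L) {
  stopifnot(inherits(diff, "difference_curve"))
  start <- first_run_start(diff$diff_pct >= threshold, as.integer(run_length))
  if (is.na(start)) NA_real_ else as.numeric(diff$t_ms[start])
}

#' Confidence-Interval divergence point analysis
#'
#' Identical resampling to [original_dpa()] but the divergence point is
#' located within every iteration: the first bin of a run of `run_length`
#' consecutive bins where the slow group survival percent is at least
#' `difference_threshold` (default 1.5) points above the fast. Across
#' iterations the detected onsets are sorted ascending; the median is the
#' divergence point estimate and the values at ranks `ci_lower_index` /
#' `ci_upper_index` (defaults 25 and 975 of 1,000) form the 95\% confidence
#' interval.
#'
#' Iterations in which no qualifying run exists are dropped before sorting;
#' the CI ranks are then rescaled to `round(0.025 m)` and `round(0.975 m)`
#' of the `m` retained values (floored at 1), and `detection_rate = m /
#' n_iterations` is reported so low-detection results can be judged. A
#' detection rate of zero yields an `NA` estimate with a warning.
#'
#' @inheritParams original_dpa
#' @param config a [dpa_config()] (procedure `"ci"`).
#' @return a `divergence_result` carrying the per-iteration onsets in
#'   `iteration_estimates`.
#' @export
ci_dpa <- function(table, config = dpa_config("ci")) {
  stopifnot(inherits(table, "latency_table"),
            identical(config$procedure, "ci"))
  pools <- cell_pools(table)
  with_seed(config$seed, {
    diffs <- boot_group_diff_matrix(pools, config$n_iterations, config$t_max)
    qual <- diffs >= config$difference_threshold
    bins <- 0:config$t_max
    starts <- vapply(seq_len(ncol(qual)), function(j) {
      first_run_start(qual[, j], config$run_length)
    }, integer(1))
    found <- bins[starts[!is.na(starts)]]
    m <- length(found)
    if (m == 0) {
      warning("ci_dpa: no iteration detected a divergence point",
              call. = FALSE)
      return(new_divergence_result("ci", NA_real_, NA_real_, NA_real_,
                                   numeric(0), 0, config))
    }
    sorted <- sort(found)
    if (m == config$n_iterations) {
      lo <- config$ci_lower_index
      hi <- config$ci_upper_index
    } else {
      lo <- max(1L, as.integer(round(0.025 * m)))
      hi <- min(m, max(lo, as.integer(round(0.975 * m))))
    }
    new_divergence_result(
      procedure = "ci",
      estimate = as.numeric(median(sorted)),
      ci_low = as.numeric(sorted[lo]),
      ci_high = as.numeric(sorted[hi]),
      iteration_estimates = as.numeric(found),
      detection_rate = m / config$n_iterations,
      config = config
    )
  })
}

#' Are two divergence-point confidence intervals disjoint?
#'
#' Two onset estimates are declared significantly different when their 95\%
#' confidence intervals do not overlap. Intervals are treated as closed, so
#' a shared endpoint counts as overlap -- the conservative convention when
#' claiming a difference between conditions.
#'
#' @param a,b `divergence_result` objects with confidence intervals.
#' @return `TRUE` if the intervals are disjoint, `FALSE` otherwise.
#' @export
compare_ci_overlap <- function(a, b) {
  for (r in list(a, b)) {
    if (!inherits(r, "divergence_result") ||
        is.na(r$ci_low) || is.na(r$ci_high)) {
      stop("both results must carry confidence intervals", call. = FALSE)
    }
  }
  a$ci_high < b$ci_low || b$ci_high < a$ci_low
}
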