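#' Procedure configuration
#'
#' Bundles the tunable parameters of the three divergence point procedures.
#' Defaults follow the standard published settings for each procedure:
#'
#' \describe{
#'   \item{original}{10,000 bootstrap iterations; a bin is significant when
#'     the lower bound of the per-bin 99.9\% interval of the slow-minus-fast
#'     difference (ranks 5 and 9,995 of the 10,000 sorted values) exceeds
#'     zero; onset = first bin of a run of 5 consecutive significant bins.}
#'   \item{ci}{1,000 iterations; within each iteration the onset is the
#'     first bin of a run of 5 consecutive bins with the slow survival
#'     percent at least 1.5 points above the fast; ranks 25 and 975 of the
#'     sorted per-iteration onsets form the 95\% confidence interval.}
#'   \item{ip}{per participant: 1,000 iterations, each drawing 1,200
#'     latencies with replacement from the slow and the fast pool, sorted
#'     and paired; onset = first pair of a run of 100 consecutive strictly
#'     positive paired differences.}
#' }
#'
#' When `n_iterations` is changed, the confidence-interval ranks are rescaled
#' proportionally (`round(0.0005 n)` / `round(0.9995 n)` for the original
#' per-bin interval, `round(0.025 n)` / `round(0.975 n)` for the CI
#' procedure, floored at 1), unless given explicitly.
#'
#' @param procedure `"original"`, `"ci"` or `"ip"`.
#' @param n_iterations number of bootstrap iterations.
#' @param run_length consecutive qualifying bins required to declare onset.
#' @param difference_threshold percent difference a bin must reach to
#'   qualify (CI procedure; the original uses the per-bin interval instead).
#' @param ci_lower_index,ci_upper_index 1-based ranks into the ascending
#'   sorted vector of iteration values.
#' @param resample_n resamples drawn per pool per iteration (IP procedure).
#' @param t_max last evaluated time bin, ms.
#' @param seed optional RNG seed recorded in results; when `NULL` the
#'   caller's RNG state is used as-is.
#'
#' @return a list of class `"dpa_config"`.
#' @examples
#' dpa_config("ci")
#' dpa_config("original", n_iterations = 1000)  # ranks rescale to 1 / 1000
#' @export
dpa_config <- function(procedure = c("original", "ci", "ip"),
                       n_iterations = NULL,
                       run_length = NULL,
                       difference_threshold = NULL,
                       ci_lower_index = NULL,
                       ci_upper_index = NULL,
                       resample_n = 1200L,
                       t_max = 600L,
                       seed = NULL) {
  procedure <- match.arg(procedure)
  defaults <- switch(procedure,
    original = list(n_iterations = 10000L, run_length = 5L,
                    difference_threshold = 0, lo_q = 0.0005, hi_q = 0.9995),
    ci       = list(n_iterations = 1000L, run_length = 5L,
                    difference_threshold = 1.5, lo_q = 0.025, hi_q = 0.975),
    ip       = list(n_iterations = 1000L, run_length = 100L,
                    difference_threshold = 0, lo_q = 0.025, hi_q = 0.975)
  )
  n_iterations <- as.integer(n_iterations %||% defaults$n_iterations)
  run_length <- as.integer(run_length %||% defaults$run_length)
  difference_threshold <-
    as.numeric(difference_threshold %||% defaults$difference_threshold)
  ci_lower_index <- as.integer(
    ci_lower_index %||% max(1, round(defaults$lo_q * n_iterations)))
  ci_upper_index <- as.integer(
    ci_upper_index %||% min(n_iterations, round(defaults$hi_q * n_iterations)))
  stopifnot(
    n_iterations >= 1, run_length >= 1, difference_threshold >= 0,
    resample_n >= 1, t_max >= 1,
    1 <= ci_lower_index, ci_lower_index < ci_upper_index,
    ci_upper_index <= n_iterations
  )
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(procedure = procedure,
         n_iterations = n_iterations,
         run_length = run_length,
         difference_threshold = difference_threshold,
         ci_lower_index = ci_lower_index,
         ci_upper_index = ci_upper_index,
         resample_n = as.integer(resample_n),
         t_max = as.integer(t_max),
         seed = seed),
    class = "dpa_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dpa_config <- function(x, ...) {
  cat(sprintf(
    "<dpa_config> procedure = %s | %d iterations, run of %d, threshold %.2f%%\n",
    x$procedure, x$n_iterations, x$run_length, x$difference_threshold))
  cat(sprintf("  CI ranks %d / %d; t_max %d ms; resample_n %d; seed %s\n",
              x$ci_lower_index, x$ci_upper_index, x$t_max, x$resample_n,
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}
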