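#' Empirical survival curve over 1-ms bins
#'
#' The survival percent at time `t` is the percentage of latencies strictly
#' greater than `t` ("surviving" responses are those not yet terminated at
#' `t`). The curve is evaluated at every integer millisecond from 0 to
#' `t_max`; bin 0 is included for convenience and always equals 100 when all
#' latencies are positive. Latencies themselves may be non-integer; strict
#' exceedance is evaluated against the raw values, the data are never
#' rounded. Latencies above `t_max` are retained in the data -- the curve is
#' simply not evaluated beyond `t_max`.
#'
#' @param latencies non-empty numeric vector of positive latencies (ms).
#' @param t_max last time bin to evaluate, in ms (default 600, the usual
#'   range for fixation durations; reaction-time tasks typically need more).
#' @param cell optional label (e.g. "participant p3, slow") used in the
#'   error message when `latencies` is empty.
#'
#' @return A `data.frame` of class `"survival_curve"` with columns `t_ms`
#'   (integers `0:t_max`) and `survival_pct` (values in `[0, 100]`,
#'   monotonically non-increasing).
#'
#' @examples
#' sc <- survival_curve(c(100, 200, 300))
#' sc$survival_pct[sc$t_ms == 0]    # 100: every latency exceeds 0
#' sc$survival_pct[sc$t_ms == 200]  # 33.3: strict ">", so only 300 survives
#' @export
survival_curve <- function(latencies, t_max = 600L, cell = NULL) {
  if (length(latencies) == 0) {
    where <- if (is.null(cell)) "" else paste0(" for cell ", cell)
    stop("empty latency pool", where, call. = FALSE)
  }
  stopifnot(is.numeric(latencies), all(is.finite(latencies)),
            all(latencies > 0), t_max >= 1)
  t_max <- as.integer(t_max)
  bins <- 0L:t_max
  n <- length(latencies)
  # count strictly > t == n - count(<= t); findInterval on the sorted pool
  # gives count(<= t) for each bin in one pass
  n_le <- findInterval(bins, sort(latencies))
  new_survival_curve(bins, 100 * (n - n_le) / n)
}

new_survival_curve <- function(bins, pct) {
  structure(
    data.frame(t_ms = as.integer(bins), survival_pct = as.numeric(pct)),
    class = c("survival_curve", "data.frame")
  )
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> bins 0..%d ms\n", max(x$t_ms)))
  NextMethod()
}

check_shared_grid <- function(a, b) {
  if (!identical(a$t_ms, b$t_ms)) {
    stop("survival curves are on different bin grids", call. = FALSE)
  }
}

#' Average survival curves across participants
#'
#' Per-bin unweighted arithmetic mean over participants. Participants are
#' the sampling unit, so each contributes equally regardless of how many
#' observations produced their curve; observation-weighted averaging is
#' deliberately not offered.
#'
#' @param curves a list of [survival_curve()] objects on an identical bin
#'   grid.
#' @return a `survival_curve` of the same grid.
#' @export
group_average_curve <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1)
  grid <- curves[[1]]$t_ms
  for (cv in curves) {
    if (!inherits(cv, "survival_curve")) {
      stop("all elements must be survival_curve objects", call. = FALSE)
    }
    if (!identical(cv$t_ms, grid)) {
      stop("survival curves are on different bin grids", call. = FALSE)
    }
  }
  mat <- vapply(curves, function(cv) cv$survival_pct, numeric(length(grid)))
  new_survival_curve(grid, rowMeans(as.matrix(mat)))
}

#' Slow-minus-fast survival difference curve
#'
#' Element-wise difference of two survival curves on the same grid, slow
#' minus fast. Positive values indicate the slow condition retains more
#' responses at that time.
#'
#' @param slow,fast [survival_curve()] objects on an identical bin grid.
#' @return A `data.frame` of class `"difference_curve"` with columns `t_ms`
#'   and `diff_pct` (values in `[-100, 100]`).
#' @export
difference_curve <- function(slow, fast) {
  stopifnot(inherits(slow, "survival_curve"), inherits(fast, "survival_curve"))
  check_shared_grid(slow, fast)
  structure(
    data.frame(t_ms = slow$t_ms,
               diff_pct = slow$survival_pct - fast$survival_pct),
    class = c("difference_curve", "data.frame")
  )
}

#' Write a survival curve to CSV
#'
#' Header `t_ms,survival_pct`.
#' @param curve a [survival_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival_curve <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
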