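#' Write a divergence result to a JSON envelope
#'
#' Serializes any procedure result together with the configuration that
#' produced it, so a run can be reproduced from its output alone. Missing
#' estimates are written as JSON `null`, never as 0. Numeric fields
#' round-trip exactly (full double precision).
#'
#' @param result a `divergence_result` (from [original_dpa()] / [ci_dpa()])
#'   or an `ip_dpa_result` (from [ip_dpa_group()]).
#' @param path output path.
#' @param iterations_csv optional path; when given, per-iteration divergence
#'   values (group procedures) or per-participant rows (IP procedure) are
#'   also written as CSV.
#' @return `path`, invisibly.
#' @seealso [read_dpa_result()]
#' @export
write_dpa_result <- function(result, path, iterations_csv = NULL) {
  env <- result_envelope(result)
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  if (!is.null(iterations_csv)) {
    if (inherits(result, "ip_dpa_result")) {
      write.csv(result$participants, iterations_csv, row.names = FALSE,
                quote = FALSE)
    } else {
      write.csv(data.frame(estimate_ms = result$iteration_estimates),
                iterations_csv, row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

result_envelope <- function(result) {
  cfg <- result$config
  config_echo <- list(
    procedure = cfg$procedure,
    n_iterations = cfg$n_iterations,
    run_length = cfg$run_length,
    difference_threshold = cfg$difference_threshold,
    ci_lower_index = cfg$ci_lower_index,
    ci_upper_index = cfg$ci_upper_index,
    resample_n = cfg$resample_n,
    t_max = cfg$t_max
  )
  base <- list(
    tool = "divpoint",
    version = as.character(packageVersion("divpoint")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = config_echo
  )
  if (inherits(result, "ip_dpa_result")) {
    c(base, list(
      procedure = "ip",
      estimate_ms = result$group_mean,
      group_sd_ms = result$group_sd,
      n_excluded = result$n_excluded,
      participants = result$participants
    ))
  } else if (inherits(result, "divergence_result")) {
    c(base, list(
      procedure = result$procedure,
      estimate_ms = result$estimate,
      ci_low_ms = result$ci_low,
      ci_high_ms = result$ci_high,
      detection_rate = result$detection_rate,
      n_iterations = result$n_iterations
    ))
  } else {
    stop("unsupported result class", call. = FALSE)
  }
}

#' Read a divergence-result JSON envelope
#'
#' @param path path written by [write_dpa_result()].
#' @return the parsed envelope as a list (numeric fields exact; JSON nulls
#'   become `NA`).
#' @export
read_dpa_result <- function(path) {
  env <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("estimate_ms", "ci_low_ms", "ci_high_ms", "group_sd_ms")) {
    if (f %in% names(env) && is.null(env[[f]])) env[[f]] <- NA_real_
  }
  env
}
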