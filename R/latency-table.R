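#' Construct a latency table
#'
#' A latency table is the universal long-format input of the package: one row
#' per observation, with a participant identifier, a condition label, and a
#' latency in milliseconds. Exactly two condition labels must be present, and
#' the caller states which label plays the "slow" role (the condition
#' expected to yield longer latencies) and which the "fast" role. The role
#' assignment always follows the supplied labels and is never inferred from
#' the data.
#'
#' @param participant vector of participant identifiers (coerced to character).
#' @param condition vector of condition labels (coerced to character).
#' @param latency_ms numeric vector of latencies in milliseconds; every value
#'   must be finite and strictly positive.
#' @param slow_label,fast_label the two condition labels and their roles.
#'
#' @return A `data.frame` of class `"latency_table"` with columns
#'   `participant`, `condition`, `latency_ms` and attributes `slow_label`
#'   and `fast_label`.
#'
#' @details Invariants enforced: all latencies finite and > 0; exactly the
#'   two stated labels occur; every (participant, condition) cell holds at
#'   least one observation (each participant appears in both conditions).
#'
#' @examples
#' tab <- latency_table(
#'   participant = rep(c("p1", "p2"), each = 4),
#'   condition   = rep(c("low", "low", "high", "high"), 2),
#'   latency_ms  = c(210, 260, 200, 230, 250, 280, 210, 240),
#'   slow_label = "low", fast_label = "high"
#' )
#' @export
latency_table <- function(participant, condition, latency_ms,
                          slow_label, fast_label) {
  df <- data.frame(
    participant = as.character(participant),
    condition = as.character(condition),
    latency_ms = as.numeric(latency_ms),
    stringsAsFactors = FALSE
  )
  validate_latency_table(df, slow_label, fast_label)
  structure(df,
    slow_label = as.character(slow_label),
    fast_label = as.character(fast_label),
    class = c("latency_table", "data.frame")
  )
}

#' Validate the latency-table invariants
#'
#' @param df data.frame with columns `participant`, `condition`, `latency_ms`.
#' @param slow_label,fast_label the two expected condition labels.
#' @return `df`, invisibly, if valid; otherwise an error listing every
#'   offending row.
#' @keywords internal
validate_latency_table <- function(df, slow_label, fast_label) {
  required <- c("participant", "condition", "latency_ms")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("latency table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  slow_label <- as.character(slow_label)
  fast_label <- as.character(fast_label)
  if (!nzchar(slow_label) || !nzchar(fast_label) ||
      identical(slow_label, fast_label)) {
    stop("slow_label and fast_label must be distinct non-empty labels",
         call. = FALSE)
  }
  problems <- character(0)
  bad_lat <- which(!is.finite(df$latency_ms) | df$latency_ms <= 0)
  if (length(bad_lat) > 0) {
    problems <- c(problems, sprintf(
      "row %d: latency_ms must be finite and > 0 (got %s)",
      bad_lat, as.character(df$latency_ms[bad_lat])))
  }
  bad_cond <- which(!(df$condition %in% c(slow_label, fast_label)))
  if (length(bad_cond) > 0) {
    problems <- c(problems, sprintf(
      "row %d: unknown condition '%s' (expected '%s' or '%s')",
      bad_cond, df$condition[bad_cond], slow_label, fast_label))
  }
  if (length(problems) > 0) {
    stop("invalid latency table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  for (lab in c(slow_label, fast_label)) {
    present <- unique(df$participant[df$condition == lab])
    absent <- setdiff(unique(df$participant), present)
    if (length(absent) > 0) {
      stop("empty (participant, condition) cell: participant(s) ",
           paste(absent, collapse = ", "), " have no '", lab,
           "' observations", call. = FALSE)
    }
  }
  if (nrow(df) == 0) stop("latency table has no rows", call. = FALSE)
  invisible(df)
}

#' @export
print.latency_table <- function(x, ...) {
  cat(sprintf(
    "<latency_table> %d observations, %d participants (slow = '%s', fast = '%s')\n",
    nrow(x), length(unique(x$participant)),
    attr(x, "slow_label"), attr(x, "fast_label")))
  NextMethod()
}

#' Read a latency table from CSV
#'
#' Expects a UTF-8 CSV with header `participant,condition,latency_ms`.
#' Rows whose condition is neither label, or whose latency is non-numeric or
#' non-positive, are reported together in a single validation error naming
#' the offending rows; no partial table is returned.
#'
#' @param path path to the CSV file.
#' @inheritParams latency_table
#' @return a [latency_table()].
#' @seealso [write_latency_table()]
#' @export
read_latency_table <- function(path, slow_label, fast_label) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("participant", "condition", "latency_ms")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  suppressWarnings(df$latency_ms <- as.numeric(df$latency_ms))
  latency_table(df$participant, df$condition, df$latency_ms,
                slow_label = slow_label, fast_label = fast_label)
}

#' Write a latency table to CSV
#'
#' @param table a [latency_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_latency_table <- function(table, path) {
  stopifnot(inherits(table, "latency_table"))
  write.csv(as.data.frame(table)[c("participant", "condition", "latency_ms")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Split a table into per-cell latency pools, sorted ascending.
# Returns a list keyed by participant, each element list(slow =, fast =).
# Participants are ordered by their first appearance in the table.
cell_pools <- function(table) {
  slow_lab <- attr(table, "slow_label")
  fast_lab <- attr(table, "fast_label")
  ids <- unique(table$participant)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    rows <- table$participant == id
    out[[id]] <- list(
      slow = sort(table$latency_ms[rows & table$condition == slow_lab]),
      fast = sort(table$latency_ms[rows & table$condition == fast_lab])
    )
  }
  out
}
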