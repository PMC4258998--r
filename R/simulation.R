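#' Pearson correlation between injected and estimated divergence points
#'
#' The parameter-recovery score: across participants with both a truth
#' value and an estimate, the Pearson correlation between the two.
#' Participants lacking an estimate (nothing detected, or excluded) are
#' dropped pairwise.
#'
#' @param truth named numeric vector, injected divergence point per
#'   participant (ms).
#' @param estimates named numeric vector of estimates (ms), `NA` allowed.
#' @return Pearson `r`.
#' @export
recovery_correlation <- function(truth, estimates) {
  if (!is.null(names(truth)) && !is.null(names(estimates))) {
    common <- intersect(names(truth), names(estimates))
    truth <- truth[common]
    estimates <- estimates[common]
  } else if (length(truth) != length(estimates)) {
    stop("truth and estimates must be named or of equal length",
         call. = FALSE)
  }
  ok <- !is.na(truth) & !is.na(estimates)
  if (sum(ok) < 3) {
    stop("fewer than 3 complete (truth, estimate) pairs", call. = FALSE)
  }
  cor(truth[ok], estimates[ok])
}

run_procedure_estimate <- function(procedure, table, config) {
  switch(procedure,
    original = original_dpa(table, config)$estimate,
    ci = ci_dpa(table, config)$estimate,
    ip = suppressWarnings(ip_dpa_group(table, config)$group_mean),
    stop("unknown procedure: ", procedure, call. = FALSE)
  )
}

default_config_for <- function(procedure, seed = NULL) {
  dpa_config(procedure, seed = seed)
}

#' Participant-subsampling robustness study
#'
#' Treats `table` as the population, computes a criterion divergence
#' estimate per procedure from the full sample, then repeatedly draws
#' participant subsets of each requested size without replacement (each of
#' the `n_samples` subsets drawn independently), re-runs each procedure on
#' each subset, and summarizes the minimum, maximum and mean estimate per
#' (procedure, size) cell. This exposes the small-sample bias of the
#' original procedure and the stability of the modified ones.
#'
#' @param table a [latency_table()]; the population.
#' @param sizes participant subset sizes (default `c(52, 26, 13)`).
#' @param n_samples subsets drawn per size (default 100).
#' @param procedures subset of `c("original", "ci", "ip")`.
#' @param configs optional named list of [dpa_config()] overrides per
#'   procedure (seeds inside are ignored; `seed` governs all randomness).
#' @param seed master seed for subset draws and procedure bootstraps.
#' @return a `data.frame` of class `"simulation_summary"` with columns
#'   `procedure`, `size`, `min`, `max`, `mean`, `n_detected`, `criterion`
#'   (the full-sample estimate for that procedure). Replicates where a
#'   procedure detected nothing are dropped from the summaries
#'   (`n_detected` counts the rest).
#' @export
simulation1 <- function(table, sizes = c(52L, 26L, 13L), n_samples = 100L,
                        procedures = c("original", "ci", "ip"),
                        configs = list(), seed = NULL) {
  stopifnot(inherits(table, "latency_table"))
  procedures <- match.arg(procedures, several.ok = TRUE)
  ids <- unique(table$participant)
  if (max(sizes) > length(ids)) {
    stop("subset size ", max(sizes), " exceeds the ", length(ids),
         "-participant population", call. = FALSE)
  }
  get_config <- function(proc, s) {
    cfg <- configs[[proc]] %||% default_config_for(proc)
    cfg$seed <- s
    cfg
  }
  rows <- list()
  for (proc in procedures) {
    crit_seed <- if (is.null(seed)) NULL else
      substream_seed(seed, paste0("criterion-", proc))
    criterion <- run_procedure_estimate(proc, table,
                                        get_config(proc, crit_seed))
    for (size in sizes) {
      ests <- vapply(seq_len(n_samples), function(rep_i) {
        sub_seed <- if (is.null(seed)) NULL else
          substream_seed(seed, sprintf("%s-%d-%d", proc, size, rep_i))
        sub_ids <- with_seed(sub_seed, sample(ids, size, replace = FALSE))
        sub_tab <- subset_participants(table, sub_ids)
        run_procedure_estimate(proc, sub_tab, get_config(proc, sub_seed))
      }, numeric(1))
      det <- ests[!is.na(ests)]
      rows[[length(rows) + 1L]] <- data.frame(
        procedure = proc, size = size,
        min = if (length(det)) min(det) else NA_real_,
        max = if (length(det)) max(det) else NA_real_,
        mean = if (length(det)) mean(det) else NA_real_,
        n_detected = length(det), criterion = criterion,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(do.call(rbind, rows),
            class = c("simulation_summary", "data.frame"))
}

# Restrict a latency table to a subset of participants.
subset_participants <- function(table, ids) {
  df <- as.data.frame(table)[table$participant %in% ids, , drop = FALSE]
  latency_table(df$participant, df$condition, df$latency_ms,
                slow_label = attr(table, "slow_label"),
                fast_label = attr(table, "fast_label"))
}

# Subsample each (participant, condition) cell down to per_cell
# observations, without replacement.
subsample_cells <- function(table, per_cell) {
  df <- as.data.frame(table)
  keep <- unlist(lapply(split(seq_len(nrow(df)),
                              list(df$participant, df$condition)),
                        function(idx) {
    if (length(idx) < per_cell) {
      stop("cell has only ", length(idx), " observations; cannot take ",
           per_cell, call. = FALSE)
    }
    sample(idx, per_cell, replace = FALSE)
  }), use.names = FALSE)
  df <- df[sort(keep), , drop = FALSE]
  latency_table(df$participant, df$condition, df$latency_ms,
                slow_label = attr(table, "slow_label"),
                fast_label = attr(table, "fast_label"))
}

#' Observation-subsampling parameter-recovery study
#'
#' Generates one artificial-effect population with known divergence points
#' (see [generate_simulation2_population()]), scores full-data recovery
#' with the Individual-Participant procedure, then for each reduced
#' per-condition observation count repeatedly subsamples every participant's
#' cells without replacement from that same parent population, re-runs the
#' procedure, and records the recovery correlation and mean estimate per
#' replicate. Set `fresh_population = TRUE` to regenerate a new parent
#' population for every replicate instead (a robustness variant).
#'
#' @param n_participants,per_cell,base,effect_spec population parameters
#'   passed to [generate_simulation2_population()].
#' @param subset_sizes reduced observations per cell (default
#'   `c(36, 24, 12)`); the full `per_cell` count is always scored once.
#' @param n_samples replicates per reduced size (default 100).
#' @param config a [dpa_config()] (procedure `"ip"`); its seed is ignored,
#'   `seed` governs all randomness.
#' @param seed master seed.
#' @param fresh_population regenerate the population each replicate?
#' @return a `data.frame` of class `"simulation_summary"` with columns
#'   `per_cell`, `n_samples`, `r_min`, `r_max`, `r_mean`, `est_min`,
#'   `est_max`, `est_mean` (estimates are the group means over reliable
#'   participants; correlations use all participants with estimates).
#' @export
simulation2 <- function(n_participants = 104L, per_cell = 60L,
                        base = exgaussian_params(),
                        effect_spec = artificial_effect_spec(),
                        subset_sizes = c(36L, 24L, 12L), n_samples = 100L,
                        config = dpa_config("ip"), seed = NULL,
                        fresh_population = FALSE) {
  stopifnot(identical(config$procedure, "ip"), all(subset_sizes <= per_cell))
  pop_seed <- if (is.null(seed)) NULL else substream_seed(seed, "population")
  pop <- generate_simulation2_population(n_participants, per_cell, base,
                                         effect_spec, seed = pop_seed)
  score <- function(tab, run_seed, truth) {
    cfg <- config
    cfg$seed <- run_seed
    res <- suppressWarnings(ip_dpa_group(tab, cfg))
    est <- res$participants$estimate_ms
    names(est) <- res$participants$participant
    list(r = recovery_correlation(truth, est),
         est_mean = res$group_mean)
  }
  full_seed <- if (is.null(seed)) NULL else substream_seed(seed, "full")
  full <- score(pop$table, full_seed, pop$truth)
  rows <- list(data.frame(
    per_cell = per_cell, n_samples = 1L,
    r_min = full$r, r_max = full$r, r_mean = full$r,
    est_min = full$est_mean, est_max = full$est_mean,
    est_mean = full$est_mean, stringsAsFactors = FALSE
  ))
  for (size in subset_sizes) {
    rs <- numeric(n_samples)
    ems <- numeric(n_samples)
    for (rep_i in seq_len(n_samples)) {
      key <- sprintf("subset-%d-%d", size, rep_i)
      rep_seed <- if (is.null(seed)) NULL else substream_seed(seed, key)
      if (fresh_population) {
        rep_pop <- generate_simulation2_population(n_participants, per_cell,
                                                   base, effect_spec,
                                                   seed = rep_seed)
        tab <- with_seed(rep_seed, subsample_cells(rep_pop$table, size))
        truth <- rep_pop$truth
      } else {
        tab <- with_seed(rep_seed, subsample_cells(pop$table, size))
        truth <- pop$truth
      }
      run_seed <- if (is.null(seed)) NULL else
        substream_seed(seed, paste0(key, "-run"))
      sc <- score(tab, run_seed, truth)
      rs[rep_i] <- sc$r
      ems[rep_i] <- sc$est_mean
    }
    rows[[length(rows) + 1L]] <- data.frame(
      per_cell = size, n_samples = n_samples,
      r_min = min(rs), r_max = max(rs), r_mean = mean(rs),
      est_min = min(ems, na.rm = TRUE), est_max = max(ems, na.rm = TRUE),
      est_mean = mean(ems, na.rm = TRUE), stringsAsFactors = FALSE
    )
  }
  structure(do.call(rbind, rows),
            class = c("simulation_summary", "data.frame"))
}
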