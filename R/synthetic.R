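#' Ex-Gaussian parameter set
#'
#' The ex-Gaussian -- a Gaussian convolved with an exponential -- is the
#' standard positively skewed model for response-latency data: its mean is
#' `mu + tau` and its variance `sigma^2 + tau^2`. The package default
#' (`mu = 176, sigma = 24, tau = 27`) gives a mean of about 203 ms with a
#' clear rightward skew and left-tail support reaching down to roughly
#' 110-120 ms, emulating a typical first-fixation-duration distribution.
#' Its SD (about 36 ms) is somewhat wider than the 26.7 ms a comparably
#' centred empirical fixation sample prints: matching that SD exactly with
#' an ex-Gaussian would truncate the left tail near 140 ms, because real
#' fixation distributions carry more low-latency mass than a Gaussian body
#' of equal SD. Support matters more than the SD for onset-recovery
#' behaviour, so the default trades SD fidelity for support fidelity.
#'
#' @param mu Gaussian mean, ms.
#' @param sigma Gaussian SD, ms (> 0).
#' @param tau exponential mean, ms (>= 0); `tau = 0` degenerates to a pure
#'   Gaussian.
#' @return a list of class `"exgaussian_params"`.
#' @export
exgaussian_params <- function(mu = 176, sigma = 24, tau = 27) {
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(tau),
            sigma > 0, tau >= 0)
  structure(list(mu = mu, sigma = sigma, tau = tau),
            class = "exgaussian_params")
}

#' Draw ex-Gaussian latencies
#'
#' `n` independent draws of `Normal(mu, sigma) + Exponential(mean = tau)`.
#' Draws that land at or below zero are redrawn (latencies must be strictly
#' positive); redrawing rather than clipping avoids a point mass at the
#' floor. With the default parameters non-positive draws are vanishingly
#' rare.
#'
#' @param n number of draws.
#' @param params an [exgaussian_params()].
#' @param seed optional RNG seed.
#' @return numeric vector of `n` positive latencies (ms).
#' @export
sample_exgaussian <- function(n, params = exgaussian_params(), seed = NULL) {
  stopifnot(inherits(params, "exgaussian_params"), n >= 1)
  with_seed(seed, {
    draw <- function(k) {
      g <- rnorm(k, params$mu, params$sigma)
      if (params$tau > 0) g <- g + rexp(k, rate = 1 / params$tau)
      g
    }
    x <- draw(n)
    while (any(x <= 0)) {
      bad <- which(x <= 0)
      x[bad] <- draw(length(bad))
    }
    x
  })
}

#' Artificial-effect specification
#'
#' Describes how a slow condition with a known, injectable divergence point
#' is manufactured from a fast condition: every latency below the
#' participant's assigned divergence value `d` is copied unchanged, and a
#' random `proportion` (default 50\%) of the latencies at or above `d` are
#' lengthened by `delta` (default 50 ms). The default divergence values are
#' 26 levels from 110 to 210 ms in 4-ms steps, each assigned to a group of
#' participants, giving a truth-map mean of exactly 160 ms.
#'
#' @param divergence_values ms; the distinct injected divergence points.
#' @param delta ms added to each lengthened latency (> 0).
#' @param proportion fraction of eligible latencies lengthened, in (0, 1].
#' @return a list of class `"artificial_effect_spec"`.
#' @export
artificial_effect_spec <- function(divergence_values = seq(110, 210, by = 4),
                                   delta = 50, proportion = 0.5) {
  stopifnot(all(divergence_values > 0), delta > 0,
            proportion > 0, proportion <= 1)
  structure(list(divergence_values = as.numeric(divergence_values),
                 delta = as.numeric(delta),
                 proportion = as.numeric(proportion)),
            class = "artificial_effect_spec")
}

#' Manufacture a slow condition with a known divergence point
#'
#' @param fast numeric vector of fast-condition latencies (ms).
#' @param d_sim the injected divergence point (ms).
#' @param delta lengthening added to the selected latencies (ms).
#' @param proportion fraction of eligible (`>= d_sim`) latencies lengthened;
#'   the subset size is `round(proportion * n_eligible)` (round half to
#'   even) and the subset is chosen uniformly at random.
#' @param seed optional RNG seed.
#' @return numeric vector of the same length and order as `fast`: values
#'   `< d_sim` identical, each eligible value either identical or exactly
#'   `delta` larger.
#' @export
make_artificial_slow <- function(fast, d_sim, delta = 50, proportion = 0.5,
                                 seed = NULL) {
  stopifnot(length(fast) >= 1, d_sim > 0, delta > 0,
            proportion > 0, proportion <= 1)
  with_seed(seed, {
    slow <- fast
    eligible <- which(fast >= d_sim)
    k <- round(proportion * length(eligible))
    if (k > 0) {
      pick <- if (length(eligible) == 1) eligible else
        sample(eligible, k, replace = FALSE)
      slow[pick] <- slow[pick] + delta
    }
    slow
  })
}

#' Generate an artificial-effect population with known divergence points
#'
#' Builds the standard parameter-recovery population: `n_participants`
#' participants are split evenly across the distinct injected divergence
#' values of `effect_spec` (default 104 participants over 26 values, 4
#' each), group membership assigned at random. Each participant's fast cell
#' is `per_cell` ex-Gaussian draws and the slow cell is
#' [make_artificial_slow()] applied to that same fast cell, so the truth is
#' known exactly per participant.
#'
#' @param n_participants number of participants; must be divisible by the
#'   number of distinct divergence values.
#' @param per_cell observations per condition per participant (default 60).
#' @param base an [exgaussian_params()] for the fast condition.
#' @param effect_spec an [artificial_effect_spec()].
#' @param seed optional RNG seed.
#' @return `list(table = latency_table, truth = named numeric)` where
#'   `truth[participant]` is the injected divergence point in ms.
#' @export
generate_simulation2_population <- function(n_participants = 104L,
                                            per_cell = 60L,
                                            base = exgaussian_params(),
                                            effect_spec = artificial_effect_spec(),
                                            seed = NULL) {
  stopifnot(inherits(effect_spec, "artificial_effect_spec"),
            n_participants >= 1, per_cell >= 1)
  n_groups <- length(effect_spec$divergence_values)
  if (n_participants %% n_groups != 0) {
    stop("n_participants (", n_participants, ") must be divisible by the ",
         "number of divergence values (", n_groups, ")", call. = FALSE)
  }
  with_seed(seed, {
    ids <- sprintf("p%03d", seq_len(n_participants))
    # random division into equal groups, one divergence value per group
    pool <- rep(effect_spec$divergence_values,
                each = n_participants / n_groups)
    d_sim <- if (length(pool) == 1) pool else sample(pool)
    names(d_sim) <- ids
    fast <- lapply(seq_len(n_participants), function(i) {
      sample_exgaussian(per_cell, base)
    })
    slow <- lapply(seq_len(n_participants), function(i) {
      make_artificial_slow(fast[[i]], d_sim[i],
                           delta = effect_spec$delta,
                           proportion = effect_spec$proportion)
    })
    tab <- latency_table(
      participant = rep(ids, each = 2 * per_cell),
      condition = rep(rep(c("slow", "fast"), each = per_cell),
                      n_participants),
      latency_ms = unlist(lapply(seq_len(n_participants), function(i) {
        c(slow[[i]], fast[[i]])
      })),
      slow_label = "slow", fast_label = "fast"
    )
    list(table = tab, truth = d_sim)
  })
}

#' Generate a null population (no true divergence)
#'
#' Slow and fast cells are drawn independently from the same ex-Gaussian,
#' so any detected divergence is a false alarm. Used to calibrate the
#' specificity of the procedures.
#'
#' @inheritParams generate_simulation2_population
#' @return a [latency_table()].
#' @export
generate_null_population <- function(n_participants = 52L, per_cell = 60L,
                                     base = exgaussian_params(),
                                     seed = NULL) {
  stopifnot(n_participants >= 1, per_cell >= 1)
  with_seed(seed, {
    ids <- sprintf("p%03d", seq_len(n_participants))
    latency_table(
      participant = rep(ids, each = 2 * per_cell),
      condition = rep(rep(c("slow", "fast"), each = per_cell),
                      n_participants),
      latency_ms = unlist(lapply(seq_len(n_participants), function(i) {
        sample_exgaussian(2 * per_cell, base)
      })),
      slow_label = "slow", fast_label = "fast"
    )
  })
}
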