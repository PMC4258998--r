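test_that("pair_iteration produces sorted, paired resamples", {
  p <- pair_iteration(rep(300, 4), rep(100, 7), resample_n = 1200)
  expect_true(all(p$slow_sorted == 300))
  expect_true(all(p$fast_sorted == 100))
  expect_true(all(p$diff == 200))
  # survival decrement per bin is 1/1200 * 100
  expect_equal(unique(round(-diff(p$survival_pct), 10)), 1 / 1200 * 100)
  expect_equal(p$survival_pct[1], 100 - 1 / 1200 * 100)
  set.seed(31)
  q <- pair_iteration(runif(40, 100, 400), runif(25, 100, 400))
  expect_length(q$slow_sorted, 1200)
  expect_true(!is.unsorted(q$slow_sorted))
  expect_true(!is.unsorted(q$fast_sorted))
  expect_error(pair_iteration(numeric(0), 1:3, cell = "p9 slow"),
               "empty slow pool.*p9")
})

test_that("the attached survival percent matches strict-exceedance survival", {
  # for a distinct-valued sorted sample, 100 - i/n*100 equals the
  # strict-exceedance survival of that sample evaluated at s_i
  # (oracle check against survival_core)
  set.seed(32)
  s <- sort(sample(50:500, 30))
  p <- make_pairs(s, s - 10)
  sc <- survival_curve(s, t_max = 600)
  expect_equal(p$survival_pct, sc$survival_pct[match(s, sc$t_ms)])
})

test_that("the run-of-k positive-difference rule finds the first pair", {
  pm <- make_pairs(rep(300, 1200), rep(100, 1200))
  expect_equal(iteration_individual_divergence(pm, 100), 200)
  # strict inequality: identical sequences never qualify
  same <- make_pairs(rep(250, 1200), rep(250, 1200))
  expect_true(is.na(iteration_individual_divergence(same, 100)))
  # a run of 99 is one short
  f <- rep(100, 1200)
  s <- f
  s[500:598] <- 200
  expect_true(is.na(iteration_individual_divergence(make_pairs(s, f), 100)))
  expect_equal(iteration_individual_divergence(make_pairs(s, f), 99),
               (200 + 100) / 2)
})

test_that("point-mass pools give an exact individual estimate of 200 ms", {
  r <- ip_dpa_participant(rep(300, 6), rep(100, 9),
                          dpa_config("ip", n_iterations = 50, seed = 33),
                          participant_id = "pm")
  expect_equal(r$estimate, 200)
  expect_equal(r$detection_rate, 1)
  expect_true(r$reliable)
})

test_that("detected divergence values are shift-equivariant", {
  set.seed(34)
  fast <- sample_exgaussian(50)
  slow <- make_artificial_slow(fast, 150)
  cfg <- dpa_config("ip", n_iterations = 100, seed = 35)
  base <- ip_dpa_participant(slow, fast, cfg)
  for (shift in c(25, 250)) {
    moved <- ip_dpa_participant(slow + shift, fast + shift, cfg)
    expect_equal(moved$iteration_values, base$iteration_values + shift)
    expect_equal(moved$estimate, base$estimate + shift)
    expect_equal(moved$detection_rate, base$detection_rate)
  }
})

test_that("individual estimates agree with the naive oracle", {
  set.seed(21)
  fast <- sample_exgaussian(60)
  slow <- make_artificial_slow(fast, 150)
  set.seed(36)
  nv <- naive_ip_participant(slow, fast, 400, 1200, 100)
  pk <- ip_dpa_participant(slow, fast,
                           dpa_config("ip", n_iterations = 400, seed = 37))
  expect_equal(nv$detection_rate, 1)
  expect_equal(pk$detection_rate, 1)
  # medians hop between neighbouring discrete pair values; pilot runs show
  # both implementations share the same candidate set within a few ms
  expect_lt(abs(nv$estimate - pk$estimate), 8)
})

test_that("identical pools leave most iterations without a divergence", {
  # ties from the shared pool break strict-inequality runs
  set.seed(38)
  unreliable <- vapply(1:10, function(k) {
    pool <- sample_exgaussian(60)
    r <- ip_dpa_participant(pool, pool,
                            dpa_config("ip", n_iterations = 60,
                                       seed = 380 + k))
    !r$reliable
  }, logical(1))
  expect_gte(mean(unreliable), 0.8)
})

test_that("group IP results are invariant to participant row order", {
  tab <- strong_effect_table(n_participants = 5, n_obs = 30, seed = 39)
  cfg <- dpa_config("ip", n_iterations = 60, seed = 40)
  res1 <- ip_dpa_group(tab, cfg)
  # permute rows, rebuild the table
  set.seed(41)
  perm <- sample(nrow(tab))
  tab2 <- latency_table(tab$participant[perm], tab$condition[perm],
                        tab$latency_ms[perm], "slow", "fast")
  res2 <- ip_dpa_group(tab2, cfg)
  m1 <- res1$participants[order(res1$participants$participant), ]
  m2 <- res2$participants[order(res2$participants$participant), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
  expect_equal(res1$group_mean, res2$group_mean)
})

test_that("group summaries use reliable participants only", {
  # half point-mass pairs (always detected), half identical-pool nulls
  ids <- c("a", "b", "c", "d")
  set.seed(42)
  null_pool <- sample_exgaussian(40)
  df <- rbind(
    data.frame(participant = "a",
               condition = rep(c("slow", "fast"), each = 10),
               latency_ms = rep(c(300, 100), each = 10)),
    data.frame(participant = "b",
               condition = rep(c("slow", "fast"), each = 10),
               latency_ms = rep(c(320, 120), each = 10)),
    data.frame(participant = "c",
               condition = rep(c("slow", "fast"), each = 40),
               latency_ms = rep(null_pool, 2)),
    data.frame(participant = "d",
               condition = rep(c("slow", "fast"), each = 40),
               latency_ms = rep(rev(null_pool), 2))
  )
  tab <- latency_table(df$participant, df$condition, df$latency_ms,
                       "slow", "fast")
  res <- ip_dpa_group(tab, dpa_config("ip", n_iterations = 80, seed = 43))
  pa <- res$participants
  expect_true(all(pa$reliable[pa$participant %in% c("a", "b")]))
  if (res$n_excluded == 2) {
    expect_equal(res$group_mean, mean(c(200, 220)))
  }
  expect_equal(res$n_excluded,
               sum(!pa$reliable | is.na(pa$estimate_ms)))
})

test_that("paired comparison of individual estimates matches closed form", {
  # differences {10, 20, 30}: t = 20 / (10/sqrt(3)), df = 2
  a <- c(p1 = 150, p2 = 170, p3 = 190)
  b <- c(p1 = 140, p2 = 150, p3 = 160)
  out <- compare_individual_estimates(a, b, paired = TRUE)
  expect_equal(out$t, 20 / (10 / sqrt(3)), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$mean_difference, 20)

  # a == b: degenerate zero-difference case
  same <- compare_individual_estimates(a, a, paired = TRUE)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # constant shift with spread: positive t with df n-1
  set.seed(44)
  x <- rnorm(12, 150, 20)
  shifted <- compare_individual_estimates(x + 24 + rnorm(12, 0, 5), x)
  expect_gt(shifted$t, 0)
  expect_equal(shifted$df, 11)

  expect_error(compare_individual_estimates(c(a = 1), c(a = 2)),
               "fewer than 2")
})
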