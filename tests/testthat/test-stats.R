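mk_outcomes <- function(first, second, amp = NULL, eligible = TRUE,
                        type = "cs_alone") {
  n <- length(first)
  data.frame(trial_id = seq_len(n), type = type, first_present = first,
             first_amp = if (is.null(amp)) ifelse(first, 4, 0.1) else amp,
             second_present = second, second_amp = ifelse(second, 3, 0.1),
             second_eligible = rep_len(eligible, n),
             stringsAsFactors = FALSE)
}

test_that("session summary counts probabilities per their definitions", {
  o <- mk_outcomes(rep(c(TRUE, FALSE), c(8, 2)),
                   rep(c(TRUE, FALSE), c(4, 6)))
  ss <- session_summary(o)
  expect_equal(ss$p_first, 0.8)
  expect_equal(ss$p_second, 0.5)

  # no first CRs: second-CR probability undefined, not zero
  none <- mk_outcomes(rep(FALSE, 5), rep(FALSE, 5))
  expect_true(is.na(session_summary(none)$p_second))

  # generated session: estimates inside exact binomial 95% CIs of the truth
  s <- generate_session(protocol_config("ipsilateral", n_blocks = 48,
                                        trials_per_block = 1),
                        gen_params(p_first_cr = 0.9, first_amp_mean = 4.5,
                                   first_amp_sd = 0.4), seed = 19)
  o <- decompose_session(s)$outcomes
  ss <- session_summary(o)
  ci1 <- binom.test(ss$n_first, ss$n_trials, 0.9)$conf.int
  expect_true(ci1[1] <= 0.9 && 0.9 <= ci1[2])
  # nearly all first CRs are supra-gate here, so p_second ~ 0.7
  ci2 <- binom.test(round(ss$p_second * ss$n_second_denom),
                    ss$n_second_denom, 0.7)$conf.int
  expect_true(ci2[1] <= 0.7 && 0.7 <= ci2[2])
})

test_that("extinction curve partitions trials with the remainder first", {
  o <- mk_outcomes(rep(TRUE, 96), rep(c(TRUE, FALSE), 48))
  cv <- extinction_curve(o)
  expect_equal(cv$n_trials, rep(12, 8))
  o2 <- mk_outcomes(rep(TRUE, 100), rep(c(TRUE, FALSE), 50))
  expect_equal(extinction_curve(o2)$n_trials, c(13, 13, 13, 13, 12, 12, 12, 12))
  expect_equal(sum(extinction_curve(o2)$n_trials), 100)
  expect_error(extinction_curve(o[1:5, ]), "fewer")

  # a generated schedule with decaying chain probability declines through
  # the session
  sched <- seq(0.9, 0.05, length.out = 200)
  s <- generate_session(protocol_config("ipsilateral", n_blocks = 200,
                                        trials_per_block = 1),
                        gen_params(p_second_given_gate = sched), seed = 23)
  cv <- extinction_curve(decompose_session(s)$outcomes)
  expect_lt(cor(cv$portion, cv$p_second), -0.8)
  expect_gt(cv$p_second[1], tail(cv$p_second, 1))
})

test_that("conditional second-CR probability is estimated per amplitude bin", {
  # degenerate bin: all second CRs present
  o <- mk_outcomes(rep(TRUE, 30), rep(TRUE, 30), amp = rep(3.5, 30))
  cp <- conditional_probability(o, seed = 1)
  row <- cp$table[cp$table$bin == "3-4", ]
  expect_equal(row$p_second, 1)
  expect_equal(c(row$ci_low, row$ci_high), c(1, 1))

  # 25 of 50: percentile bootstrap CI sits inside the exact binomial CI
  o <- mk_outcomes(rep(TRUE, 50), rep(c(TRUE, FALSE), 25), amp = rep(2.5, 50))
  cp <- conditional_probability(o, seed = 2)
  row <- cp$table[cp$table$bin == "2-3", ]
  expect_equal(row$p_second, 0.5)
  expect_gte(row$ci_low, 0.34)
  expect_lte(row$ci_high, 0.66)

  # empty bins are excluded from the chi-square with df reduced
  o3 <- mk_outcomes(rep(TRUE, 60), rep(c(TRUE, FALSE), 30),
                    amp = rep(c(0.1, 2.5, 3.5), each = 20))
  cp3 <- conditional_probability(o3, seed = 3)
  expect_equal(cp3$df, 2)
  expect_equal(sum(cp3$table$n > 0), 3)

  # independence between amplitude and second CR: ~5% rejections at 0.05
  set.seed(9)
  rej <- vapply(1:150, function(r) {
    amp <- runif(140, 0.35, 5.9)
    oo <- mk_outcomes(rep(TRUE, 140), runif(140) < 0.5, amp = amp)
    p <- conditional_probability(oo, n_boot = 10, seed = r)$p_value
    !is.na(p) && p < 0.05
  }, NA)
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.12)
})

test_that("normalized-fraction times invert the profile", {
  t <- trial_time_grid()
  ramp <- approx(c(-200, 300, 500, 2299), c(0, 0, 4, 4), xout = t)$y
  ft <- fraction_times(ramp, t, onset = 300, peak_time = 500)
  expect_equal(ft$time_ms[ft$fraction == 1], 500)
  expect_equal(ft$time_ms[ft$fraction == 0.5], 400, tolerance = 1e-9)
  expect_equal(ft$time_ms[ft$fraction == 0.25], 350, tolerance = 1e-9)
  expect_equal(diff(ft$fraction)[1], 0.005)
  # the inverted ramp is linear in the fraction
  fit <- lm(time_ms ~ fraction, data = ft)
  expect_equal(unname(coef(fit)[2]), 200, tolerance = 1e-6)

  coarse <- fraction_times(ramp, t, onset = 300, peak_time = 500, step = 0.5)
  expect_lte(nrow(coarse), 3)
  expect_gte(nrow(coarse), 2)
})

test_that("timing co-variation applies thresholds and outlier removal", {
  ev <- function(id, idx, lat, amp)
    data.frame(trial_id = id, eye = "left", index_in_sequence = idx,
               onset = lat - 10, latency_to_criterion = lat, amplitude = amp,
               peak_time = lat + 150, t_peak_velocity = lat + 40,
               t_half_peak = lat + 60, t_90_peak = lat + 120)
  lat1 <- c(300, 320, 340, 360, 380)
  events <- do.call(rbind, c(
    lapply(seq_along(lat1), function(i) ev(i, 1, lat1[i], 4)),
    lapply(seq_along(lat1), function(i) ev(i, 2, lat1[i] + 600, 3))))
  outc <- mk_outcomes(rep(TRUE, 5), rep(TRUE, 5))
  tp <- timing_covariation(events, outc)
  expect_equal(tp$r, 1)
  expect_equal(tp$intervals, rep(600, 5))

  # sub-threshold amplitudes are excluded
  events$amplitude[events$trial_id == 3] <- 1.5
  expect_equal(timing_covariation(events, outc)$n, 4)

  # an outlying pair is discarded before the correlation
  lat1 <- seq(260, 420, by = 4)
  n <- length(lat1)
  set.seed(4)
  lat2 <- lat1 + 600 + rnorm(n, 0, 5)
  lat2[10] <- lat1[10] + 1300  # ~10 SD out in the second coordinate
  events <- do.call(rbind, c(
    lapply(seq_len(n), function(i) ev(i, 1, lat1[i], 4)),
    lapply(seq_len(n), function(i) ev(i, 2, lat2[i], 3))))
  tp <- timing_covariation(events, mk_outcomes(rep(TRUE, n), rep(TRUE, n)))
  expect_equal(tp$n_outliers, 1)
  expect_equal(tp$n, n - 1)
  expect_gt(tp$r, 0.9)
})

test_that("shuffle null is invariant on degenerate data and detects chaining", {
  # identical pairs: shuffling changes nothing
  sh <- shuffle_null(rep(300, 10), rep(900, 10), n_perm = 50, seed = 1)
  expect_equal(sh$ks_stat, 0)
  expect_gt(sh$p, 0.9)

  # chained generator: tight intervals against a broad shuffled pool
  s <- cs_alone_session(160, seed = 31, interval_jitter_sd = 20, noise_sd = 0)
  p <- truth_pairs(s, 100)
  sh <- shuffle_null(p$t1, p$t2, n_perm = 500, seed = 2)
  expect_lt(sh$p, 0.01)
  expect_lt(sh$ks_p, 0.01)
  expect_equal(length(sh$shuffled_intervals), 500 * length(p$t1))
})

test_that("CS2 transfer separates feedback-driven from CS-bound chaining", {
  o <- rbind(
    mk_outcomes(rep(TRUE, 20), rep(c(TRUE, FALSE), c(18, 2)), type = "paired"),
    mk_outcomes(rep(c(TRUE, FALSE), c(10, 12)),
                c(rep(c(TRUE, FALSE), c(9, 1)), rep(FALSE, 12)),
                type = "cs2_alone"))
  ct <- cs2_transfer(list(o))
  expect_equal(ct$per_session$p_cs1, 0.9)
  expect_equal(ct$per_session$p_cs2, 0.9)
  expect_equal(ct$per_session$p_cs2_nofirst, 0)

  # a session missing a trial type yields NA for that group
  ct2 <- cs2_transfer(list(o[o$type == "paired", ]))
  expect_true(is.na(ct2$per_session$p_cs2))
})
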