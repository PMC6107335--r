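test_that("inverse-ISI rate estimation matches constant and alternating trains", {
  tt <- seq(0, 5000)
  rs <- instantaneous_rate(seq(0, 5000, by = 20), tt)
  expect_false(rs$flagged)
  expect_lt(max(abs(rs$rate[tt > 100 & tt < 4900] - 50)), 0.5)

  # single spike: flagged zero series
  rs1 <- instantaneous_rate(1000, tt)
  expect_true(rs1$flagged)
  expect_equal(rs1$rate, numeric(length(tt)))

  # alternating 10/20 ms ISIs: piecewise rates 100/50 Hz (narrow kernel)
  sp <- cumsum(c(0, rep(c(10, 20), 60)))
  rs <- instantaneous_rate(sp, seq(0, 1700), kernel_sd = 0.2)
  expect_equal(rs$rate[306], 100, tolerance = 1)  # inside a 10 ms ISI
  expect_equal(rs$rate[316], 50, tolerance = 1)   # inside a 20 ms ISI

  expect_error(instantaneous_rate(c(30, 10, 20), tt), "sorted")
})

test_that("baseline normalization rescales to dimensionless rates", {
  tt <- seq(-1500, 2299)
  rs <- instantaneous_rate(seq(-1500, 2299, by = 12.5), tt)  # 80 Hz
  nr <- normalize_rate(rs)
  expect_equal(mean(nr$rate[tt < 0]), 1, tolerance = 1e-6)
  expect_equal(nr$baseline_hz, 80, tolerance = 0.5)

  # 80 Hz baseline with a 40 Hz dip reads 0.5
  sp <- sort(c(seq(-1500, 499, by = 12.5), seq(500, 999, by = 25),
               seq(1000, 2299, by = 12.5)))
  nr <- normalize_rate(instantaneous_rate(sp, tt))
  expect_equal(mean(nr$rate[tt > 600 & tt < 900]), 0.5, tolerance = 0.05)

  # Poisson baseline: 50-trial average near 1
  set.seed(41)
  mats <- t(replicate(50, {
    sp <- cumsum(rexp(500, 70 / 1000)) - 1500
    normalize_rate(instantaneous_rate(sp[sp < 2299], tt))$rate
  }))
  avg <- colMeans(mats)
  expect_gt(mean(avg[tt < 0]), 0.97)
  expect_lt(mean(avg[tt < 0]), 1.03)
})

test_that("unit classification requires a pause and US-locked complex spikes", {
  pc <- pc_gen_params(p_cs_given_us = 0.9, spont_cs_rate = 0.5)
  tt <- seq(-1500, 2299)
  flat <- numeric(length(tt))
  gather <- function(pc, us_on, n_trials = 40, seed = 51) {
    set.seed(seed)
    simple <- c(); cx <- c(); us <- c()
    for (i in seq_len(n_trials)) {
      off <- (i - 1) * 5000
      st <- generate_spike_train(list(profile = flat, t = tt,
                                      us_time = if (us_on) 500 else NA), pc)
      simple <- c(simple, st$time_ms[st$spike_type == "simple"] + off)
      cx <- c(cx, st$time_ms[st$spike_type == "complex"] + off)
      if (us_on) us <- c(us, 500 + off)
    }
    list(simple = simple, cx = cx, us = us)
  }
  d <- gather(pc, us_on = TRUE)
  v <- verify_eyelid_pc(d$simple, d$cx, d$us)
  expect_equal(v$classification, "eyelid_pc")
  expect_gte(v$us_cs_fraction, 0.5)

  # complex spikes never US-locked
  d <- gather(pc_gen_params(cs_locked_to_us = FALSE, spont_cs_rate = 1),
              us_on = TRUE, seed = 52)
  expect_equal(verify_eyelid_pc(d$simple, d$cx, d$us)$classification,
               "non_eyelid_pc")

  # no complex spikes at all
  d <- gather(pc_gen_params(has_complex = FALSE), us_on = TRUE, seed = 53)
  expect_equal(verify_eyelid_pc(d$simple, d$cx, d$us)$classification,
               "not_pc")

  # no US trials: eyelid-PC status undefined
  d <- gather(pc, us_on = FALSE, seed = 54)
  expect_warning(v <- verify_eyelid_pc(d$simple, d$cx, numeric()),
                 "undefined")
  expect_true(is.na(v$classification))
})

test_that("trial grouping splits CR trials evenly after the non-CR group", {
  o <- data.frame(trial_id = 1:12,
                  first_present = c(rep(TRUE, 9), FALSE, FALSE, FALSE),
                  first_onset = c(9:1 * 10, NA, NA, NA),
                  first_amp = c(rep(4, 9), 0.1, 0.1, 0.1),
                  second_present = FALSE, second_onset = NA_real_,
                  second_amp = NA_real_, second_eligible = TRUE)
  g <- group_trials(o, "first_onset")
  expect_equal(g$non_cr, 10:12)
  expect_equal(lengths(g$groups), c(3L, 3L, 3L))
  # ordered by increasing onset: onsets are 90..10 over trials 1..9
  expect_equal(g$groups[[1]], c(9, 8, 7))
  # partition: every eligible trial in exactly one group
  all_ids <- c(g$non_cr, unlist(g$groups))
  expect_equal(sort(all_ids), 1:12)

  o10 <- o[c(1:9, 1:1), ]; o10$trial_id <- 1:10
  o10$first_onset <- 1:10; o10$first_present <- TRUE
  expect_equal(lengths(group_trials(o10, "first_onset")$groups), c(4L, 3L, 3L))
  expect_error(group_trials(o[10:12, ], "first_onset"), "fewer")
})

test_that("pointwise averages, CIs and separation behave at the extremes", {
  tt <- 0:99
  same <- matrix(rep(sin(tt / 10), 5), 5, byrow = TRUE)
  av <- average_with_ci(same, tt)
  expect_equal(av$rate, sin(tt / 10))
  expect_equal(av$ci_low, av$ci_high)

  a <- average_with_ci(matrix(0.4 + rnorm(500, 0, 0.01), 5), tt)
  b <- average_with_ci(matrix(1.0 + rnorm(500, 0, 0.01), 5), tt)
  expect_true(all(ci_separation(a, b)))
  expect_error(average_with_ci(matrix(1, 1, 100), tt), "2 trials")

  # spurious separation of two null groups at a fixed point is rare
  set.seed(61)
  sep <- replicate(200, {
    g1 <- average_with_ci(matrix(rnorm(20 * 50, 1, 0.2), 20), 1:50)
    g2 <- average_with_ci(matrix(rnorm(20 * 50, 1, 0.2), 20), 1:50)
    ci_separation(g1, g2)[25]
  })
  expect_lte(mean(sep), 0.05)
})

test_that("CR-onset alignment shifts consistently and recovers the lead", {
  tt <- seq(-1500, 2299)
  # constant onsets: alignment is a constant shift
  base <- 1 - 0.3 * exp(-((tt - 400) / 100)^2)
  mat <- rbind(base, base, base)
  al <- align_to_cr_onset(mat, tt, onsets = c(400, 400, 400),
                          window = c(-200, 200), seed = 1)
  expect_equal(al$cr$rate[al$tau == 0], base[tt == 400], tolerance = 1e-9)
  expect_equal(al$cr$rate[al$tau == 100], base[tt == 500], tolerance = 1e-9)

  # aligning then averaging equals averaging pre-shifted series
  onsets <- c(350, 400, 450)
  mat <- do.call(rbind, lapply(onsets, function(on)
    1 - 0.3 * exp(-((tt - on) / 100)^2)))
  al <- align_to_cr_onset(mat, tt, onsets, window = c(-200, 200), seed = 1)
  expect_equal(al$cr$rate, 1 - 0.3 * exp(-(al$tau / 100)^2), tolerance = 1e-6)
  expect_error(align_to_cr_onset(mat, tt, c(NA, NA, NA)), "empty")
})
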