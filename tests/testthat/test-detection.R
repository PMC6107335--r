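test_that("prominence peak finding matches its definition", {
  t <- trial_time_grid()
  x <- cr_waveform(300, 4, 180, 150, t) + cr_waveform(1050, 3, 180, 150, t)
  pk <- find_peaks(x, 0.5)
  expect_equal(nrow(pk), 2)
  expect_lte(max(abs(t[pk$index] - c(480, 1230))), 2)
  expect_equal(pk$value, c(max(x[t < 800]), max(x[t > 800])))

  # a 0.4 mm ripple riding on the first CR's tail is a genuine local
  # maximum, but with prominence under the 0.5 mm rule it is not a CR
  ripple <- x + cr_waveform(740, 0.4, 30, 60, t)
  expect_equal(nrow(find_peaks(ripple, 0.5)), 2)
  expect_gte(nrow(find_peaks(ripple, 0.05)), 3)

  # plateau: earliest sample wins
  y <- c(0, 1, 2, 2, 2, 1, 0)
  expect_equal(find_peaks(y)$index, 3)
})

test_that("CR detection crosses the 0.3 mm criterion at the right latency", {
  t <- trial_time_grid()
  expect_false(detect_cr(numeric(length(t)), t)$present)

  ramp <- approx(c(-200, 300, 500, 2299), c(0, 0, 1, 1), xout = t)$y
  d <- detect_cr(ramp, t)
  expect_true(d$present)
  expect_equal(d$latency_to_criterion, 360)  # 0.3 = (t - 300) / 200

  # raising the criterion never converts absent into present
  set.seed(8)
  for (r in 1:20) {
    x <- cr_waveform(runif(1, 100, 400), runif(1, 0, 2), 180, 150, t) +
      rnorm(length(t), 0, 0.05)
    crits <- c(0.2, 0.3, 0.5, 1)
    pres <- vapply(crits, function(cc) detect_cr(x, t, cc)$present, NA)
    expect_true(all(diff(as.integer(pres)) <= 0))
  }
})

test_that("two-step onset back-projects to the baseline crossing", {
  t <- trial_time_grid()
  ramp <- approx(c(-200, 300, 500, 2299), c(0, 0, 1, 1), xout = t)$y
  on <- cr_onset(ramp, t, latency = 360)
  expect_false(on$fallback)
  expect_equal(on$onset, 300, tolerance = 1e-6)

  # step function: onset bracketed by the two samples
  step <- ifelse(t >= 401, 2, 0)
  on <- cr_onset(step, t, latency = 401)
  expect_gte(on$onset, 400)
  expect_lte(on$onset, 401)

  # Monte-Carlo: ramp + 0.05 mm noise, mean |error| < 5 ms
  set.seed(77)
  errs <- replicate(200, {
    x <- smooth_trace(ramp + rnorm(length(t), 0, 0.05))
    lat <- detect_cr(x, t)$latency_to_criterion
    cr_onset(x, t, lat)$onset - 300
  })
  expect_lt(mean(abs(errs)), 5)
})

test_that("timing measures follow their definitions on analytic profiles", {
  t <- trial_time_grid()
  ramp <- approx(c(-200, 300, 500, 2299), c(0, 0, 4, 0), xout = t)$y
  v <- eyelid_velocity(ramp, window = 0)
  tm <- timing_measures(ramp, v, t, onset = 300, peak_time = 500)
  expect_equal(tm$amplitude, 4)
  expect_equal(tm$t_half_peak, 400)
  expect_equal(tm$t_90_peak, 480)

  # raised-cosine rise: peak velocity at the midpoint of the rise
  rise <- ifelse(t >= 300 & t <= 500, 4 * sin(pi * (t - 300) / 400)^2,
                 ifelse(t > 500, 4, 0))
  v <- eyelid_velocity(rise, window = 0)
  tm <- timing_measures(rise, v, t, onset = 300, peak_time = 500)
  expect_lt(abs(tm$t_peak_velocity - 400), 2)

  # 0.3 mm event: t_half_peak is the first crossing of 0.15 mm
  small <- approx(c(-200, 300, 500, 2299), c(0, 0, 0.3, 0.3), xout = t)$y
  tm <- timing_measures(small, eyelid_velocity(small, window = 0), t,
                        onset = 300, peak_time = 500)
  expect_equal(tm$t_half_peak, 400)
})

test_that("ipsilateral decomposition recovers planted multi-CR structure", {
  t <- trial_time_grid()
  x <- planted_trace(list(list(onset = 270, amp = 4),
                          list(onset = 900, amp = 3)))
  d <- decompose_trial(x, t, type = "cs_alone", smooth = FALSE)
  expect_true(d$outcome$first_present)
  expect_true(d$outcome$second_present)
  expect_false(d$outcome$third_present)
  expect_equal(nrow(d$events), 2)
  expect_lte(max(abs(d$events$peak_time - c(450, 1080))), 2)
  expect_equal(d$events$amplitude[1], 4, tolerance = 0.01)
  expect_equal(d$outcome$second_onset, 900, tolerance = 5)

  # sub-prominence ripple is not counted as an extra CR
  xr <- x + cr_waveform(600, 0.4, 40, 50, t)
  d <- decompose_trial(xr, t, type = "cs_alone", smooth = FALSE)
  expect_equal(d$outcome$n_cr, 2)
})

test_that("squint gate excludes trials whose valley range is under 1 mm", {
  t <- trial_time_grid()
  # slow sustained squint: max(400-1100) = 2.2, min(800-1100) = 1.5
  x <- approx(c(-200, 250, 420, 800, 1100, 2299),
              c(0, 0, 2.2, 1.8, 1.5, 1.2), xout = t)$y
  d <- decompose_trial(x, t, type = "cs_alone", smooth = FALSE)
  expect_false(d$outcome$squint_gate_passed)
  expect_false(d$outcome$second_eligible)
  # first CR is still reported
  expect_true(d$outcome$first_present)

  # same shape but a full valley passes
  y <- approx(c(-200, 250, 420, 800, 1100, 1250, 2299),
              c(0, 0, 2.2, 0.4, 2.0, 0.5, 0), xout = t)$y
  expect_true(decompose_trial(y, t, type = "cs_alone",
                              smooth = FALSE)$outcome$squint_gate_passed)
})

test_that("paired trials constrain the second CR to the US2 window", {
  t <- trial_time_grid()
  x <- planted_trace(list(list(onset = 300, amp = 4),
                          list(onset = 900, amp = 3)))
  d <- decompose_trial(x, t, type = "paired", us_time = 1100,
                       smooth = FALSE)
  expect_true(d$outcome$second_eligible)
  expect_true(d$outcome$second_present)
  expect_gte(d$outcome$second_peak_time, 1000)
  expect_lt(d$outcome$second_peak_time, 1100)

  # US1-truncated trial: no second-CR analysis
  d1 <- decompose_trial(planted_trace(list(list(onset = 300, amp = 2))), t,
                        type = "paired", us_time = 500, smooth = FALSE)
  expect_false(d1$outcome$second_eligible)
  expect_true(d1$outcome$first_present)
})

test_that("right-eye amplitude subtracts co-movement during the CS", {
  t <- trial_time_grid()
  r1 <- cr_waveform(200, 0.4, 100, 2000, t) + cr_waveform(800, 1.6, 180, 500, t)
  a <- right_eye_amplitude(r1, t)
  expect_equal(a$amplitude, max(r1) - max(r1[t >= 0 & t < 500]),
               tolerance = 1e-9)

  r2 <- cr_waveform(700, 1.0, 180, 150, t)  # flat during CS
  expect_equal(right_eye_amplitude(r2, t)$amplitude, 1.0, tolerance = 1e-6)
  expect_true(right_eye_amplitude(r2, t)$present)

  r3 <- cr_waveform(100, 2.0, 100, 4000, t)  # co-movement only
  a3 <- right_eye_amplitude(r3, t)
  expect_lte(a3$amplitude, 0.1)
  expect_false(a3$present)
  # corrected amplitude never exceeds the raw maximum deviation
  for (r in list(r1, r2, r3))
    expect_lte(right_eye_amplitude(r, t)$amplitude, max(r))
})

test_that("decomposed sessions never contain a second CR without a first", {
  for (seed in c(2, 5)) {
    s <- small_ipsi(seed = seed, n_blocks = 6)
    o <- decompose_session(s)$outcomes
    expect_equal(sum(o$second_present & !o$first_present), 0)
  }
  sc <- generate_session(protocol_config("contralateral", n_blocks = 6),
                         gen_params(), seed = 3)
  oc <- decompose_session(sc)$outcomes
  expect_equal(sum(oc$second_present & !oc$first_present), 0)
})
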