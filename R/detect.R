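#' Detect a conditioned response
#'
#' An eyelid response counts as a CR if its amplitude reaches the 0.3 mm
#' criterion (5% of full closure) within the analysis window. The latency to
#' criterion is the first time point at which position deviates to or above
#' the criterion.
#'
#' @param x Calibrated (baseline-zeroed) position series (mm).
#' @param t Time grid (ms).
#' @param criterion CR criterion (mm, default 0.3).
#' @param window Analysis window `[a, b)` in ms (default CS onset to end of
#'   record).
#' @return List with `present` (logical), `latency_to_criterion` (ms or NA)
#'   and `amplitude` (window maximum, mm).
#' @export
detect_cr <- function(x, t = trial_time_grid(), criterion = 0.3,
                      window = c(0, max(t) + 1)) {
  m <- win_mask(t, window[1], window[2])
  amp <- max(x[m])
  if (amp < criterion)
    return(list(present = FALSE, latency_to_criterion = NA_real_,
                amplitude = amp))
  i <- which(m)[which(x[m] >= criterion)[1]]
  list(present = TRUE, latency_to_criterion = t[i], amplitude = amp)
}

#' Two-step CR onset estimation
#'
#' Step 1 scans backward from the criterion crossing for the initial
#' deflection away from the pre-CS baseline: the last sample at which
#' position is at or below `baseline + noise_k * SD(pre-CS)` and has stayed
#' there for at least `sustain_ms` ms. Step 2 back-projects a least-squares
#' line fitted to the departure segment (departure sample to criterion
#' crossing) down to the baseline level and returns the interpolated crossing
#' time. If no departure precedes the crossing the latency to criterion is
#' returned with `fallback = TRUE`.
#'
#' @param x Position series (mm).
#' @param t Time grid (ms).
#' @param latency Latency to criterion from [detect_cr()] (ms).
#' @param baseline Baseline level (mm); default mean of `pre_cs` window.
#' @param pre_cs Pre-CS window `[a, b)` used for baseline statistics.
#' @param noise_k Departure threshold in pre-CS noise SDs (default 2).
#' @param sustain_ms Required time at/below threshold (default 5 ms).
#' @return List with `onset` (ms) and `fallback` (logical).
#' @export
cr_onset <- function(x, t = trial_time_grid(), latency,
                     baseline = NULL, pre_cs = c(-200, 0),
                     noise_k = 2, sustain_ms = 5) {
  pm <- win_mask(t, pre_cs[1], pre_cs[2])
  if (is.null(baseline)) baseline <- mean(x[pm])
  noise_sd <- sd(x[pm])
  if (!is.finite(noise_sd)) noise_sd <- 0
  th <- baseline + noise_k * noise_sd + 1e-12
  ci <- which(t >= latency)[1]
  below <- x <= th
  d <- NA_integer_
  for (i in seq.int(ci, 2L)) {
    if (below[i] && all(below[max(1L, i - sustain_ms + 1L):i])) {
      d <- i
      break
    }
  }
  if (is.na(d) || d >= ci)
    return(list(onset = latency, fallback = TRUE))
  # departure segment: the rising stretch from leaving the noise band up to
  # twice the criterion level (still within the near-linear early rise);
  # points inside the noise band would drag the back-projected line toward
  # the baseline plateau, and a longer lever arm tames the smoothing-induced
  # noise correlation
  s <- seq.int(d, ci)
  s1 <- s[which(x[s] > th)[1]]
  if (is.na(s1) || ci - s1 < 4) s1 <- d
  hi <- seq.int(ci, min(ci + 80, length(x)))
  ci2 <- hi[which(x[hi] >= 2 * (x[ci] - baseline) + baseline)[1]]
  if (is.na(ci2)) ci2 <- ci
  seg <- seq.int(s1, ci2)
  fit <- stats::lm.fit(cbind(1, t[seg]), x[seg])
  b <- fit$coefficients
  onset <- if (is.finite(b[2]) && b[2] > 0) (baseline - b[1]) / b[2]
           else t[d]
  # the back-projected crossing lies at or before the departure sample;
  # clamp only against runaway extrapolation
  onset <- min(max(onset, t[d] - 100), latency)
  list(onset = onset, fallback = FALSE)
}

#' CR timing measures
#'
#' Computes the timing measures of one CR event: time of CR peak, time of
#' peak CR velocity, time to half of CR peak and time to 90% of CR peak. All
#' "time to fraction" measures are the first sample within
#' `[onset, peak_time]` at or above the fraction of the peak; ties take the
#' earliest sample.
#'
#' @param x Position series (mm), `v` velocity series (mm/ms).
#' @param t Time grid (ms).
#' @param onset,peak_time Event bounds (ms).
#' @return List with `amplitude`, `peak_time`, `t_peak_velocity`,
#'   `t_half_peak`, `t_90_peak`.
#' @export
timing_measures <- function(x, v, t = trial_time_grid(), onset, peak_time) {
  m <- t >= onset & t <= peak_time
  im <- which(m)
  amp <- x[im[length(im)]]   # position at event peak
  first_at <- function(frac) {
    i <- im[which(x[im] >= frac * amp)[1]]
    if (is.na(i)) peak_time else t[i]
  }
  list(amplitude = amp, peak_time = peak_time,
       t_peak_velocity = t[im[which.max(v[im])]],
       t_half_peak = first_at(0.5), t_90_peak = first_at(0.9))
}

#' Corrected contralateral right-eye CR amplitude
#'
#' The right-eye CR amplitude is the overall maximum of right eyelid position
#' minus its maximum during the CS (when any sympathetic co-movement with the
#' left-eye CR would occur); a right-eye CR is present iff the corrected
#' amplitude reaches the 0.3 mm criterion.
#'
#' @param right Right-eye position series (mm).
#' @param t Time grid (ms).
#' @param cs_window CS window `[a, b)` (ms, default `c(0, 500)`).
#' @param window Overall analysis window `[a, b)` (ms).
#' @param criterion CR criterion (mm).
#' @return List with `amplitude` (mm), `present` and `peak_time` (ms).
#' @export
right_eye_amplitude <- function(right, t = trial_time_grid(),
                                cs_window = c(0, 500),
                                window = c(0, max(t) + 1), criterion = 0.3) {
  m <- win_mask(t, window[1], window[2])
  overall <- max(right[m])
  during_cs <- max(right[win_mask(t, cs_window[1], cs_window[2])])
  amp <- overall - during_cs
  ipk <- which(m)[which.max(right[m])]
  list(amplitude = amp, present = amp >= criterion, peak_time = t[ipk])
}

# Onset of a later CR in a sequence: the time of the position minimum
# between consecutive peaks, refined to sub-sample precision by
# intersecting least-squares lines fitted to the two valley flanks (the
# valley is an asymmetric V, so a smoothed argmin alone is biased toward
# the shallow flank).
valley_onset <- function(x, t, seg, flank = c(8, 60)) {
  i0 <- seg[which.min(x[seg])]
  lw <- seg[seg >= i0 - flank[2] & seg <= i0 - flank[1]]
  rw <- seg[seg >= i0 + flank[1] & seg <= i0 + flank[2]]
  if (length(lw) < 5 || length(rw) < 5) return(t[i0])
  f1 <- stats::lm.fit(cbind(1, t[lw]), x[lw])$coefficients
  f2 <- stats::lm.fit(cbind(1, t[rw]), x[rw])$coefficients
  tx <- (f1[1] - f2[1]) / (f2[2] - f1[2])
  if (!is.finite(tx) || tx < t[i0] - flank[2] || tx > t[i0] + flank[2])
    t[i0] else tx
}

# build one CR event row
cr_event_row <- function(trial_id, eye, j, onset, latency, tm) {
  data.frame(trial_id = trial_id, eye = eye, index_in_sequence = j,
             onset = onset, latency_to_criterion = latency,
             amplitude = tm$amplitude, peak_time = tm$peak_time,
             t_peak_velocity = tm$t_peak_velocity,
             t_half_peak = tm$t_half_peak, t_90_peak = tm$t_90_peak,
             stringsAsFactors = FALSE)
}

#' Decompose one ipsilateral trial into a CR sequence
#'
#' Implements the multi-CR amplitude rules for the ipsilateral protocol:
#'
#' 1. *Squint gate*: the difference between the maximum of position in
#'    400-1100 ms from CS onset and the minimum in 800-1100 ms must exceed
#'    1 mm, otherwise the trial is flagged `squint_gate_failed` and excluded
#'    from second-CR analysis.
#' 2. On CS-alone trials, local maxima with prominence >= 0.5 mm estimate the
#'    number of CRs. With >= 2 peaks and first-CR onset before CS offset, the
#'    peaks define CR count, peak times and amplitudes. With a first-CR onset
#'    at or after CS offset, the windowed-maximum rule applies: first-CR
#'    amplitude is the position maximum from CS onset to 200 ms after CS
#'    offset, second-CR amplitude the maximum 200-800 ms after CS offset
#'    (a delayed first CR is one whose windowed maximum still reaches
#'    criterion).
#' 3. On paired trials the same procedure applies with the analysis truncated
#'    at the delivered US and the second-CR peak constrained to within 100 ms
#'    of the US2 time.
#' 4. The onset of CR k >= 2 is the time of the position minimum between
#'    consecutive peaks (refined to sub-sample precision by intersecting
#'    lines fitted to the two valley flanks); the first-CR onset comes from
#'    [cr_onset()].
#'
#' @param x Screened, calibrated position series (mm) for the trained eye.
#' @param t Time grid (ms).
#' @param type Trial type (`"cs_alone"`, `"paired"`, ...).
#' @param us_time Delivered US time (ms, NA if none).
#' @param cfg A [protocol_config()].
#' @param criterion CR criterion (mm).
#' @param min_prominence Peak prominence threshold (mm, default 0.5).
#' @param trial_id Identifier copied into the outputs.
#' @param smooth Apply [smooth_trace()] before decomposition (default TRUE).
#' @return List with `outcome` (one-row data.frame: squint gate, per-CR
#'   presence/amplitudes/onsets) and `events` (data.frame of CR events with
#'   timing measures).
#' @export
decompose_trial <- function(x, t = trial_time_grid(), type = "cs_alone",
                            us_time = NA, cfg = protocol_config(),
                            criterion = 0.3, min_prominence = 0.5,
                            trial_id = NA_integer_, smooth = TRUE) {
  if (smooth) x <- smooth_trace(x)
  v <- eyelid_velocity(x, window = if (smooth) 21 else 0)
  cs_off <- cfg$cs_duration
  us2 <- cfg$cs_duration + cfg$gap_interval
  t_end <- max(t) + 1
  paired <- !is.na(us_time)
  win_hi <- if (paired) us_time else t_end

  first <- detect_cr(x, t, criterion, window = c(0, win_hi))

  # squint gate: a sustained squint after the first CR can mask the
  # presence/absence of a following CR. Applied only to trials with a first
  # CR (a flat no-CR trace has nothing to mask) whose record extends through
  # the gate windows.
  gate_ok <- TRUE
  if (first$present && (win_hi > 1100 - 1e-9 || !paired)) {
    gmax <- max(x[win_mask(t, 400, 1101)])
    gmin <- min(x[win_mask(t, 800, 1101)])
    gate_ok <- (gmax - gmin) >= 1
  }
  out <- data.frame(trial_id = trial_id, type = type,
                    squint_gate_passed = gate_ok,
                    first_present = FALSE, delayed_first = FALSE,
                    first_onset = NA_real_, first_latency = NA_real_,
                    first_amp = max(x[win_mask(t, 0, win_hi)]),
                    first_peak_time = NA_real_,
                    second_eligible = FALSE, second_present = FALSE,
                    second_onset = NA_real_, second_amp = NA_real_,
                    second_peak_time = NA_real_, third_present = FALSE,
                    n_cr = 0L, stringsAsFactors = FALSE)
  events <- list()

  # second-CR analysis is possible when the record is not truncated at US1:
  # CS-alone trials always qualify, paired trials only when US2 was delivered
  out$second_eligible <- gate_ok && (!paired || win_hi >= us2 - 1e-9)

  # second-CR search windows: around US2 on paired trials, 200-800 ms after
  # CS offset on CS-alone trials
  w2_lo <- if (paired) max(cs_off + 200, us2 - 100) else cs_off + 200
  w2_hi <- if (paired) win_hi else min(cs_off + 800, t_end)

  if (!first$present) {
    # the whole-window maximum is below criterion, so the second-CR window
    # maximum is below criterion too: no-first-CR trials report the measured
    # (sub-criterion) second amplitude rather than an enforced zero
    out$second_amp <- if (out$second_eligible && w2_hi > w2_lo)
      max(x[win_mask(t, w2_lo, w2_hi)]) else NA_real_
    return(list(outcome = out, events = empty_events()))
  }

  on1 <- cr_onset(x, t, first$latency_to_criterion)
  out$first_present <- TRUE
  out$first_latency <- first$latency_to_criterion
  out$first_onset <- on1$onset

  # peak-based decomposition (CS-alone trials; full record available)
  use_peaks <- FALSE
  if (!paired) {
    m <- which(win_mask(t, 0, win_hi))
    pk <- find_peaks(x[m], min_prominence)
    pk$index <- m[pk$index]
    use_peaks <- nrow(pk) >= 2 && on1$onset < cs_off
  }
  if (use_peaks) {
    n_cr <- nrow(pk)
    peak_times <- t[pk$index]
    amps <- pk$value
    onsets <- numeric(n_cr)
    onsets[1] <- on1$onset
    for (j in seq_len(n_cr)[-1]) {
      seg <- seq.int(pk$index[j - 1], pk$index[j])
      onsets[j] <- valley_onset(x, t, seg)
    }
    for (j in seq_len(n_cr)) {
      lat <- if (j == 1) first$latency_to_criterion else onsets[j]
      tm <- timing_measures(x, v, t, onsets[j], peak_times[j])
      events[[j]] <- cr_event_row(trial_id, "left", j, onsets[j], lat, tm)
    }
    out$first_amp <- amps[1]
    out$first_peak_time <- peak_times[1]
    out$n_cr <- n_cr
    if (out$second_eligible && n_cr >= 2) {
      out$second_present <- amps[2] >= criterion
      out$second_onset <- onsets[2]
      out$second_amp <- amps[2]
      out$second_peak_time <- peak_times[2]
      out$third_present <- n_cr >= 3
    }
  } else {
    # windowed-maximum rule: paired trials (second-CR peak assumed within
    # 100 ms of US2, record truncated at the US), and CS-alone trials with
    # a single prominent peak or a delayed first CR
    w1 <- win_mask(t, 0, min(cs_off + 200, win_hi))
    i1 <- which(w1)[which.max(x[w1])]
    out$first_amp <- x[i1]
    out$first_peak_time <- t[i1]
    out$delayed_first <- on1$onset >= cs_off
    out$first_present <- out$first_amp >= criterion
    if (out$first_present) {
      tm <- timing_measures(x, v, t, on1$onset, t[i1])
      events[[1]] <- cr_event_row(trial_id, "left", 1L, on1$onset,
                                  first$latency_to_criterion, tm)
      out$n_cr <- 1L
    }
    if (out$first_present && out$second_eligible && w2_hi > w2_lo) {
      w2 <- win_mask(t, w2_lo, w2_hi)
      i2 <- which(w2)[which.max(x[w2])]
      rise <- x[i2] - min(x[seq.int(i1, i2)])
      out$second_amp <- x[i2]
      # a genuine second CR must both reach criterion and rise by at least
      # the criterion above the trough after the first CR (guards against
      # the decaying tail of a large first CR)
      out$second_present <- x[i2] >= criterion && rise >= criterion
      if (out$second_present) {
        seg <- seq.int(i1, i2)
        out$second_onset <- valley_onset(x, t, seg)
        out$second_peak_time <- t[i2]
        tm2 <- timing_measures(x, v, t, out$second_onset, t[i2])
        events[[2]] <- cr_event_row(trial_id, "left", 2L, out$second_onset,
                                    out$second_onset, tm2)
        out$n_cr <- 2L
      }
    }
  }
  if (!out$first_present)
    return(list(outcome = out, events = empty_events()))
  list(outcome = out, events = do.call(rbind, events))
}

empty_events <- function() {
  data.frame(trial_id = integer(), eye = character(),
             index_in_sequence = integer(), onset = numeric(),
             latency_to_criterion = numeric(), amplitude = numeric(),
             peak_time = numeric(), t_peak_velocity = numeric(),
             t_half_peak = numeric(), t_90_peak = numeric(),
             stringsAsFactors = FALSE)
}

#' Decompose one contralateral trial
#'
#' The first CR is detected on the left eye as usual; the second CR is the
#' right-eye response with the sympathetic co-movement correction of
#' [right_eye_amplitude()], searched after CS offset and truncated at the
#' delivered US.
#'
#' @inheritParams decompose_trial
#' @param left,right Position series for the two eyes (mm).
#' @return Same structure as [decompose_trial()].
#' @export
decompose_contra_trial <- function(left, right, t = trial_time_grid(),
                                   type = "cs_alone", us_time = NA,
                                   cfg = protocol_config("contralateral"),
                                   criterion = 0.3,
                                   trial_id = NA_integer_, smooth = TRUE) {
  if (smooth) {
    left <- smooth_trace(left)
    right <- smooth_trace(right)
  }
  vl <- eyelid_velocity(left, window = if (smooth) 21 else 0)
  vr <- eyelid_velocity(right, window = if (smooth) 21 else 0)
  cs_off <- cfg$cs_duration
  t_end <- max(t) + 1
  paired <- !is.na(us_time)
  win_hi <- if (paired) us_time else t_end

  first <- detect_cr(left, t, criterion, window = c(0, min(win_hi, t_end)))
  out <- data.frame(trial_id = trial_id, type = type,
                    squint_gate_passed = TRUE,
                    first_present = first$present, delayed_first = FALSE,
                    first_onset = NA_real_,
                    first_latency = first$latency_to_criterion,
                    first_amp = first$amplitude,
                    first_peak_time = NA_real_,
                    second_eligible = !paired || win_hi > cs_off + 100,
                    second_present = FALSE, second_onset = NA_real_,
                    second_amp = NA_real_, second_peak_time = NA_real_,
                    third_present = FALSE, n_cr = 0L,
                    stringsAsFactors = FALSE)
  events <- list()
  if (first$present) {
    on1 <- cr_onset(left, t, first$latency_to_criterion)
    out$first_onset <- on1$onset
    m <- win_mask(t, 0, win_hi)
    i1 <- which(m)[which.max(left[m])]
    out$first_peak_time <- t[i1]
    tm <- timing_measures(left, vl, t, on1$onset, t[i1])
    out$first_amp <- tm$amplitude
    events[[1]] <- cr_event_row(trial_id, "left", 1L, on1$onset,
                                first$latency_to_criterion, tm)
    out$n_cr <- 1L
  }
  if (out$second_eligible) {
    r <- right_eye_amplitude(right, t, cs_window = c(0, cs_off),
                             window = c(0, win_hi), criterion = criterion)
    out$second_amp <- r$amplitude
    out$second_present <- r$present && first$present
    if (out$second_present) {
      rd <- detect_cr(right, t, criterion, window = c(cs_off, win_hi))
      lat <- if (rd$present) rd$latency_to_criterion else r$peak_time
      on2 <- cr_onset(right, t, lat)
      tm2 <- timing_measures(right, vr, t, on2$onset, r$peak_time)
      out$second_onset <- on2$onset
      out$second_peak_time <- r$peak_time
      events[[2]] <- cr_event_row(trial_id, "right", 2L, on2$onset, lat, tm2)
      out$n_cr <- 2L
    }
  }
  list(outcome = out,
       events = if (length(events)) do.call(rbind, events) else
         empty_events())
}

#' Decompose every kept trial of a session
#'
#' Screens (optionally) and decomposes all trials of a session, dispatching
#' on the protocol.
#'
#' @param session A `cr_session`.
#' @param screen Data frame from [screen_session()], or NULL to screen here.
#' @param ... Passed to the per-trial decomposition.
#' @return List with `outcomes` (one row per kept trial) and `events` (one
#'   row per CR event).
#' @export
decompose_session <- function(session, screen = NULL, ...) {
  if (is.null(screen)) screen <- screen_session(session)
  tr <- session$trials
  contra <- session$cfg$protocol == "contralateral"
  outs <- list(); evs <- list()
  for (i in seq_len(nrow(tr))) {
    if (!screen$kept[i]) next
    if (contra) {
      d <- decompose_contra_trial(session$traces$left[i, ],
                                  session$traces$right[i, ], session$t,
                                  type = tr$type[i], us_time = tr$us_time[i],
                                  cfg = session$cfg,
                                  trial_id = tr$trial_id[i], ...)
    } else {
      d <- decompose_trial(session$traces$left[i, ], session$t,
                           type = tr$type[i], us_time = tr$us_time[i],
                           cfg = session$cfg, trial_id = tr$trial_id[i], ...)
    }
    outs[[length(outs) + 1]] <- d$outcome
    if (nrow(d$events)) evs[[length(evs) + 1]] <- d$events
  }
  list(outcomes = do.call(rbind, outs),
       events = if (length(evs)) do.call(rbind, evs) else empty_events())
}
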