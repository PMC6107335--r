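#' Calibrate a raw eyelid trace
#'
#' Scales a raw detector readout so that full eyelid closure reads 6.0 mm
#' (the adult-rabbit convention; a test US elicits full closure at the start
#' of each session), and removes the baseline offset so the pre-CS window
#' mean is zero.
#'
#' @param raw Numeric raw position series.
#' @param full_closure_reading Raw units corresponding to full closure, > 0.
#' @param t Time grid (ms) matching `raw`.
#' @param full_closure Calibrated full-closure value (mm, default 6.0).
#' @param pre_cs Pre-CS baseline window `[a, b)` in ms (default `c(-200, 0)`).
#' @return Calibrated position series (mm), with attribute `"scale"`
#'   (mm per raw unit).
#' @export
calibrate <- function(raw, full_closure_reading, t = trial_time_grid(),
                      full_closure = 6.0, pre_cs = c(-200, 0)) {
  if (!is.finite(full_closure_reading) || full_closure_reading <= 0)
    stop("full_closure_reading must be positive")
  scale <- full_closure / full_closure_reading
  x <- raw * scale
  x <- x - mean(x[win_mask(t, pre_cs[1], pre_cs[2])])
  attr(x, "scale") <- scale
  x
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of an eyelid position series.
#' Output length equals input length; any polynomial of degree <= `polyorder`
#' passes through unchanged, and the filter has unit DC gain.
#'
#' @param x Numeric series.
#' @param window Odd window length in samples (default 21, i.e. 21 ms at
#'   1 kHz; preserves CR rise times of 50-100 ms while suppressing sensor
#'   noise).
#' @param polyorder Polynomial order (default 3).
#' @return Smoothed series.
#' @export
smooth_trace <- function(x, window = 21, polyorder = 3) {
  if (window %% 2 == 0 || window < polyorder + 2)
    stop("window must be odd and >= polyorder + 2")
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window))
}

#' Eyelid velocity
#'
#' Second-order-accurate derivative of eyelid position (central differences
#' in the interior, one-sided second-order stencils at the endpoints),
#' followed by the same Savitzky-Golay smoothing as [smooth_trace()].
#'
#' @param x Position series (mm), length >= 3.
#' @param dt Sample interval (ms, default 1).
#' @param window,polyorder Smoothing parameters; set `window = 0` to skip
#'   smoothing.
#' @return Velocity series (mm/ms).
#' @export
eyelid_velocity <- function(x, dt = 1, window = 21, polyorder = 3) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
  v[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  if (window > 0) v <- smooth_trace(v, window, polyorder)
  v
}

#' Screen a trial for exclusion
#'
#' Applies the trial exclusion rules: (1) upward eyelid movement exceeding
#' the 0.3 mm CR criterion during the 200 ms before CS onset
#' (`pre_cs_upward`) or the first 100 ms from CS onset (`early_cs_upward`);
#' (2) negative eyelid deviation below -0.5 mm relative to baseline at any
#' time prior to US onset on paired trials, or from trial start to 500 ms
#' after CS offset on CS-alone trials (`negative_deviation`). Rule (1) is
#' checked before rule (2). Deviations are measured relative to the pre-CS
#' baseline mean; "exceeding" is a strict inequality. For contralateral
#' trials both eyes are screened and either can trigger exclusion.
#'
#' @param traces Named list of calibrated position series by eye (or a single
#'   numeric vector, taken as the left eye).
#' @param type Trial type; `"cs_alone"`-like types use the CS-alone window
#'   for rule (2).
#' @param us_time Delivered/scheduled US time (ms); required for paired
#'   trials.
#' @param t Time grid (ms).
#' @param cs_duration CS duration (ms, default 500).
#' @param criterion CR criterion (mm, default 0.3).
#' @param neg_limit Negative-deviation limit (mm, default 0.5).
#' @param trial_id Optional identifier copied into the report.
#' @return One-row data.frame: `trial_id`, `kept`, `reason`
#'   (`none`/`pre_cs_upward`/`early_cs_upward`/`negative_deviation`),
#'   `offending_time` (ms) and `offending_eye`.
#' @export
screen_trial <- function(traces, type = "cs_alone", us_time = NA,
                         t = trial_time_grid(), cs_duration = 500,
                         criterion = 0.3, neg_limit = 0.5,
                         trial_id = NA_integer_) {
  if (is.numeric(traces)) traces <- list(left = traces)
  paired <- type %in% c("paired", "cs2_paired")
  if (paired && is.na(us_time))
    stop("paired trial requires a US time for screening")
  report <- function(reason, time, eye)
    data.frame(trial_id = trial_id, kept = reason == "none", reason = reason,
               offending_time = time, offending_eye = eye,
               stringsAsFactors = FALSE)

  for (eye in names(traces)) {
    x <- traces[[eye]]
    base <- mean(x[win_mask(t, -200, 0)])
    dev <- x - base
    # rule 1: upward movement > criterion pre-CS or in [0, 100) ms
    m <- win_mask(t, -200, 0)
    if (any(dev[m] > criterion)) {
      i <- which(m)[which(dev[m] > criterion)[1]]
      return(report("pre_cs_upward", t[i], eye))
    }
    m <- win_mask(t, 0, 100)
    if (any(dev[m] > criterion)) {
      i <- which(m)[which(dev[m] > criterion)[1]]
      return(report("early_cs_upward", t[i], eye))
    }
  }
  for (eye in names(traces)) {
    x <- traces[[eye]]
    base <- mean(x[win_mask(t, -200, 0)])
    dev <- x - base
    hi <- if (paired) us_time else cs_duration + 500
    m <- win_mask(t, t[1], hi)
    if (any(dev[m] < -neg_limit)) {
      i <- which(m)[which(dev[m] < -neg_limit)[1]]
      return(report("negative_deviation", t[i], eye))
    }
  }
  report("none", NA_real_, NA_character_)
}

#' Screen all trials of a session
#'
#' Applies [screen_trial()] to every trial of a generated or imported
#' session.
#'
#' @param session A `cr_session`.
#' @param ... Passed to [screen_trial()].
#' @return Data frame of exclusion reports, one row per trial.
#' @export
screen_session <- function(session, ...) {
  tr <- session$trials
  out <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    traces <- lapply(session$traces, function(m) m[i, ])
    out[[i]] <- screen_trial(traces, type = tr$type[i],
                             us_time = tr$us_time[i], t = session$t,
                             cs_duration = session$cfg$cs_duration,
                             trial_id = tr$trial_id[i], ...)
  }
  do.call(rbind, out)
}
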