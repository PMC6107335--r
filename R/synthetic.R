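#' CR waveform
#'
#' Smooth unimodal eyelid-closure waveform: a quarter-sine rise from 0 to
#' `amplitude` over `rise_time` ms followed by exponential relaxation with
#' time constant `decay_time`. The peak equals `amplitude` exactly, at
#' `onset + rise_time`; velocity is highest just after onset and zero at the
#' peak, giving the abrupt, well-defined onsets characteristic of real
#' conditioned eyelid responses. Waveforms are additive across overlapping
#' CRs.
#'
#' @param onset Onset time (ms, trial clock).
#' @param amplitude Peak closure (mm, >= 0).
#' @param rise_time Rise duration (ms, > 0).
#' @param decay_time Decay time constant (ms, > 0).
#' @param t Time grid (ms).
#' @return Numeric position series (mm) on `t`.
#' @export
cr_waveform <- function(onset, amplitude, rise_time, decay_time,
                        t = trial_time_grid()) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (rise_time <= 0 || decay_time <= 0) stop("rise/decay times must be positive")
  w <- numeric(length(t))
  x <- (t - onset) / rise_time
  rising <- x > 0 & x <= 1
  w[rising] <- amplitude * sin(pi / 2 * x[rising])
  after <- x > 1
  w[after] <- amplitude * exp(-(t[after] - onset - rise_time) / decay_time)
  w
}

#' Amplitude-contingent US schedule
#'
#' Applies the closed-loop contingency rule: if the first-CR amplitude at the
#' scheduled US1 time is below the target, US1 is delivered at CS offset; at
#' or above target, US1 is omitted and US2 is delivered `gap_interval` ms
#' after CS offset. The contralateral protocol substitutes US_L/US_R (US_R to
#' the right eye) with the same rule.
#'
#' @param first_cr_amplitude_at_us1 Eyelid position (mm) at the scheduled US1
#'   time, >= 0.
#' @param cfg A [protocol_config()].
#' @return List with `us` (label), `time` (ms) and `eye`.
#' @export
simulate_contingency <- function(first_cr_amplitude_at_us1, cfg) {
  if (first_cr_amplitude_at_us1 < 0) stop("amplitude must be non-negative")
  ut <- us_times_for(cfg)
  contra <- cfg$protocol == "contralateral"
  if (first_cr_amplitude_at_us1 < cfg$target_amplitude) {
    list(us = if (contra) "US_L" else "US1", time = ut$us1, eye = "left")
  } else {
    list(us = if (contra) "US_R" else "US2", time = ut$us2,
         eye = if (contra) "right" else "left")
  }
}

# trial-type layout for one session
session_layout <- function(cfg) {
  if (cfg$protocol == "cs2_test") {
    n <- cfg$n_trials_cs2
    counts <- round(cfg$cs2_mix * n)
    counts[1] <- n - sum(counts[-1])   # absorb rounding in the largest group
    types <- rep(c("paired", "cs2_paired", "cs2_alone"), counts)
    data.frame(trial_id = seq_len(n), block = NA_integer_,
               type = sample(types), stringsAsFactors = FALSE)
  } else {
    per_block <- c("cs_alone", rep("paired", cfg$trials_per_block - 1L))
    types <- rep(per_block, cfg$n_blocks)
    data.frame(trial_id = seq_along(types),
               block = rep(seq_len(cfg$n_blocks), each = cfg$trials_per_block),
               type = types, stringsAsFactors = FALSE)
  }
}

rnorm_trunc <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Generate a closed-loop session
#'
#' Generates a full session of trials under one of the amplitude-contingent
#' sequence protocols: planted CR waveforms with variable onset and amplitude,
#' US schedules driven by the contingency rule evaluated on the generated
#' first-CR amplitude at the scheduled US1 time, chained (or independent)
#' later CRs, unconditioned responses after each delivered US, additive trace
#' noise, and optionally Purkinje-cell spike trains. Fully reproducible given
#' `seed`.
#'
#' The chain is truncated by any delivered US: paired US1 trials carry no
#' second CR, US2-paired trials no third CR; full chains occur on CS-alone
#' (and CS2-alone) trials only. In the contralateral protocol the second CR
#' is produced by the right eye and the chain stops there.
#'
#' @param cfg A [protocol_config()].
#' @param gen A [gen_params()].
#' @param pc Optional [pc_gen_params()]; when supplied, a spike train for one
#'   simulated eyelid PC is attached to every trial.
#' @param seed Integer seed.
#' @return A `cr_session` list with elements `cfg`, `gen`, `pc`, `seed`,
#'   `trials` (per-trial metadata data.frame, including the delivered US and
#'   the generated first-CR amplitude at US1 time), `traces` (list by eye of
#'   trial x time matrices, mm), `truth` (data.frame of planted CR events:
#'   onset, planted amplitude, and the peak time/value of the noiseless
#'   composite trace), and `spikes` (data.frame or NULL).
#' @export
generate_session <- function(cfg, gen, pc = NULL, seed = 1) {
  stopifnot(inherits(cfg, "protocol_config"), inherits(gen, "gen_params"))
  if (!is.null(pc)) stopifnot(inherits(pc, "pc_gen_params"))
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(seed)
  t <- trial_time_grid()
  n_t <- length(t)
  t_end <- t[n_t]
  ut <- us_times_for(cfg)
  layout <- session_layout(cfg)
  n_trials <- nrow(layout)
  contra <- cfg$protocol == "contralateral"
  eyes <- if (contra) c("left", "right") else "left"

  p_first <- rep_len(gen$p_first_cr, n_trials)
  p_second <- rep_len(gen$p_second_given_gate, n_trials)
  # onset-to-onset spacing: by default the chained CR peaks at the US2 time
  icc <- if (is.null(gen$inter_cr_interval))
    ut$us2 - gen$rise_time - gen$first_onset_mean else gen$inter_cr_interval

  traces <- lapply(eyes, function(e) matrix(0, n_trials, n_t))
  names(traces) <- eyes
  clean <- lapply(eyes, function(e) matrix(0, n_trials, n_t))
  names(clean) <- eyes
  truth <- list()
  meta <- data.frame(trial_id = layout$trial_id, block = layout$block,
                     type = layout$type, us = "none", us_time = NA_real_,
                     us_eye = NA_character_, amp_at_us1 = 0,
                     stringsAsFactors = FALSE)

  for (i in seq_len(n_trials)) {
    type <- layout$type[i]
    events <- list()   # each: eye, onset, amp
    has_first <- runif(1) < p_first[i]
    if (has_first) {
      onset1 <- rnorm_trunc(gen$first_onset_mean, gen$first_onset_sd,
                            25, cfg$cs_duration - 50)
      amp1 <- rnorm_trunc(gen$first_amp_mean, gen$first_amp_sd,
                          0, cfg$full_closure)
      events[[1]] <- list(eye = "left", onset = onset1, amp = amp1)
    }
    amp_at_us1 <- if (has_first)
      cr_waveform(events[[1]]$onset, events[[1]]$amp, gen$rise_time,
                  gen$decay_time, ut$us1) else 0

    # US schedule
    us <- list(us = "none", time = NA_real_, eye = NA_character_)
    if (type == "paired") {
      us <- simulate_contingency(amp_at_us1, cfg)
    } else if (type == "cs2_paired") {
      # CS2 maintenance trials: US at CS offset, always
      us <- list(us = if (contra) "US_L" else "US1", time = ut$us1,
                 eye = "left")
    }

    # chained later CRs: not past a truncating US
    truncated_at <- if (us$us %in% c("US1", "US_L")) ut$us1 else
      if (us$us %in% c("US2", "US_R")) ut$us2 else Inf
    chain_allowed <- has_first &&
      !(gen$transfer_mode == "cs_bound" &&
          type %in% c("cs2_paired", "cs2_alone"))
    k <- 1
    while (chain_allowed) {
      prev <- events[[k]]
      gate <- cfg$target_amplitude
      p_eff <- if (prev$amp >= gate) p_second[i] else
        p_second[i] * (prev$amp / gate)^2
      if (runif(1) >= p_eff) break
      if (gen$chain_mode == "chained") {
        onset_k <- gen$chain_gain * prev$onset + icc +
          rnorm(1, 0, gen$interval_jitter_sd)
      } else {
        onset_k <- gen$first_onset_mean + k * icc +
          rnorm(1, 0, sqrt(gen$first_onset_sd^2 + gen$interval_jitter_sd^2))
      }
      amp_k <- min(max(gen$amp_decay * prev$amp +
                         rnorm(1, 0, gen$amp_noise_sd), 0), cfg$full_closure)
      # a chained CR is generated only if it is large enough to count as a
      # response, starts before any delivered US (US2 arrives at the
      # reinforced second CR's peak) and fits the window
      if (amp_k < gen$min_cr_amp) break
      if (onset_k >= truncated_at || onset_k + gen$rise_time > t_end - 100)
        break
      if (k + 1 > 2 && contra) break
      eye_k <- if (contra) "right" else "left"
      events[[k + 1]] <- list(eye = eye_k, onset = onset_k, amp = amp_k)
      k <- k + 1
      if (contra && k >= 2) break
      if (k >= 5) break
    }

    # noiseless CR composites per eye, truth peaks from the composite
    onsets <- vapply(events, `[[`, 0, "onset")
    for (e in eyes) {
      comp <- numeric(n_t)
      for (ev in events) if (ev$eye == e)
        comp <- comp + cr_waveform(ev$onset, ev$amp, gen$rise_time,
                                   gen$decay_time, t)
      clean[[e]][i, ] <- comp
    }
    if (length(events)) {
      for (j in seq_along(events)) {
        ev <- events[[j]]
        seg_lo <- ev$onset
        later <- onsets[onsets > ev$onset + 1]
        seg_hi <- if (length(later)) min(later) else t_end
        mask <- which(t >= seg_lo & t <= seg_hi)
        comp <- clean[[ev$eye]][i, ]
        pk <- mask[which.max(comp[mask])]
        truth[[length(truth) + 1]] <-
          data.frame(trial_id = layout$trial_id[i], eye = ev$eye,
                     cr_index = j, onset = ev$onset, planted_amp = ev$amp,
                     peak_time = t[pk], peak_value = comp[pk],
                     stringsAsFactors = FALSE)
      }
    }

    # delivered-US unconditioned response + noise
    for (e in eyes) {
      tr <- clean[[e]][i, ]
      if (!is.na(us$time) && identical(us$eye, e)) {
        base_at <- cr_waveform_value(tr, t, us$time + 15)
        ur_amp <- max(cfg$full_closure - base_at, 0)
        tr <- tr + cr_waveform(us$time + 15, ur_amp, 40, 500, t)
      }
      if (gen$noise_sd > 0) tr <- tr + rnorm(n_t, 0, gen$noise_sd)
      traces[[e]][i, ] <- tr
    }

    meta$us[i] <- us$us
    meta$us_time[i] <- us$time
    meta$us_eye[i] <- if (is.null(us$eye)) NA_character_ else us$eye
    meta$amp_at_us1[i] <- amp_at_us1
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(trial_id = integer(), eye = character(), cr_index = integer(),
               onset = numeric(), planted_amp = numeric(),
               peak_time = numeric(), peak_value = numeric())

  spikes <- NULL
  if (!is.null(pc)) {
    sp <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      tt <- seq(-pc$pre_window, t_end)
      prof <- approx(t, clean$left[i, ], xout = tt, yleft = 0,
                     yright = 0)$y
      tr <- list(profile = prof, t = tt,
                 us_time = if (identical(meta$us_eye[i], "left"))
                   meta$us_time[i] else NA_real_)
      st <- generate_spike_train(tr, pc)
      if (nrow(st)) {
        st$trial_id <- meta$trial_id[i]
        sp[[i]] <- st
      }
    }
    spikes <- do.call(rbind, sp[!vapply(sp, is.null, TRUE)])
    if (!is.null(spikes)) {
      spikes$unit_id <- "unit1"
      spikes <- spikes[, c("trial_id", "unit_id", "time_ms", "spike_type")]
      rownames(spikes) <- NULL
    }
  }

  structure(list(format_version = 1L, cfg = cfg, gen = gen, pc = pc,
                 seed = seed, t = t, trials = meta, traces = traces,
                 clean = clean, truth = truth, spikes = spikes),
            class = "cr_session")
}

# linear-interpolated trace value at time `at`
cr_waveform_value <- function(x, t, at) approx(t, x, xout = at, rule = 2)$y

#' Generate a Purkinje-cell spike train for one trial
#'
#' Simple spikes follow an inhomogeneous Poisson process (thinning algorithm)
#' with rate `baseline * (1 - dip_depth * profile(t + dip_lead))`, clipped at
#' zero, where `profile` is the noiseless CR-only eyelid profile in mm; spike
#' times are rounded to the nearest ms. When a US is delivered, one complex
#' spike follows it at `complex_spike_latency` ms (with probability
#' `p_cs_given_us`), and every complex spike silences simple spikes for
#' `post_cs_pause` ms. Spontaneous complex spikes occur at `spont_cs_rate` Hz.
#'
#' @param trial List with `profile` (mm series), `t` (ms grid, 1 kHz) and
#'   `us_time` (ms or NA).
#' @param pc A [pc_gen_params()].
#' @return Data frame with columns `time_ms` and `spike_type`
#'   (`"simple"`/`"complex"`).
#' @export
generate_spike_train <- function(trial, pc) {
  t <- trial$t
  span <- range(t)
  dur_s <- (span[2] - span[1]) / 1000
  # rate profile, dip led by dip_lead ms
  shifted <- approx(t, trial$profile, xout = t + pc$dip_lead,
                    yleft = 0, yright = 0)$y
  rate <- pmax(pc$baseline_rate * (1 - pc$dip_depth * shifted), 0)

  # thinning: homogeneous candidates at the max rate
  rmax <- max(rate, pc$baseline_rate)
  n_cand <- stats::rpois(1, rmax * dur_s)
  cand <- sort(runif(n_cand, span[1], span[2]))
  r_at <- approx(t, rate, xout = cand, rule = 2)$y
  simple <- cand[runif(n_cand) < r_at / rmax]
  simple <- sort(unique(round(simple)))

  complex <- numeric()
  if (pc$has_complex) {
    n_sp <- stats::rpois(1, pc$spont_cs_rate * dur_s)
    complex <- runif(n_sp, span[1], span[2])
    if (pc$cs_locked_to_us && !is.na(trial$us_time) &&
        runif(1) < pc$p_cs_given_us)
      complex <- c(complex, trial$us_time + pc$complex_spike_latency)
    complex <- sort(unique(round(complex)))
  }
  # post-complex-spike pause in simple spikes
  for (cs in complex)
    simple <- simple[!(simple > cs & simple <= cs + pc$post_cs_pause)]
  simple <- setdiff(simple, complex)

  rbind(
    if (length(simple)) data.frame(time_ms = simple, spike_type = "simple",
                                   stringsAsFactors = FALSE),
    if (length(complex)) data.frame(time_ms = complex, spike_type = "complex",
                                    stringsAsFactors = FALSE)
  ) -> out
  if (is.null(out))
    out <- data.frame(time_ms = numeric(), spike_type = character(),
                      stringsAsFactors = FALSE)
  out[order(out$time_ms), , drop = FALSE]
}
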