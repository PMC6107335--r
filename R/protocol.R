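#' Trial time grid
#'
#' Sample times (ms, 1 kHz) for a behavioral trial window. t = 0 is CS onset;
#' the default window is 200 ms pre-CS plus 2300 ms post-CS.
#'
#' @param t0 Time of the first sample in ms (default -200).
#' @param n Number of 1-ms samples (default 2500).
#' @return Integer vector of sample times in ms.
#' @export
trial_time_grid <- function(t0 = -200, n = 2500) {
  as.numeric(seq.int(t0, by = 1, length.out = n))
}

# index of time t on a grid starting at t0 with 1 ms steps (1-based)
t_index <- function(t, t0 = -200) as.integer(round(t - t0)) + 1L

# logical mask for the half-open window [a, b) on grid `t`
win_mask <- function(t, a, b) t >= a & t < b

#' Protocol configuration
#'
#' Describes one training protocol: the amplitude-contingent ipsilateral or
#' contralateral sequence protocol, or the CS2 transfer-test session. Sessions
#' are composed of blocks of 1 CS-alone + 8 paired trials (ipsi/contra), or of
#' a CS1/CS2 trial mix (cs2_test). The US is scheduled by the contingency
#' rule: first-CR amplitude below `target_amplitude` at the scheduled US1 time
#' triggers US1 at CS offset; at or above target, US1 is omitted and US2 is
#' delivered `gap_interval` ms after CS offset.
#'
#' @param protocol One of `"ipsilateral"`, `"contralateral"`, `"cs2_test"`.
#' @param cs_duration CS duration in ms (default 500).
#' @param isi CS-onset-to-US1 interval in ms (default 500; US1 at CS offset).
#' @param gap_interval CS-offset-to-US2 interval in ms; one of 300, 400, 500,
#'   600 (default 600 for ipsilateral, 400 for contralateral).
#' @param target_amplitude Contingency target in mm (default 3.0, half of full
#'   closure).
#' @param full_closure Full eyelid closure in mm (default 6.0).
#' @param n_blocks Number of blocks per session (default 12).
#' @param trials_per_block Trials per block (default 9: 1 CS-alone + 8 paired).
#' @param cs2_mix Named fractions of trial types for cs2_test sessions
#'   (must sum to 1).
#' @param n_trials_cs2 Total trials in a cs2_test session (default 108).
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(protocol = c("ipsilateral", "contralateral", "cs2_test"),
                            cs_duration = 500, isi = 500,
                            gap_interval = NULL,
                            target_amplitude = 3.0, full_closure = 6.0,
                            n_blocks = 12, trials_per_block = 9,
                            cs2_mix = c(cs1_paired = 0.60, cs2_paired = 0.25,
                                        cs2_alone = 0.15),
                            n_trials_cs2 = 108) {
  protocol <- match.arg(protocol)
  if (is.null(gap_interval))
    gap_interval <- if (protocol == "contralateral") 400 else 600
  if (!gap_interval %in% c(300, 400, 500, 600))
    stop("gap_interval must be one of 300, 400, 500, 600 ms")
  if (abs(sum(cs2_mix) - 1) > 1e-8)
    stop("cs2_mix fractions must sum to 1")
  if (target_amplitude <= 0 || full_closure <= 0)
    stop("amplitudes must be positive")
  structure(list(protocol = protocol, cs_duration = cs_duration, isi = isi,
                 gap_interval = gap_interval,
                 target_amplitude = target_amplitude,
                 full_closure = full_closure, n_blocks = n_blocks,
                 trials_per_block = trials_per_block, cs2_mix = cs2_mix,
                 n_trials_cs2 = n_trials_cs2),
            class = "protocol_config")
}

#' Behavioral generator parameters
#'
#' Parameters of the synthetic CR-sequence generator. In `chained` mode the
#' second (and later) CR timing is a deterministic function of the previous CR
#' timing plus jitter, emulating a feedback-driven chain; in `independent`
#' mode later-CR timing is drawn without reference to the previous CR (the
#' null used for calibration of shuffle tests). Second CRs occur only on
#' trials with a first CR; a first CR at or above `gate` (the protocol target
#' amplitude) chains with probability `p_second_given_gate`, while sub-gate
#' first CRs chain with probability scaled down by `(amp/gate)^2`.
#'
#' `transfer_mode` controls CS2-test generation: `"feedback"` chains off any
#' first CR regardless of which CS elicited it; `"cs_bound"` chains only on
#' CS1 trials (the alternative generative model the CS2 analysis must reject).
#'
#' @param p_first_cr Probability of a first CR per trial; scalar or per-trial
#'   vector (recycled), allowing acquisition/extinction schedules.
#' @param first_onset_mean,first_onset_sd First-CR onset distribution (ms).
#' @param first_amp_mean,first_amp_sd First-CR amplitude distribution (mm),
#'   truncated to `[0, full_closure]`.
#' @param rise_time,decay_time CR waveform kinematics (ms).
#' @param chain_mode `"chained"` or `"independent"`.
#' @param chain_gain Slope of second-CR onset on first-CR onset in chained
#'   mode (default 1).
#' @param inter_cr_interval Mean onset-to-onset spacing of successive CRs
#'   (ms). The default `NULL` derives the spacing from the protocol so that
#'   the chained CR peaks at the scheduled US2 time (the timing the
#'   contingency reinforces): `us2_time - rise_time - first_onset_mean`.
#' @param interval_jitter_sd SD of spacing jitter (ms).
#' @param p_second_given_gate Probability that a supra-gate CR is followed by
#'   the next CR; scalar or per-trial vector (recycled).
#' @param amp_decay Ratio of successive CR amplitudes.
#' @param amp_noise_sd SD of additive amplitude noise for later CRs (mm).
#' @param min_cr_amp Minimum amplitude of a chained CR (mm, default 0.8):
#'   the chain stops rather than plant a closure too small to count as a CR.
#' @param noise_sd SD of additive Gaussian trace noise (mm).
#' @param transfer_mode `"feedback"` or `"cs_bound"` (cs2_test sessions only).
#' @return A `gen_params` list.
#' @export
gen_params <- function(p_first_cr = 0.9,
                       first_onset_mean = 300, first_onset_sd = 40,
                       first_amp_mean = 4.0, first_amp_sd = 1.2,
                       rise_time = 180, decay_time = 150,
                       chain_mode = c("chained", "independent"),
                       chain_gain = 1,
                       inter_cr_interval = NULL, interval_jitter_sd = 30,
                       p_second_given_gate = 0.7,
                       amp_decay = 0.75, amp_noise_sd = 0.3,
                       min_cr_amp = 0.8, noise_sd = 0.05,
                       transfer_mode = c("feedback", "cs_bound")) {
  chain_mode <- match.arg(chain_mode)
  transfer_mode <- match.arg(transfer_mode)
  stopifnot(all(p_first_cr >= 0 & p_first_cr <= 1),
            all(p_second_given_gate >= 0 & p_second_given_gate <= 1),
            rise_time > 0, decay_time > 0,
            is.null(inter_cr_interval) || inter_cr_interval > 0,
            interval_jitter_sd >= 0, amp_decay >= 0, noise_sd >= 0)
  structure(list(p_first_cr = p_first_cr,
                 first_onset_mean = first_onset_mean,
                 first_onset_sd = first_onset_sd,
                 first_amp_mean = first_amp_mean, first_amp_sd = first_amp_sd,
                 rise_time = rise_time, decay_time = decay_time,
                 chain_mode = chain_mode, chain_gain = chain_gain,
                 inter_cr_interval = inter_cr_interval,
                 interval_jitter_sd = interval_jitter_sd,
                 p_second_given_gate = p_second_given_gate,
                 amp_decay = amp_decay, amp_noise_sd = amp_noise_sd,
                 min_cr_amp = min_cr_amp, noise_sd = noise_sd,
                 transfer_mode = transfer_mode),
            class = "gen_params")
}

#' Purkinje-cell generator parameters
#'
#' Parameters for synthetic eyelid-PC spike trains. Simple spikes follow an
#' inhomogeneous Poisson process whose rate dips below baseline in proportion
#' to the CR profile, led by `dip_lead` ms (the rate decrease precedes CR
#' onset); each delivered US is followed by one complex spike after
#' `complex_spike_latency` ms and a simple-spike pause of `post_cs_pause` ms.
#'
#' @param baseline_rate Baseline simple-spike rate (Hz), > 0.
#' @param dip_depth Fractional rate decrease per mm of CR amplitude
#'   (`dip_depth * full_closure` must be <= 1).
#' @param dip_lead Lead of the rate decrease relative to the eyelid trace (ms).
#' @param complex_spike_latency Complex-spike latency after the US (ms).
#' @param post_cs_pause Simple-spike pause after each complex spike (ms), > 0.
#' @param cs_locked_to_us If `FALSE`, complex spikes occur only at random
#'   times instead of US-locked (a non-eyelid PC).
#' @param p_cs_given_us Probability that a delivered US evokes a complex
#'   spike (default 0.9).
#' @param spont_cs_rate Spontaneous complex-spike rate (Hz, default 1).
#' @param has_complex If `FALSE`, no complex spikes at all (not a PC).
#' @param pre_window Pre-CS spike recording span (ms, default 1500).
#' @return A `pc_gen_params` list.
#' @export
pc_gen_params <- function(baseline_rate = 80, dip_depth = 0.12,
                          dip_lead = 50, complex_spike_latency = 3,
                          post_cs_pause = 15, cs_locked_to_us = TRUE,
                          p_cs_given_us = 0.9, spont_cs_rate = 1,
                          has_complex = TRUE, pre_window = 1500) {
  stopifnot(baseline_rate > 0, dip_depth >= 0, post_cs_pause > 0,
            pre_window >= 1500, p_cs_given_us >= 0, p_cs_given_us <= 1,
            spont_cs_rate >= 0)
  structure(list(baseline_rate = baseline_rate, dip_depth = dip_depth,
                 dip_lead = dip_lead,
                 complex_spike_latency = complex_spike_latency,
                 post_cs_pause = post_cs_pause,
                 cs_locked_to_us = cs_locked_to_us,
                 p_cs_given_us = p_cs_given_us, spont_cs_rate = spont_cs_rate,
                 has_complex = has_complex, pre_window = pre_window),
            class = "pc_gen_params")
}

# scheduled US times (ms from CS onset) for a protocol config
us_times_for <- function(cfg) {
  list(us1 = cfg$isi, us2 = cfg$cs_duration + cfg$gap_interval)
}
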