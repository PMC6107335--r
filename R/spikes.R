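# Gaussian kernel smoothing with edge renormalization: near the window
# edges the kernel is renormalized to unit mass inside the window, avoiding
# artificial dips.
gaussian_smooth <- function(x, sd_ms = 20, dt = 1) {
  r <- ceiling(4 * sd_ms / dt)
  k <- stats::dnorm(seq(-r, r) * dt, sd = sd_ms)
  k <- k / sum(k)
  n <- length(x)
  num <- stats::convolve(x, rev(k), type = "open")[(r + 1):(r + n)]
  den <- stats::convolve(rep(1, n), rev(k), type = "open")[(r + 1):(r + n)]
  num / den
}

#' Instantaneous firing rate from a spike train
#'
#' Estimates the simple-spike rate on one trial as the inverse inter-spike
#' interval (a piecewise-constant rate of `1000/ISI` Hz between consecutive
#' spikes, extended to the window edges), followed by a two-sided Gaussian
#' kernel with 20 ms standard deviation (unit area; renormalized at window
#' edges). Trials with fewer than two spikes return a zero series with
#' `flagged = TRUE`.
#'
#' @param spike_times Sorted simple-spike times (ms, trial clock).
#' @param t Time grid (ms, 1 kHz) on which to evaluate the rate.
#' @param kernel_sd Gaussian kernel SD (ms, default 20).
#' @return List of class `rate_series`: `t`, `rate` (Hz), `flagged`.
#' @export
instantaneous_rate <- function(spike_times, t, kernel_sd = 20) {
  if (is.unsorted(spike_times)) stop("spike times must be sorted")
  if (length(spike_times) < 2)
    return(structure(list(t = t, rate = numeric(length(t)), flagged = TRUE),
                     class = "rate_series"))
  s <- spike_times
  k <- length(s)
  isi_rate <- 1000 / diff(s)
  # piecewise-constant 1/ISI rate, extended to the window edges with the
  # median ISI rate (a single edge ISI is heavy-tailed through 1/ISI),
  # discretized by exact integration over each 1-ms bin (the cumulative
  # integral is piecewise-linear, so linear interpolation of it is exact;
  # avoids aliasing of sub-bin ISIs)
  lo <- min(t[1], s[1]) - 1
  hi <- max(t[length(t)] + 1, s[k]) + 1
  breaks <- c(lo, s, hi)
  edge_rate <- median(isi_rate)
  seg_rate <- c(edge_rate, isi_rate, edge_rate)
  cum <- c(0, cumsum(seg_rate * diff(breaks)))
  at <- function(q) approx(breaks, cum, xout = q)$y
  raw <- at(t + 1) - at(t)   # Hz x ms over a 1-ms bin = mean Hz in the bin
  structure(list(t = t, rate = gaussian_smooth(raw, kernel_sd),
                 flagged = FALSE),
            class = "rate_series")
}

#' Normalize a rate series by its pre-CS baseline
#'
#' Divides the rate by its mean over the baseline window (1500 ms of pre-CS
#' activity by default), giving a dimensionless series with baseline near 1.
#'
#' @param rs A `rate_series` from [instantaneous_rate()].
#' @param baseline Baseline window `[a, b)` in ms (default `c(-1500, 0)`).
#' @return A normalized `rate_series` (`flagged = TRUE` and zero series if
#'   the baseline mean is zero).
#' @export
normalize_rate <- function(rs, baseline = c(-1500, 0)) {
  m <- win_mask(rs$t, baseline[1], baseline[2])
  if (!any(m)) stop("baseline window outside recorded span")
  b <- mean(rs$rate[m])
  if (!is.finite(b) || b <= 0) {
    rs$flagged <- TRUE
    rs$rate <- numeric(length(rs$rate))
  } else {
    rs$rate <- rs$rate / b
    rs$baseline_hz <- b
  }
  rs
}

#' Classify a unit as eyelid PC, non-eyelid PC, or not a PC
#'
#' A unit counts as a Purkinje cell if complex spikes are present and the
#' complex-spike-triggered simple-spike average shows a post-complex-spike
#' pause (simple-spike rate below `pause_frac` of the pre-event rate for at
#' least `pause_min_ms` consecutive ms within `pause_window_ms` after the
#' complex spike). An eyelid PC additionally shows US-evoked complex spikes:
#' the fraction of US deliveries followed by a complex spike within
#' `us_window_ms` must reach `us_frac`.
#'
#' @param simple,complex Spike time vectors (ms) pooled over the session
#'   (complex times on the same clock).
#' @param us_times Delivered-US times (ms, absolute on the same clock);
#'   length 0 makes the eyelid-PC check undefined (returns NA with a
#'   warning if the unit is otherwise a PC).
#' @param pause_frac,pause_min_ms,pause_window_ms Pause-detection tunables.
#' @param us_window_ms,us_frac US-evoked complex-spike tunables.
#' @return List: `classification` (`"eyelid_pc"`, `"non_eyelid_pc"`,
#'   `"not_pc"` or NA), `pause_ok`, `us_cs_fraction`.
#' @export
verify_eyelid_pc <- function(simple, complex, us_times,
                             pause_frac = 0.5, pause_min_ms = 8,
                             pause_window_ms = 20,
                             us_window_ms = 10, us_frac = 0.5) {
  if (length(complex) == 0)
    return(list(classification = "not_pc", pause_ok = FALSE,
                us_cs_fraction = NA_real_))
  # complex-spike-triggered simple-spike histogram at 1 ms resolution
  pre_lo <- -50
  offs <- unlist(lapply(complex, function(cs) {
    d <- simple - cs
    d[d >= pre_lo & d <= pause_window_ms]
  }))
  ncs <- length(complex)
  pre_rate <- sum(offs >= pre_lo & offs < 0) / (abs(pre_lo) * ncs)
  post <- vapply(seq_len(pause_window_ms), function(b)
    sum(offs > b - 1 & offs <= b) / ncs, 0)
  below <- post < pause_frac * pre_rate
  runs <- rle(below)
  pause_ok <- any(runs$values & runs$lengths >= pause_min_ms)
  if (!pause_ok)
    return(list(classification = "not_pc", pause_ok = FALSE,
                us_cs_fraction = NA_real_))
  if (length(us_times) == 0) {
    warning("no US trials: eyelid-PC check undefined")
    return(list(classification = NA_character_, pause_ok = TRUE,
                us_cs_fraction = NA_real_))
  }
  evoked <- vapply(us_times, function(u)
    any(complex > u & complex <= u + us_window_ms), NA)
  frac <- mean(evoked)
  list(classification = if (frac >= us_frac) "eyelid_pc" else "non_eyelid_pc",
       pause_ok = TRUE, us_cs_fraction = frac)
}

#' Group trials by a CR key
#'
#' Trials without the keyed response form their own non-CR group; CR trials
#' are sorted by the key and split into `n_groups` near-equal ordered groups
#' (remainder to the earliest groups). For second-CR keys only trials with a
#' first CR larger than `first_amp_gate` are eligible.
#'
#' @param outcomes Outcomes data.frame.
#' @param key One of `"first_onset"`, `"first_amp"`, `"second_onset"`,
#'   `"second_amp"`.
#' @param n_groups Number of CR subgroups (default 3).
#' @param first_amp_gate First-CR amplitude gate for second-CR keys (mm,
#'   default 3).
#' @return List: `non_cr` (trial ids) and `groups` (list of trial-id
#'   vectors, ordered by increasing key).
#' @export
group_trials <- function(outcomes,
                         key = c("first_onset", "first_amp",
                                 "second_onset", "second_amp"),
                         n_groups = 3, first_amp_gate = 3) {
  key <- match.arg(key)
  second <- startsWith(key, "second")
  if (second) {
    eligible <- outcomes[outcomes$first_present &
                           outcomes$first_amp > first_amp_gate &
                           outcomes$second_eligible, , drop = FALSE]
    is_cr <- eligible$second_present
  } else {
    eligible <- outcomes
    is_cr <- eligible$first_present
  }
  cr <- eligible[is_cr, , drop = FALSE]
  if (nrow(cr) < n_groups) stop("fewer CR trials than groups")
  ord <- order(cr[[key]])
  sizes <- rep(nrow(cr) %/% n_groups, n_groups)
  rem <- nrow(cr) %% n_groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  grp <- rep(seq_len(n_groups), sizes)
  list(non_cr = eligible$trial_id[!is_cr],
       groups = lapply(seq_len(n_groups), function(g)
         cr$trial_id[ord[grp == g]]))
}

#' Average rate series with pointwise 95% confidence interval
#'
#' Pointwise mean across trials with a 95% CI (mean +/- 1.96 SEM); the
#' absence of CI overlap between two groups at a time point is used as
#' evidence of reliable separation (see [ci_separation()]).
#'
#' @param mat Trials x time matrix of (normalized) rates.
#' @param t Time grid (ms).
#' @return List of class `rate_series` with `rate` (mean), `ci_low`,
#'   `ci_high`, `n_trials`.
#' @export
average_with_ci <- function(mat, t) {
  if (is.null(dim(mat)) || nrow(mat) < 2)
    stop("need at least 2 trials for a CI")
  m <- colMeans(mat)
  sem <- apply(mat, 2, sd) / sqrt(nrow(mat))
  structure(list(t = t, rate = m, ci_low = m - 1.96 * sem,
                 ci_high = m + 1.96 * sem, n_trials = nrow(mat)),
            class = "rate_series")
}

#' Pointwise CI separation between two averaged series
#'
#' @param a,b `rate_series` objects from [average_with_ci()] on the same
#'   grid.
#' @return Logical vector: TRUE where the 95% CIs do not overlap.
#' @export
ci_separation <- function(a, b) {
  a$ci_high < b$ci_low | b$ci_high < a$ci_low
}

#' Lead time of the pre-onset CI separation
#'
#' Finds the contiguous run of CI separation that contains aligned time 0
#' and returns how many ms before 0 it begins (positive = the separation
#' precedes CR onset). Isolated spurious crossings elsewhere are ignored.
#'
#' @param sep Logical separation vector from [ci_separation()].
#' @param tau Aligned time grid (ms).
#' @return Lead in ms (positive if separation starts before 0), or NA if
#'   the groups are not separated at time 0.
#' @export
separation_lead <- function(sep, tau) {
  r <- rle(sep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i0 <- which(tau == 0)
  j <- which(r$values & starts <= i0 & ends >= i0)
  if (!length(j)) return(NA_real_)
  -tau[starts[j]]
}

#' Align rate series to CR onset
#'
#' Shifts each CR trial's rate series so that its CR onset maps to aligned
#' time 0; non-CR trials are assigned a pseudo-onset drawn (seeded, with
#' replacement) from the empirical distribution of CR onset times. Averages
#' and 95% CIs are computed on the aligned grid, and the pre-onset decrease
#' metric is the mean normalized rate of CR trials at aligned time 0.
#'
#' @param mat Trials x time matrix of normalized rates.
#' @param t Time grid (ms) of `mat` columns.
#' @param onsets CR onset per trial (ms; NA for non-CR trials).
#' @param window Aligned window `c(lo, hi)` in ms around onset.
#' @param seed Seed for pseudo-onset sampling.
#' @return List: `tau` (aligned grid), `cr` and `non_cr` (averaged
#'   `rate_series`), `metric_at_onset` (mean CR-trial rate at aligned 0),
#'   `onsets_used`.
#' @export
align_to_cr_onset <- function(mat, t, onsets, window = c(-300, 300),
                              seed = 1) {
  cr_idx <- which(!is.na(onsets))
  if (!length(cr_idx)) stop("empty onset distribution")
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(seed)
  non_idx <- which(is.na(onsets))
  pseudo <- sample(onsets[cr_idx], length(non_idx), replace = TRUE)
  all_onsets <- onsets
  all_onsets[non_idx] <- pseudo
  tau <- seq(window[1], window[2])
  shift_one <- function(i)
    approx(t, mat[i, ], xout = all_onsets[i] + tau, rule = 2)$y
  cr_mat <- do.call(rbind, lapply(cr_idx, shift_one))
  out <- list(tau = tau, cr = average_with_ci(cr_mat, tau),
              non_cr = NULL, onsets_used = all_onsets)
  if (length(non_idx) >= 2)
    out$non_cr <- average_with_ci(do.call(rbind, lapply(non_idx, shift_one)),
                                  tau)
  out$metric_at_onset <- mean(cr_mat[, which(tau == 0)])
  out
}

#' Pooled PC study across simulated units
#'
#' Generates one session per unit (one seed each), decomposes the behavior,
#' and pools the per-trial normalized rate series and outcomes across units,
#' mirroring a multi-cell eyelid-PC study. Trial ids are made unique across
#' units.
#'
#' @param seeds Integer vector, one seed per simulated unit/session.
#' @param cfg,gen,pc Generator configurations (see [generate_session()]).
#' @return List: `t` (rate grid), `mat` (pooled trials x time normalized
#'   rates), `outcomes` (pooled, row-matched to `mat`).
#' @export
pool_pc_sessions <- function(seeds, cfg = protocol_config(),
                             gen = gen_params(), pc = pc_gen_params()) {
  mats <- list(); outs <- list()
  tt <- NULL
  for (u in seq_along(seeds)) {
    s <- generate_session(cfg, gen, pc = pc, seed = seeds[u])
    dec <- decompose_session(s)
    rm <- session_rate_matrix(s)
    tt <- rm$t
    o <- dec$outcomes[match(rm$trial_ids, dec$outcomes$trial_id), ,
                      drop = FALSE]
    keep <- !is.na(o$trial_id)
    o <- o[keep, , drop = FALSE]
    o$trial_id <- o$trial_id + u * 100000
    mats[[u]] <- rm$mat[keep, , drop = FALSE]
    outs[[u]] <- o
  }
  list(t = tt, mat = do.call(rbind, mats), outcomes = do.call(rbind, outs))
}

#' Per-trial normalized rate matrix for a session's recorded unit
#'
#' Convenience wrapper: estimates and baseline-normalizes the simple-spike
#' rate of every spike-carrying trial of a generated or imported session.
#'
#' @param session A `cr_session` with a `spikes` table.
#' @param unit_id Unit to extract (default the first).
#' @return List: `t` (extended grid incl. 1500 ms pre-CS), `mat` (trials x
#'   time normalized rates), `trial_ids`.
#' @export
session_rate_matrix <- function(session, unit_id = NULL) {
  sp <- session$spikes
  if (is.null(sp)) stop("session has no spike data")
  if (is.null(unit_id)) unit_id <- sp$unit_id[1]
  sp <- sp[sp$unit_id == unit_id & sp$spike_type == "simple", ]
  pre <- if (!is.null(session$pc)) session$pc$pre_window else 1500
  tt <- seq(-pre, max(session$t))
  ids <- sort(unique(sp$trial_id))
  mat <- do.call(rbind, lapply(ids, function(id) {
    rs <- instantaneous_rate(sort(sp$time_ms[sp$trial_id == id]), tt)
    normalize_rate(rs)$rate
  }))
  list(t = tt, mat = mat, trial_ids = ids)
}
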