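#' Session-level CR sequence summary
#'
#' First-CR probability is the fraction of analyzable trials with a first CR;
#' second-CR probability is the fraction of trials with a first CR (and with
#' the second response observable, i.e. squint gate passed and no truncation
#' at US1) on which a second CR was present too. Mean amplitudes are taken
#' over the respective CR trials. Undefined probabilities (zero denominator)
#' are reported as NA, not 0.
#'
#' @param outcomes Outcomes data.frame from [decompose_session()].
#' @return One-row data.frame with `n_trials`, `p_first`, `p_second`,
#'   `mean_first_amp`, `mean_second_amp` and the denominators used.
#' @export
session_summary <- function(outcomes) {
  n <- nrow(outcomes)
  n_first <- sum(outcomes$first_present)
  sec_den <- outcomes$first_present & outcomes$second_eligible
  n_sec_den <- sum(sec_den)
  data.frame(
    n_trials = n,
    p_first = if (n > 0) n_first / n else NA_real_,
    p_second = if (n_sec_den > 0)
      sum(outcomes$second_present[sec_den]) / n_sec_den else NA_real_,
    n_first = n_first, n_second_denom = n_sec_den,
    mean_first_amp = if (n_first > 0)
      mean(outcomes$first_amp[outcomes$first_present]) else NA_real_,
    mean_second_amp = if (any(outcomes$second_present))
      mean(outcomes$second_amp[outcomes$second_present]) else NA_real_)
}

#' Within-session acquisition/extinction curve
#'
#' Splits the chronologically ordered trials of a session into `n_portions`
#' contiguous, near-equal portions (any remainder spread over the earliest
#' portions) and summarises each with [session_summary()], to evaluate the
#' time course of acquisition or extinction through the session.
#'
#' @param outcomes Chronologically ordered outcomes data.frame.
#' @param n_portions Number of portions (default 8).
#' @return Data frame: one row per portion with the summary columns.
#' @export
extinction_curve <- function(outcomes, n_portions = 8) {
  n <- nrow(outcomes)
  if (n < n_portions) stop("fewer trials than portions")
  sizes <- rep(n %/% n_portions, n_portions)
  rem <- n %% n_portions
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  idx <- rep(seq_len(n_portions), sizes)
  out <- do.call(rbind, lapply(seq_len(n_portions), function(k)
    session_summary(outcomes[idx == k, , drop = FALSE])))
  cbind(portion = seq_len(n_portions), out)
}

#' Second-CR probability conditioned on first-CR amplitude
#'
#' Bins trials by first-CR amplitude (first bin = non-CR, amplitude below the
#' 0.3 mm criterion) and estimates the probability of a second CR per bin,
#' with 95% percentile-bootstrap confidence intervals (trials resampled
#' within bin) and a chi-square test of association on the bins'
#' present/absent contingency table. Empty bins are reported as NA and
#' excluded from the chi-square with the degrees of freedom reduced
#' accordingly.
#'
#' @param outcomes Outcomes restricted by the caller to the trials of
#'   interest (e.g. CS-alone trials from sessions with second-CR probability
#'   above 40%); only rows with `second_eligible` are used.
#' @param bin_edges Interior amplitude bin edges in mm (default
#'   `c(0.3, 1, 2, 3, 4, 5)`, giving 7 bins: non-CR, 0.3-1, ..., >= 5).
#' @param n_boot Bootstrap repetitions (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `cond_prob_table`: `table` (per-bin n, p_second,
#'   ci_low, ci_high), `chi2`, `df`, `p_value`, `n_total`, `seed`.
#' @export
conditional_probability <- function(outcomes, bin_edges = c(0.3, 1, 2, 3, 4, 5),
                                    n_boot = 2000, seed = 1) {
  d <- outcomes[outcomes$second_eligible, , drop = FALSE]
  breaks <- c(-Inf, bin_edges, Inf)
  labs <- c(sprintf("<%.1f", bin_edges[1]),
            paste0(head(bin_edges, -1), "-", tail(bin_edges, -1)),
            sprintf(">=%.1f", tail(bin_edges, 1)))
  bin <- cut(d$first_amp, breaks, labels = labs, right = FALSE)
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(seed)
  per_bin <- lapply(levels(bin), function(b) {
    y <- d$second_present[bin == b]
    n <- length(y)
    if (n == 0)
      return(data.frame(bin = b, n = 0L, n_second = 0L, p_second = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    p <- mean(y)
    boot <- colMeans(matrix(sample(y, n * n_boot, replace = TRUE), n))
    ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
    data.frame(bin = b, n = n, n_second = sum(y), p_second = p,
               ci_low = ci[1], ci_high = ci[2])
  })
  tab <- do.call(rbind, per_bin)
  nonempty <- tab$n > 0
  chi2 <- df <- p_value <- NA_real_
  if (sum(nonempty) >= 2) {
    ct <- rbind(yes = tab$n_second[nonempty],
                no = tab$n[nonempty] - tab$n_second[nonempty])
    if (sum(ct["yes", ]) > 0 && sum(ct["no", ]) > 0) {
      ht <- suppressWarnings(chisq.test(ct))
      chi2 <- unname(ht$statistic); df <- unname(ht$parameter)
      p_value <- ht$p.value
    }
  }
  structure(list(table = tab, chi2 = chi2, df = df, p_value = p_value,
                 n_total = sum(tab$n), seed = seed),
            class = "cond_prob_table")
}

#' Normalized-fraction timing of a CR profile
#'
#' Normalizes a CR profile by its peak value, then, from the onset fraction
#' up to 1.0 in `step` increments, finds the first time within
#' `[onset, peak_time]` at which the normalized profile reaches each
#' fraction, with linear interpolation between samples. Non-monotone profiles
#' use the first crossing.
#'
#' @param x Position series (mm).
#' @param t Time grid (ms).
#' @param onset,peak_time Event bounds (ms), `onset < peak_time`.
#' @param step Fraction increment (default 0.005).
#' @return Data frame with `fraction` and `time_ms`.
#' @export
fraction_times <- function(x, t = trial_time_grid(), onset, peak_time,
                           step = 0.005) {
  stopifnot(onset < peak_time)
  seg <- which(t >= onset & t <= peak_time)
  xs <- x[seg]; ts <- t[seg]
  peak <- xs[length(xs)]
  if (peak <= 0) stop("non-positive peak value")
  norm <- xs / peak
  run <- cummax(norm)
  f0 <- norm[1]
  levels <- seq(ceiling(f0 / step) * step, 1, by = step)
  if (tail(levels, 1) < 1) levels <- c(levels, 1)
  time_at <- vapply(levels, function(f) {
    i <- which(run >= f)[1]
    if (is.na(i)) return(ts[length(ts)])
    if (i == 1 || norm[i - 1] >= f) return(ts[i])
    ts[i - 1] + (f - norm[i - 1]) / (norm[i] - norm[i - 1])
  }, 0)
  data.frame(fraction = levels, time_ms = time_at)
}

#' Trial-by-trial co-variation of CR timing measures
#'
#' Collects, per qualifying trial, a timing measure of one CR in the
#' sequence against a timing measure of the following CR, and computes the
#' Pearson correlation. Trials qualify when both CR amplitudes exceed
#' `amp_threshold` (2 mm default); for pairs involving the third or later CR
#' only CS-alone trials are used. Outliers further than `outlier_sd`
#' standard deviations from the mean in either coordinate are discarded.
#'
#' @param events Events data.frame from [decompose_session()].
#' @param outcomes Matching outcomes data.frame (for trial types).
#' @param pair Integer pair of CR ordinals, default `c(1, 2)`.
#' @param measure_first,measure_second Column names of the timing measures
#'   (default `"latency_to_criterion"` for both).
#' @param amp_threshold Amplitude inclusion threshold (mm, default 2).
#' @param outlier_sd Outlier cut in SDs (default 3).
#' @return List of class `timing_pair`: `pairs` (t_first, t_second per
#'   trial), `intervals`, `r`, `p_value`, `n`, `n_outliers`.
#' @export
timing_covariation <- function(events, outcomes, pair = c(1, 2),
                               measure_first = "latency_to_criterion",
                               measure_second = measure_first,
                               amp_threshold = 2, outlier_sd = 3) {
  e1 <- events[events$index_in_sequence == pair[1], ]
  e2 <- events[events$index_in_sequence == pair[2], ]
  ids <- intersect(e1$trial_id, e2$trial_id)
  if (max(pair) >= 3) {
    cs_alone <- outcomes$trial_id[outcomes$type %in% c("cs_alone", "cs2_alone")]
    ids <- intersect(ids, cs_alone)
  }
  e1 <- e1[match(ids, e1$trial_id), ]
  e2 <- e2[match(ids, e2$trial_id), ]
  ok <- e1$amplitude > amp_threshold & e2$amplitude > amp_threshold
  d <- data.frame(trial_id = ids[ok],
                  t_first = e1[[measure_first]][ok],
                  t_second = e2[[measure_second]][ok])
  n0 <- nrow(d)
  out <- rep(FALSE, n0)
  if (n0 >= 3) {
    for (col in c("t_first", "t_second")) {
      z <- abs(d[[col]] - mean(d[[col]]))
      s <- sd(d[[col]])
      if (is.finite(s) && s > 0) out <- out | z > outlier_sd * s
    }
  }
  d <- d[!out, , drop = FALSE]
  r <- p <- NA_real_
  if (nrow(d) >= 3 && sd(d$t_first) > 0 && sd(d$t_second) > 0) {
    ct <- cor.test(d$t_first, d$t_second)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(pairs = d, intervals = d$t_second - d$t_first, r = r,
                 p_value = p, n = nrow(d), n_outliers = sum(out)),
            class = "timing_pair")
}

# two-sample KS statistic between a sample x and a large sorted pool,
# evaluated at the unique sample values with both right limits and left
# limits (ties handled correctly: tied atoms jump together)
ks_stat_vs_pool <- function(pool_sorted, x) {
  v <- sort(unique(x))
  n <- length(x)
  N <- length(pool_sorted)
  f2 <- cumsum(tabulate(match(sort(x), v))) / n
  f2m <- c(0, f2[-length(f2)])
  f1 <- findInterval(v, pool_sorted) / N
  f1m <- findInterval(v, pool_sorted, left.open = TRUE) / N
  max(abs(f1 - f2), abs(f1m - f2m))
}

#' Shuffle null for inter-CR intervals
#'
#' Tests whether the inter-CR interval distribution is tighter than expected
#' if the two timings were independent: the first-CR timings are randomly
#' permuted across trials (`n_perm` times, sampling without replacement),
#' intervals recomputed and pooled into a shuffled distribution, and the true
#' intervals compared to the pool with a two-sample Kolmogorov-Smirnov
#' statistic. The primary p-value is permutation-calibrated (the observed KS
#' statistic ranked among each permutation's own KS statistic against the
#' pool); the classical asymptotic KS p-value is also reported as `ks_p`.
#'
#' @param t_first,t_second Paired timing measures (ms), one pair per trial.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @return List of class `shuffle_null`: `true_intervals`,
#'   `shuffled_intervals` (pooled), `ks_stat`, `p` (permutation-calibrated),
#'   `ks_p`, `n_perm`, `seed`.
#' @export
shuffle_null <- function(t_first, t_second, n_perm = 2000, seed = 1) {
  stopifnot(length(t_first) == length(t_second), length(t_first) >= 2)
  restore <- preserve_rng()
  on.exit(restore())
  set.seed(seed)
  n <- length(t_first)
  true_int <- t_second - t_first
  perm <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- t_second - sample(t_first)
  pool <- sort(as.vector(perm))
  d_obs <- ks_stat_vs_pool(pool, true_int)
  d_perm <- apply(perm, 2, function(col) ks_stat_vs_pool(pool, col))
  p_perm <- (1 + sum(d_perm >= d_obs)) / (n_perm + 1)
  ks_p <- suppressWarnings(ks.test(true_int, as.vector(perm))$p.value)
  structure(list(true_intervals = true_int, shuffled_intervals = as.vector(perm),
                 ks_stat = d_obs, p = p_perm, ks_p = ks_p,
                 n_perm = n_perm, seed = seed),
            class = "shuffle_null")
}

#' CS2 transfer analysis
#'
#' For each CS2 test session, computes the second-CR probability in three
#' trial groups: CS1 trials with a supra-target first CR, CS2-alone trials
#' with a supra-target first CR, and CS2-alone trials without a first CR.
#' Under a feedback-driven chain the CS1 and CS2 group probabilities should
#' be near-equal (and co-vary across sessions), while a CS-bound second CR
#' would give a near-zero CS2-group probability. Also reports the Pearson
#' correlation of CS1- and CS2-group probabilities across sessions.
#'
#' @param outcomes_list List of per-session outcomes data.frames (CS2 test
#'   sessions).
#' @param amp_gate First-CR amplitude gate in mm (default 3).
#' @return List of class `cs2_transfer`: `per_session` (p_cs1, p_cs2,
#'   p_cs2_nofirst per session, NA when a group is missing), group means, and
#'   `r`/`r_p` across sessions.
#' @export
cs2_transfer <- function(outcomes_list, amp_gate = 3) {
  rows <- lapply(seq_along(outcomes_list), function(s) {
    o <- outcomes_list[[s]]
    grp_p <- function(sel) {
      sel <- sel & o$second_eligible
      if (!any(sel)) NA_real_ else mean(o$second_present[sel])
    }
    data.frame(
      session = s,
      p_cs1 = grp_p(o$type == "paired" & o$first_present &
                      o$first_amp > amp_gate),
      p_cs2 = grp_p(o$type == "cs2_alone" & o$first_present &
                      o$first_amp > amp_gate),
      p_cs2_nofirst = grp_p(o$type == "cs2_alone" & !o$first_present))
  })
  per_session <- do.call(rbind, rows)
  r <- r_p <- NA_real_
  ok <- stats::complete.cases(per_session[, c("p_cs1", "p_cs2")])
  if (sum(ok) >= 3 && sd(per_session$p_cs1[ok]) > 0 &&
      sd(per_session$p_cs2[ok]) > 0) {
    ct <- cor.test(per_session$p_cs1[ok], per_session$p_cs2[ok])
    r <- unname(ct$estimate); r_p <- ct$p.value
  }
  structure(list(per_session = per_session,
                 mean_p_cs1 = mean(per_session$p_cs1, na.rm = TRUE),
                 mean_p_cs2 = mean(per_session$p_cs2, na.rm = TRUE),
                 mean_p_cs2_nofirst = mean(per_session$p_cs2_nofirst,
                                           na.rm = TRUE),
                 r = r, r_p = r_p),
            class = "cs2_transfer")
}
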