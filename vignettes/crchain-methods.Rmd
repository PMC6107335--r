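---
title: "Detecting and analyzing chained conditioned eyelid responses"
author: "crchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analyzing chained conditioned eyelid responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crchain)
```

## The experimental model

In eyeblink conditioning a conditioned stimulus (CS; here a 500 ms cue) is
paired with a reinforcing unconditioned stimulus (US) at a 500 ms
inter-stimulus interval, and the animal learns a predictive eyelid closure
— the conditioned response (CR). Sequence training closes the loop around
the CR itself: on every paired trial the eyelid position at the scheduled
US time is compared against a target amplitude of 3 mm (half of the 6 mm
full closure). Below target, US₁ is delivered at CS offset to maintain the
first CR; at or above target, US₁ is omitted and US₂ is delivered a *gap
interval* after CS offset (600 ms ipsilaterally; 300–500 ms for the
contralateral variant, where US_R goes to the other eye). The animal then
learns a second CR timed to US₂ — and, because that second CR itself
generates the same kind of feedback, a third CR appears on CS-alone trials
without ever being reinforced.

The analyses in this package quantify that chain: whether a second CR
requires a first, how its probability depends on first-CR amplitude, how
tightly the two responses' timings co-vary, and whether Purkinje-cell (PC)
simple-spike rates show a decrease that precedes and scales with each CR in
the sequence.

## Conventions

Time is in milliseconds with t = 0 at CS onset; behavioral traces are
sampled at 1 kHz over 2500 ms (200 ms pre-CS, 2300 ms post-CS); positions
are in millimetres, with full closure calibrated to 6.0 mm at the start of
each session; all windows are half-open `[a, b)`; peak/crossing ties take
the earliest sample. Spike-trial records carry 1500 ms of pre-CS spikes;
the behavioral and spike clocks share t = 0.

## Trace processing

`calibrate()` scales raw detector units so the test-US closure reads
6.0 mm and removes the pre-CS baseline mean. `smooth_trace()` is a
Savitzky–Golay filter; the window/order are nowhere dictated by the
physiology, so the defaults (21 ms window, order 3) were chosen to preserve
CR rise times of 50–100 ms while suppressing sensor noise, and both are
arguments. `eyelid_velocity()` uses second-order central differences with
one-sided second-order stencils at the ends, then the same smoothing.

`screen_trial()` discards trials whole (no interpolation): upward movement
exceeding the 0.3 mm criterion in the 200 ms pre-CS window or the first
100 ms after CS onset, or negative deviation below −0.5 mm (relative to the
pre-CS baseline mean) before the US on paired trials, or from trial start
to 500 ms after CS offset on CS-alone trials. "Exceeding" is read as a
strict inequality, the early-CS window as `[0, 100)`. On contralateral
trials both eyes are screened and either can trigger exclusion.

## CR detection and decomposition

A response is a CR when it reaches the 0.3 mm criterion (5 % of full
closure); latency to criterion is the first sample at or above it. Onset
uses a two-step estimator: step 1 scans backward from the criterion
crossing for the last sample that has stayed within the noise band
(baseline + 2 pre-CS SDs, configurable) for at least 5 ms; step 2 fits a
least-squares line to the rising stretch between leaving the noise band and
twice the criterion level and back-projects it to the baseline. The fit
stops at 2× criterion because the early rise is still near-linear there,
and the longer lever arm suppresses the noise correlation the smoothing
introduces; the back-projected crossing may legitimately precede the
departure sample. On an ideal ramp the estimator is exact; with 0.05 mm
noise its mean absolute error is below 2 ms.

Multi-CR trials are decomposed by topographic peak prominence: local maxima
with prominence ≥ 0.5 mm (in trace units, matching the mm convention of the
criterion) estimate the CR count on CS-alone trials. A *squint gate* — the
maximum of position in 400–1100 ms minus the minimum in 800–1100 ms must
reach 1 mm — excludes trials where a sustained squint after the first CR
makes the presence of a following CR undecidable. The gate is applied only
to trials *with* a first CR: a flat no-CR trace has nothing to mask, and
no-first-CR trials must stay analyzable for the necessity analysis. When
the first CR starts at or after CS offset, a windowed-maximum rule applies
instead (first-CR amplitude = max in `[0, 700)`, second = max in
`[700, 1300)`), which also covers CS-alone trials with a single prominent
peak. On paired trials the analysis is truncated at the delivered US and
the second-CR peak is constrained to within 100 ms of US₂. The onset of CR
k ≥ 2 is the position minimum between consecutive peaks; because that
valley is an asymmetric V whose smoothed argmin is biased toward the
shallow flank, the minimum is refined by intersecting lines fitted to the
two flanks. A "second CR" under the windowed rule must both reach criterion
and rise by at least the criterion above the inter-CR trough, so the
decaying tail of a large first CR is not miscounted.

For contralateral sessions the right-eye CR amplitude subtracts the
right-eye maximum during the CS (sympathetic co-movement with the left-eye
CR) from its overall maximum, so co-movement alone yields zero amplitude.

## Sequence statistics

`session_summary()` defines first-CR probability over analyzable trials and
second-CR probability over trials with a first CR on which a second
response was observable (gate passed, not truncated at US₁).
`extinction_curve()` splits a session into eight contiguous near-equal
portions (remainder to the earliest portions). `conditional_probability()`
bins trials by first-CR amplitude — default edges `{<0.3 (non-CR), 0.3–1,
1–2, 2–3, 3–4, 4–5, ≥5}` mm, i.e. seven bins — and reports per-bin
second-CR probability with percentile bootstrap CIs (2000 repetitions,
trials resampled within bin; the simplest interval consistent with plain
bootstrap resampling) and a chi-square test on the present/absent table,
with empty bins dropped and the degrees of freedom reduced.

`timing_covariation()` collects pairs of timing measures from trials where
both CR amplitudes exceed 2 mm (for third-and-later CRs, CS-alone trials
only), discards outliers beyond 3 SDs in either coordinate, and reports
Pearson r with the standard t-approximation p-value. The amplitude
threshold is 2 mm by default with 3 mm available via the argument; the
profile-wide co-variation analysis (`fraction_times()`, 0.005 fraction
increments with linear interpolation) conventionally uses the 3 mm gate.

`shuffle_null()` tests whether inter-CR intervals are tighter than expected
under independent timing: the first-CR timings are permuted across trials
(sampling without replacement, 2000 permutations by default), intervals are
recomputed and pooled, and the true intervals are compared to the pool with
a two-sample Kolmogorov–Smirnov statistic. Because the pooled distribution
is built from the same data, the asymptotic KS p-value is not guaranteed
calibrated; the object's primary `p` is therefore permutation-calibrated
(the observed KS statistic ranked among each permutation's own statistic
against the pool), with the classical value kept as `ks_p`. The calibration
suite measures a type-I error of ~0.05 under the independent generator and
essentially complete power against chained timing with 20 ms interval
jitter at 100 pairs.

`cs2_transfer()` implements the transfer analysis: in sessions mixing CS1
trials (60 %), CS2-paired trials (25 %) and CS2-alone probes (15 %; 108
trials), it compares second-CR probability on CS1 trials with a supra-3 mm
first CR, on CS2-alone trials with a supra-3 mm first CR, and on CS2-alone
trials without a first CR. A feedback-driven chain predicts the first two
to be equal and the third near zero; a CS-bound chain predicts the CS2
group to collapse.

## Spike analysis

`instantaneous_rate()` estimates the simple-spike rate as the inverse
inter-spike interval — a piecewise-constant 1000/ISI Hz between consecutive
spikes — smoothed by a two-sided Gaussian kernel with 20 ms SD. Numerical
choices: the piecewise rate is discretized by *exact integration* over each
1 ms bin (the cumulative integral is piecewise-linear, so interpolating it
is exact; pointwise sampling would alias sub-millisecond ISIs), the window
edges are extended with the median ISI rate (a single edge ISI is
heavy-tailed through 1/ISI), and the kernel is renormalized to unit mass
inside the window at the edges to avoid artificial dips. Trials with fewer
than two spikes are flagged and zeroed. `normalize_rate()` divides by the
mean rate over 1500 ms of pre-CS baseline. Calibration: time-averaged
estimates recover homogeneous Poisson rates of 20/50/100 Hz to well within
2 % (averaged over ten 100 s realizations), and 50-trial averaged
normalized baselines sit within 1.00 ± 0.03.

`verify_eyelid_pc()` classifies units: a PC requires complex spikes plus a
post-complex-spike pause in the complex-spike-triggered simple-spike
average (rate below 50 % of the pre-event rate for ≥ 8 consecutive ms
within 20 ms; thresholds configurable, since only the existence of a pause
is physiologically dictated), and an eyelid PC additionally requires a
complex spike within 10 ms of at least half of US deliveries.

`group_trials()` forms a non-CR group plus three near-equal CR subgroups
ordered by onset or amplitude (remainder to the earliest groups); for
second-CR keys only trials with a first CR above 3 mm are eligible. The
text of the source analyses is ambiguous between "three groups including
non-CRs" and "three CR subgroups plus non-CRs"; the package uses the
latter and compares the extreme subgroups. `average_with_ci()` uses
pointwise mean ± 1.96 SEM; CI non-overlap is the separation criterion.
Under two null groups of 20 trials this criterion is conservative
(spurious separation at a fixed time point well below 5 %).

`align_to_cr_onset()` maps each CR trial's onset to aligned time 0 and
assigns each non-CR trial a pseudo-onset drawn (seeded) from the empirical
CR-onset distribution. The pre-onset decrease metric is the mean normalized
rate of CR trials at the aligned-onset sample (a 10 ms window average gives
indistinguishable values). `separation_lead()` reports where the CI
separation run that persists through onset begins; isolated spurious
crossings elsewhere in the window are ignored.

## The synthetic session generator

`generate_session()` emulates the training protocols so that every analysis
stage can be validated against ground truth. Design of the generator:

* **Waveform.** Each CR is a quarter-sine rise to its amplitude over
  `rise_time` (default 180 ms) followed by exponential relaxation
  (`decay_time`, default 150 ms; eyelid CRs relax within ~100–300 ms).
  The quarter-sine was chosen over a sigmoid deliberately: real CRs show an
  abrupt velocity rise at onset, and a zero-slope (sigmoid) onset would
  make the planted onset unidentifiable to within 10 ms under realistic
  noise — onset-recovery validation would then measure the waveform's
  pathology rather than the detector. Waveforms are additive across
  overlapping CRs; planted truth records the local maxima of the noiseless
  composite, which is what any detector can recover.
* **First CR.** Present with probability `p_first_cr` (default 0.9, a
  well-trained animal); onset ~ N(300, 40) ms truncated to the CS window;
  amplitude ~ N(4, 1.2) mm truncated to [0, 6]. These are placeholders in
  the realistic range for trained rabbits — the source experiments report
  no numeric onset/amplitude distributions to copy.
* **Contingency.** The US schedule is computed by `simulate_contingency()`
  from the noiseless first-CR value at the scheduled US₁ time; amplitude at
  or above target goes to the US₂ branch. A delivered US appends a fast
  unconditioned closure to full closure in the trace (the analyses truncate
  at the US, but the UR keeps traces realistic for screening tests).
* **Chain.** In `chained` mode the next onset is the previous onset plus a
  spacing chosen so the chained CR peaks at the scheduled US₂ time (the
  timing the contingency reinforces) plus N(0, 30 ms) jitter; amplitudes
  decay by 0.75 with 0.3 mm noise. A supra-target CR chains with
  probability 0.7; sub-target CRs chain with probability scaled by
  `(amp/3)²`, giving the smooth decline of second-CR probability with
  first-CR amplitude that the conditional analysis expects. The chain never
  starts without a first CR, stops at any delivered US (so third CRs occur
  on CS-alone trials only, and never in the contralateral protocol), and
  stops below 0.8 mm — a closure too small to count as a response would be
  undetectable by the 0.5 mm prominence rule by construction, which would
  make planted-recovery validation vacuous rather than informative. In
  `independent` mode later onsets are drawn with the same marginal
  distribution but without reference to the first CR — the null for
  calibrating the shuffle test.
* **CS2 sessions** mix CS1-paired/CS2-paired/CS2-alone trials 60/25/15 in a
  108-trial session. `transfer_mode = "feedback"` chains off any first CR;
  `"cs_bound"` chains only on CS1 trials — the alternative generative model
  the transfer analysis must reject.
* **Spikes.** Simple spikes are an inhomogeneous Poisson process (thinning,
  then 1 ms rounding) with rate `baseline · (1 − dip_depth · profile(t +
  dip_lead))`, clipped at zero: the rate decrease *leads* the eyelid by
  `dip_lead` (default 50 ms), with `dip_depth` 0.12 per mm and an 80 Hz
  baseline. Each delivered US evokes one complex spike after 3 ms (with
  probability 0.9) plus spontaneous complex spikes at 1 Hz; every complex
  spike silences simple spikes for 15 ms.
* **Reproducibility.** All randomness flows from one seed per session;
  seeded package functions restore the caller's RNG state on exit.

What the generator does *not* emulate: learning dynamics across sessions
(acquisition/extinction enter only through per-trial parameter schedules,
e.g. a vector-valued `p_second_given_gate`), biomechanics (no oscillations,
drift, or blink artifacts beyond white noise), sub-criterion partial
responses, and PC diversity (one modeled unit per session; population
effects are emulated by pooling seeded sessions). Passing tests therefore
demonstrate that the analysis chain is correct and calibrated under the
stated statistical structure — not that real data meet that structure.

## Validation problem sizes

The test-suite and the acceptance script work at these sizes, chosen to
make the Monte-Carlo error small relative to each criterion while keeping a
full run in minutes on one CPU: planted-event recovery on 500 CS-alone
trials (noise-free and 0.05 mm noise); shuffle-null type-I error over 200
independent-mode replicates of 100 pairs (400 permutations each — the
permutation p needs only 0.0025 resolution here) and power over 30 chained
replicates; bootstrap coverage over 500 replicates at 50 trials per bin
with 2000 bootstrap repetitions, assessed in the bins where the binomial is
non-degenerate at n = 50 (percentile intervals are known to undercover
when n·p < 5 — a property of the method, not of the implementation); rate
calibration over ten 100 s realizations per rate; and a pooled PC study of
16 simulated units, matching a realistic eyelid-PC sample.

## Known limitations

* The two-step onset estimator assumes a monotone early rise; heavily
  oscillating traces will back-project poorly (the fallback is the latency
  to criterion, flagged).
* The windowed-maximum rule reports absolute amplitudes, so on paired
  trials a second CR riding on a first CR's plateau is attributed the
  plateau height; the rise-above-trough requirement guards presence, not
  amplitude.
* The chi-square on the conditional-probability table uses the asymptotic
  distribution; with very sparse bins it becomes conservative. The suite
  checks its type-I error only with adequately filled bins.
* `read_session()`/`write_session()` round-trip through delimited text at
  ~15 significant digits — lossless for analysis purposes, not bit-exact.
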