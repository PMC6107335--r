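# Shared fixture builders; everything is generated in code.

# small ipsilateral session with defaults
small_ipsi <- function(seed = 42, n_blocks = 4, ...) {
  generate_session(protocol_config("ipsilateral", n_blocks = n_blocks),
                   gen_params(...), seed = seed)
}

# all-CS-alone session (n trials), handy for chain analyses
cs_alone_session <- function(n = 100, seed = 1, ...) {
  generate_session(protocol_config("ipsilateral", n_blocks = n,
                                   trials_per_block = 1),
                   gen_params(...), seed = seed)
}

# (t_first, t_second) onset pairs straight from the generator log
truth_pairs <- function(session, max_pairs = Inf) {
  tru <- session$truth
  t1 <- tru[tru$cr_index == 1, ]
  t2 <- tru[tru$cr_index == 2, ]
  ids <- intersect(t1$trial_id, t2$trial_id)
  ids <- ids[seq_len(min(max_pairs, length(ids)))]
  list(t1 = t1$onset[match(ids, t1$trial_id)],
       t2 = t2$onset[match(ids, t2$trial_id)])
}

# noiseless trace from explicit CR parameters
planted_trace <- function(events, t = trial_time_grid(), rise = 180,
                          decay = 150) {
  x <- numeric(length(t))
  for (ev in events)
    x <- x + cr_waveform(ev$onset, ev$amp, rise, decay, t)
  x
}
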