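CR_FORMAT_VERSION <- 1L

# deterministic polynomial hash of an R object (config fingerprinting);
# arithmetic kept below 2^53 so the result is exact in doubles
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              dec = ".")
}

#' Write a session to disk
#'
#' Serializes a `cr_session` to a directory of tab-separated text files plus
#' a YAML metadata sidecar: `session.yaml` (format version, protocol and
#' generator parameters, seed), `trials.tsv` (per-trial metadata),
#' `traces.tsv` (long format: trial, eye, time, position), `truth.tsv`
#' (planted CR events, generated sessions only) and `spikes.tsv` (spike
#' events, if present). Numeric columns carry explicit units in their names.
#' The round trip through [read_session()] is lossless.
#'
#' @param session A `cr_session`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format_version = CR_FORMAT_VERSION,
               seed = session$seed,
               t0_ms = session$t[1], n_samples = length(session$t),
               cfg = unclass(session$cfg),
               gen = unclass(session$gen),
               pc = if (is.null(session$pc)) NULL else unclass(session$pc))
  meta$cfg$cs2_mix <- as.list(meta$cfg$cs2_mix)
  yaml::write_yaml(meta, file.path(path, "session.yaml"))

  tr <- session$trials
  names(tr)[names(tr) == "us_time"] <- "us_time_ms"
  names(tr)[names(tr) == "amp_at_us1"] <- "amp_at_us1_mm"
  write_tsv(tr, file.path(path, "trials.tsv"))

  long <- do.call(rbind, lapply(names(session$traces), function(e) {
    m <- session$traces[[e]]
    cl <- session$clean[[e]]
    data.frame(trial_id = rep(session$trials$trial_id, each = ncol(m)),
               eye = e, t_ms = rep(session$t, nrow(m)),
               position_mm = as.vector(t(m)), clean_mm = as.vector(t(cl)))
  }))
  write_tsv(long, file.path(path, "traces.tsv"))

  tru <- session$truth
  names(tru) <- c("trial_id", "eye", "cr_index", "onset_ms",
                  "planted_amp_mm", "peak_time_ms", "peak_value_mm")
  write_tsv(tru, file.path(path, "truth.tsv"))

  if (!is.null(session$spikes))
    write_tsv(session$spikes, file.path(path, "spikes.tsv"))
  invisible(path)
}

load_error <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a session from disk
#'
#' Inverse of [write_session()], with validation: the format version must be
#' present and known, required columns present, and every trial's trace
#' uniformly sampled at 1 ms; violations produce a load error naming the
#' offending trial/field.
#'
#' @param path Session directory.
#' @return A `cr_session`.
#' @export
read_session <- function(path) {
  yml <- file.path(path, "session.yaml")
  if (!file.exists(yml)) load_error("missing session.yaml in %s", path)
  meta <- yaml::read_yaml(yml)
  if (is.null(meta$format_version))
    load_error("file %s has no format_version: not a session store", yml)
  if (meta$format_version != CR_FORMAT_VERSION)
    load_error("unsupported format_version %s (supported: %d)",
               meta$format_version, CR_FORMAT_VERSION)
  cfg <- meta$cfg
  cfg$cs2_mix <- unlist(cfg$cs2_mix)
  cfg <- do.call(protocol_config, cfg)
  gen <- do.call(gen_params, meta$gen)
  pc <- if (is.null(meta$pc)) NULL else do.call(pc_gen_params, meta$pc)

  tr <- read.delim(file.path(path, "trials.tsv"),
                   stringsAsFactors = FALSE)
  need <- c("trial_id", "type", "us", "us_time_ms", "amp_at_us1_mm")
  miss <- setdiff(need, names(tr))
  if (length(miss)) load_error("trials.tsv missing columns: %s",
                               paste(miss, collapse = ", "))
  names(tr)[names(tr) == "us_time_ms"] <- "us_time"
  names(tr)[names(tr) == "amp_at_us1_mm"] <- "amp_at_us1"
  if (anyDuplicated(tr$trial_id))
    load_error("duplicate trial ids in trials.tsv")

  t <- trial_time_grid(meta$t0_ms, meta$n_samples)
  long <- read.delim(file.path(path, "traces.tsv"),
                     stringsAsFactors = FALSE)
  need <- c("trial_id", "eye", "t_ms", "position_mm")
  miss <- setdiff(need, names(long))
  if (length(miss)) load_error("traces.tsv missing columns: %s",
                               paste(miss, collapse = ", "))
  eyes <- unique(long$eye)
  traces <- list(); clean <- list()
  for (e in eyes) {
    sub <- long[long$eye == e, ]
    m <- matrix(NA_real_, nrow(tr), length(t))
    cm <- matrix(NA_real_, nrow(tr), length(t))
    for (i in seq_len(nrow(tr))) {
      s <- sub[sub$trial_id == tr$trial_id[i], ]
      if (nrow(s) != length(t))
        load_error("trial %s eye %s: %d samples, expected %d",
                   tr$trial_id[i], e, nrow(s), length(t))
      if (any(diff(s$t_ms) != 1))
        load_error("trial %s eye %s: non-uniform sampling near t = %s ms",
                   tr$trial_id[i], e,
                   s$t_ms[which(diff(s$t_ms) != 1)[1]])
      m[i, ] <- s$position_mm
      if ("clean_mm" %in% names(s)) cm[i, ] <- s$clean_mm
    }
    traces[[e]] <- m
    clean[[e]] <- cm
  }

  tru_path <- file.path(path, "truth.tsv")
  truth <- if (file.exists(tru_path)) {
    tb <- read.delim(tru_path, stringsAsFactors = FALSE)
    names(tb) <- c("trial_id", "eye", "cr_index", "onset", "planted_amp",
                   "peak_time", "peak_value")
    tb
  } else NULL

  sp_path <- file.path(path, "spikes.tsv")
  spikes <- if (file.exists(sp_path))
    read.delim(sp_path, stringsAsFactors = FALSE) else NULL

  structure(list(format_version = CR_FORMAT_VERSION, cfg = cfg, gen = gen,
                 pc = pc, seed = meta$seed, t = t, trials = tr,
                 traces = traces, clean = clean, truth = truth,
                 spikes = spikes),
            class = "cr_session")
}

pipeline_defaults <- function() {
  list(simulate = TRUE, input = NULL, protocol = "ipsilateral",
       seed = 1, n_blocks = 12, gap_interval = NULL,
       gen = list(), pc = NULL,
       analyses = c("summary", "condprob", "curves"),
       n_boot = 2000, n_perm = 2000, out_dir = "crchain_out")
}

#' Run the analysis pipeline
#'
#' Executes simulate (optional) -> screen -> detect -> selected analyses and
#' writes all tables (tab-separated, unit-suffixed columns), a
#' machine-readable `summary.json` (carrying the materialized configuration,
#' its hash and the seed) and the per-stage outputs. Identical configuration
#' and seed produce identical outputs. Unknown configuration keys are
#' rejected before any computation.
#'
#' @param config Named list (or path to a YAML file) overriding the
#'   defaults: `simulate`, `input` (session directory when not simulating),
#'   `protocol`, `seed`, `n_blocks`, `gap_interval`, `gen` (generator
#'   overrides), `analyses` (subset of `"summary"`, `"condprob"`, `"curves"`,
#'   `"timing"`, `"shuffle"`), `n_boot`, `n_perm`, `out_dir`.
#' @return Invisibly, a list with the computed objects.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  bad <- setdiff(cfg$analyses, c("summary", "condprob", "curves", "timing",
                                 "shuffle"))
  if (length(bad)) stop("unknown analysis: ", paste(bad, collapse = ", "))

  if (cfg$simulate) {
    pc_args <- protocol_config(cfg$protocol, n_blocks = cfg$n_blocks,
                               gap_interval = cfg$gap_interval)
    gen <- do.call(gen_params, cfg$gen)
    session <- generate_session(pc_args, gen, seed = cfg$seed)
  } else {
    if (is.null(cfg$input)) stop("input session path required when simulate = FALSE")
    session <- read_session(cfg$input)
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  screen <- screen_session(session)
  write_tsv(screen, file.path(cfg$out_dir, "screening.tsv"))
  dec <- decompose_session(session, screen)
  write_tsv(dec$events, file.path(cfg$out_dir, "events.tsv"))
  write_tsv(dec$outcomes, file.path(cfg$out_dir, "outcomes.tsv"))

  results <- list(session = session, screen = screen, decomposition = dec)
  summary_out <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                      config_hash = config_hash(cfg[setdiff(names(cfg),
                                                            "out_dir")]),
                      seed = cfg$seed,
                      n_trials = nrow(session$trials),
                      n_kept = sum(screen$kept))
  if ("summary" %in% cfg$analyses)
    summary_out$session_summary <- as.list(session_summary(dec$outcomes))
  if ("condprob" %in% cfg$analyses) {
    cp <- conditional_probability(dec$outcomes, n_boot = cfg$n_boot,
                                  seed = cfg$seed)
    write_tsv(cp$table, file.path(cfg$out_dir, "condprob.tsv"))
    summary_out$condprob <- list(chi2 = cp$chi2, df = cp$df,
                                 p_value = cp$p_value, n = cp$n_total)
    results$condprob <- cp
  }
  if ("curves" %in% cfg$analyses) {
    cv <- extinction_curve(dec$outcomes)
    write_tsv(cv, file.path(cfg$out_dir, "curve.tsv"))
    results$curve <- cv
  }
  if ("timing" %in% cfg$analyses || "shuffle" %in% cfg$analyses) {
    tp <- timing_covariation(dec$events, dec$outcomes)
    results$timing <- tp
    summary_out$timing <- list(r = tp$r, p_value = tp$p_value, n = tp$n)
    if ("shuffle" %in% cfg$analyses && tp$n >= 2) {
      sh <- shuffle_null(tp$pairs$t_first, tp$pairs$t_second,
                         n_perm = cfg$n_perm, seed = cfg$seed)
      results$shuffle <- sh
      summary_out$shuffle <- list(ks_stat = sh$ks_stat, p = sh$p,
                                  ks_p = sh$ks_p)
    }
  }
  jsonlite::write_json(summary_out, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(results)
}
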