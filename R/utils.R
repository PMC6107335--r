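# Capture the caller's RNG state and return a restorer, so that seeded
# package functions do not perturb the global random stream:
#   on.exit(preserve_rng()())  is wrong -- call as:
#   restore <- preserve_rng(); on.exit(restore())
preserve_rng <- function() {
  ge <- globalenv()
  if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
    old <- get(".Random.seed", envir = ge)
    function() assign(".Random.seed", old, envir = ge)
  } else {
    function() if (exists(".Random.seed", envir = ge, inherits = FALSE))
      rm(".Random.seed", envir = ge)
  }
}
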