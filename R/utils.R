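# Evaluate code under a fixed RNG seed, then restore the caller's RNG
# state, so seeded package functions never perturb the user's stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", .GlobalEnv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  code
}
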