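# Shared internal helpers.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so generators behave as pure functions of
# (parameters, seed).
.with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("a finite integer seed is required")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Bohr radius in Angstrom.
.BOHR_A <- 0.529177210903

# hartree in cm^-1 (energy-wavenumber conversion).
.HARTREE_CM1 <- 219474.6313632

# eV-nm product for photon energy conversion.
.EV_NM <- 1239.842
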