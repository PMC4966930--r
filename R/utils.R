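# Internal helpers: scoped seeding and seed-stream derivation.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. A NULL seed uses (and advances)
# the current RNG state.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed and a stream index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483629 + 104729 * as.numeric(index)) %%
               2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
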