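# Run code under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Counter-based fan-out of a master seed into per-stage / per-repeat seeds.
# Kept below 2^31 so the result is always a valid integer seed.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + 7919 * as.numeric(index)) %%
               2147483587)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}
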