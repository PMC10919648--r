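# Splittable deterministic random streams.
#
# All randomness in the package flows from one integer seed through keyed
# splitmix64 streams (C++ side); R's global RNG is never consulted or
# advanced. Stream keys are small integers namespacing the purpose of the
# draw (run, channel, voxel block, ...), so adding a consumer never perturbs
# the draws of existing ones.

# purpose keys (key1); key2 is free per purpose
.RNG_KEY <- c(timeline = 1L, latent = 2L, eeg = 3L, bold = 4L,
              voi = 5L, masks = 6L, delay = 7L, misc = 8L)

rng_normal <- function(n, seed, purpose, sub = 0L) {
  .rng_normal_cpp(as.integer(n), as.double(seed),
                  as.double(.RNG_KEY[[purpose]]), as.double(sub))
}

rng_unif <- function(n, seed, purpose, sub = 0L) {
  .rng_unif_cpp(as.integer(n), as.double(seed),
                as.double(.RNG_KEY[[purpose]]), as.double(sub))
}

# seeded permutation of seq_len(n) (rank of uniform draws)
rng_perm <- function(n, seed, purpose, sub = 0L) {
  order(rng_unif(n, seed, purpose, sub))
}

# derive a bounded child seed for nested generators (subjects in a cohort)
derive_seed <- function(seed, index) {
  u <- rng_unif(index, seed, "misc", 999L)[index]
  as.integer(floor(u * 2000000000))
}
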