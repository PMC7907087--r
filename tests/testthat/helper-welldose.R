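# Shared fixtures for the test suite: the generating truth used throughout
# the simulation-based tests, and a convenience simulator.

truth_params <- function() {
  cover_params(4, 1.29, 6.18, -1, cover = "adhesive_foil",
               provenance = "synthetic truth")
}

# chemicals + simulated ratios in one call; seeds derived from one base so
# chemicals and noise never reuse a stream
sim_dataset <- function(n, noise_sd, seed, params = truth_params(), ...) {
  chems <- generate_chemicals(n, seed = seed, ...)
  ratios <- simulate_ratios(chems, params, noise_sd = noise_sd,
                            seed = seed + 13579L)
  list(chems = chems, ratios = ratios)
}
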