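# shared fixtures built in code

# three-state chain used throughout: moderately metastable, irreducible
fixture_T3 <- function() {
  matrix(c(0.90, 0.08, 0.02,
           0.15, 0.70, 0.15,
           0.05, 0.15, 0.80), nrow = 3, byrow = TRUE)
}

# uniform ensemble of n walkers at a common coordinate
uniform_ensemble <- function(n, coords = 0, tau = 1) {
  we_ensemble(lapply(seq_len(n), function(j)
    we_walker(j, 0L, 1 / n, coords, payload = coords)), tau = tau)
}

# ensemble with given weights (must sum to ~1) and 1-D coords
weighted_ensemble <- function(weights, coords = seq_along(weights)) {
  we_ensemble(lapply(seq_along(weights), function(j)
    we_walker(j, 0L, weights[j], coords[j], payload = coords[j])))
}

# the three-coordinate unbinding-style score spec with the 0.8 window
fixture_unbind_spec <- function(regions = list(c(10, 13, 0.8))) {
  score_spec(list(
    coordinate_spec("rmsd", 0, 25, regions = regions),
    coordinate_spec("eint", 350, -200),
    coordinate_spec("dist", 0, 10)))
}

# minimal markov-chain run config
markov3_cfg <- function(resampler = list(type = "mabl", n_split_merge = 2L),
                        walkers = 10L, iterations = 10L, seed = 1L,
                        recycling = FALSE, ...) {
  c(list(system = list(kind = "markov_chain",
                       parameters = list(transition = fixture_T3())),
         resampler = resampler, walker_count = walkers, tau = 1,
         iterations = iterations, seed = seed, recycling = recycling),
    list(...))
}
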