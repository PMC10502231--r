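# Shared fixtures: everything is generated in code at test time.

noisefree_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, noise_cv = 0, ...)
}

# tiny complete proteome with a known planted structure, for fast tests
tiny_proteome <- function(seed = 1L, n_proteins = 30L, n_planted = 4L,
                          effect_size = 1.5, missing_rate = 0) {
  simulate_proteome(sim_config(
    seed = seed, n_proteins = n_proteins, n_planted = n_planted,
    effect_size = effect_size, missing_rate = missing_rate))
}

# hand-built proteome matrix from explicit intensities (log2 scale)
manual_proteome <- function(x, response) {
  proteome_matrix(x, response, log2 = TRUE)
}
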