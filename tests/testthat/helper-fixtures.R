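# Shared fixtures: small designs and strongly structured pattern sets used
# across test files. Everything is generated in code at test time.

default_design <- function(seed = 1) generate_design(design_params(seed = seed))

# A compact design: 4 blocks x 8 trials, still satisfying all divisibility
# constraints (2 per stimulus per half), for fast structural tests.
tiny_design <- function(seed = 1)
  generate_design(design_params(n_blocks = 4L, trials_per_block = 8L, seed = seed))

# Betas with a strong, easily decodable stimulus signal.
separable_betas <- function(design = default_design(), n_voxels = 30,
                            stimulus_amp = 4, threat_amp = 4, noise_sd = 0.5,
                            seed = 11, ...) {
  sp <- synth_params(n_voxels = n_voxels, stimulus_amp = stimulus_amp,
                     threat_amp = threat_amp, noise_sd = noise_sd,
                     seed = seed, ...)
  simulate_betas(design, make_pattern_basis(sp), sp)
}

# Strip metadata attributes for plain-matrix comparisons.
bare <- function(m) {
  a <- as.matrix(m)
  attributes(a) <- list(dim = dim(a))
  a
}

# Pure-noise betas: no stimulus information at all.
noise_betas <- function(design = default_design(), n_voxels = 30, seed = 12) {
  sp <- synth_params(n_voxels = n_voxels, stimulus_amp = 0, threat_amp = 0,
                     noise_sd = 1, seed = seed)
  simulate_betas(design, make_pattern_basis(sp), sp)
}
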