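# Small, fast scene factories shared across test files.

tiny_scene <- function(seed = 5, noise_sigma = 0, n_live = 3, n_dead = 3,
                       shape = c(128, 128), cluster_fraction = 0) {
  render_scene(
    lattice = fiber_lattice_spec(),
    illumination = illumination_spec(),
    cells = cell_population_spec(n_live = n_live, n_dead = n_dead,
                                 cluster_fraction = cluster_fraction),
    shape = shape, noise_sigma = noise_sigma, seed = seed
  )
}

# A deterministic ramp image with well-spread values.
ramp_image <- function(rows = 32, cols = 32) {
  matrix(seq(0, 1, length.out = rows * cols), rows, cols)
}
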