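# Simulated factorial surfaces with known generative structure, and the
# fixed synthetic-slab study conditions shared by the trend tests.

# Additive factorial response over the (roi, offset, quantization) grid
# with the invalid offset >= roi cells removed.
sim_surface <- function(seed, q_effect = c(0, 1, 2, 4), roi_effect = 0.2,
                        d_effect = 0.1, interaction = 0, sigma = 0.1,
                        reps = 2L) {
  set.seed(seed)
  grid <- expand.grid(roi_size = c(10, 25, 50, 100),
                      offset = c(1, 5, 7, 10, 15, 20),
                      quantization = c(8, 32, 64, 128),
                      rep = seq_len(reps))
  grid <- grid[grid$offset < grid$roi_size, ]
  qi <- match(grid$quantization, c(8, 32, 64, 128))
  ri <- match(grid$roi_size, c(10, 25, 50, 100))
  di <- match(grid$offset, c(1, 5, 7, 10, 15, 20))
  grid$value <- q_effect[qi] + roi_effect * ri + d_effect * di +
    interaction * (ri == 2) * (qi >= 3) +
    rnorm(nrow(grid), 0, sigma)
  grid
}

# Texture surfaces over the fixed synthetic study conditions (two
# densities, both filter arms, all four quantizations), computed once per
# test run and cached.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_surfaces <- function() {
  if (!is.null(.acceptance_cache$surfaces)) return(.acceptance_cache$surfaces)
  arms <- list()
  for (dens in c(0.25, 0.5)) {
    spec <- phantom_spec(height = 160L, width = 160L,
                         density_fraction = dens,
                         seed = if (dens == 0.25) 101L else 102L)
    noisy <- add_acquisition_noise(generate_tissue_field(spec), spec)
    for (slab in list(noisy, wiener_filter(noisy))) {
      arms[[length(arms) + 1L]] <- slab_texture_surface(
        slab,
        quantizations = c(8L, 32L, 64L, 128L),
        roi_sizes = c(25L, 50L),
        offsets = c(1L, 5L, 7L, 10L, 15L, 20L)
      )
    }
  }
  .acceptance_cache$surfaces <- dplyr::bind_rows(arms)
  .acceptance_cache$surfaces
}
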