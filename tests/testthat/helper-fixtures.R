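# shared fixtures: small grids keep every test inside a few seconds

small_grid <- function(voxel = 4) voxel_grid(c(32L, 32L, 24L), voxel)

tiny_grid <- function(voxel = 8) voxel_grid(c(16L, 16L, 12L), voxel)

small_phantom <- function(grid = small_grid(), ...) {
  build_phantom(grid, seed = 1, ...)
}

# a lesion comfortably inside the brain of small_grid() (mm coordinates;
# grid extent is 128 x 128 x 96 mm, centre at (64, 64, 48))
centre_lesion <- function(radius = 14, reduction = 0.6) {
  list(center = c(64, 96, 48), radius = radius, cbf_reduction = reduction)
}

fine_aif <- function() gamma_variate_aif(peak_time = 30, peak_value = 30,
                                         shape = 3,
                                         times = seq(0, 300, by = 0.25))

# deterministic constant-CBF phantom (uniform perfusion inside the brain)
uniform_phantom <- function(grid = small_grid(), f = 50) {
  ph <- build_phantom(grid, seed = 1)
  ph$true_cbf[ph$brain_mask] <- f
  ph
}
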