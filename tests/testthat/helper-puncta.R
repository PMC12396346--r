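# shared small rendering config: 12 x 12 x 3 um field, confocal-like voxels
small_cfg <- function(seed = 1, ...) {
  puncta_sim_config(volume = c(12, 12, 3), voxel_size = c(0.15, 0.1, 0.1),
                    blob_sigma = 0.3, peak_snr = 10, seed = seed, ...)
}

# jittered-grid blob coordinates with >= 4 sigma separation, away from edges
grid_coords <- function(n, extent = 12, spacing = 1.6, margin = 1.2,
                        z_range = c(1, 2), seed = 5) {
  withr::with_seed(seed, {
    g <- seq(margin, extent - margin, by = spacing)
    pts <- as.matrix(expand.grid(x = g, y = g))
    pts <- pts[sample(nrow(pts), n), ]
    cbind(x_um = pts[, 1] + runif(n, -0.15, 0.15),
          y_um = pts[, 2] + runif(n, -0.15, 0.15),
          z_um = runif(n, z_range[1], z_range[2]))
  })
}
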