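# Shared fixtures: a reduced probe for cheap forward-model tests, and a
# voxelized sphere helper.

`%inrange%` <- function(x, r) x >= r[1] & x <= r[2]

tiny_geometry <- function() {
  probe_geometry(
    source_positions = cbind(c(-2, 0, 2), c(-1.5, 2.5, -1.5), 0),
    detector_positions = cbind(c(-1, 1, 0, 2.5), c(0, 0, -2.2, 1), 0))
}

sphere_inclusion <- function(center, radius, delta_mua, h = 0.25) {
  s <- seq(-radius + h / 2, radius - h / 2, by = h)
  gr <- as.matrix(expand.grid(x = s, y = s, z = s))
  gr <- gr[rowSums(gr^2) <= radius^2, , drop = FALSE]
  gr <- sweep(gr, 2, center, "+")
  list(centers = gr, volumes = h^3, delta_mua = delta_mua)
}

# deterministic spherical test scene without heterogeneity
plain_sphere_scene <- function(center = c(0, 0, 1.5), radius = 1,
                               target_mua = 0.15, bg_mua = 0.02,
                               bg_musp = 7) {
  sc <- sample_scene(1, chest_wall_prob = 0)
  sc$target$shape <- "sphere"
  sc$target$harmonics <- numeric(5)
  sc$target$center <- center
  sc$target$radius <- radius
  sc$target$mua <- target_mua
  sc$background <- optical_properties(bg_mua, bg_musp)
  sc$heterogeneity$amplitude_frac <- 0
  sc
}
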