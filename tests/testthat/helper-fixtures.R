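# Small geometries and phantoms shared across tests. Everything is built in
# code; nothing is read from disk.

tiny_grid <- function(n = 8, nz = 1, vs = 1) volume_grid(n, n, nz, vs)

tiny_geom <- function(n = 8, num_proj = 6, span = 360, dim_proj = 2 * n,
                      mode = "fanbeam2d") {
  default_geometry(tiny_grid(n), num_proj, span, dim_proj, mode = mode)
}

random_volume <- function(grid, seed = 1) {
  set.seed(seed)
  ct_volume(grid, array(runif(grid$nx * grid$ny * grid$nz),
                        c(grid$nx, grid$ny, grid$nz)))
}

random_stack <- function(geom, seed = 1) {
  set.seed(seed)
  dims <- c(geom$det_pixels_u, geom$det_pixels_v, length(geom$angles))
  projection_stack(geom, array(runif(prod(dims)), dims))
}

# dense backprojection matrix built independently of dense_system_matrix,
# by probing the backprojector with detector impulses
dense_backprojection_matrix <- function(geom, grid, mode = "voxel") {
  nray <- geom$det_pixels_u * geom$det_pixels_v * length(geom$angles)
  nvox <- grid$nx * grid$ny * grid$nz
  B <- matrix(0, nvox, nray)
  e <- array(0, c(geom$det_pixels_u, geom$det_pixels_v, length(geom$angles)))
  for (j in seq_len(nray)) {
    e[j] <- 1
    B[, j] <- as.vector(back_project(projection_stack(geom, e), grid,
                                     mode = mode)$values)
    e[j] <- 0
  }
  B
}
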