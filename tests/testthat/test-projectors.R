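test_that("forward projection is linear and zero on the zero volume", {
  grid <- tiny_grid(8)
  geom <- tiny_geom(8)
  z <- forward_project(ct_volume(grid, 0), geom)
  expect_true(all(z$values == 0))
  x <- random_volume(grid, 1)
  y <- random_volume(grid, 2)
  lhs <- forward_project(ct_volume(grid, 2 * x$values + 3 * y$values), geom)$values
  rhs <- 2 * forward_project(x, geom)$values + 3 * forward_project(y, geom)$values
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("axis-aligned rays integrate the exact slab thickness", {
  # uniform unit slab; at angle 0 rays near the detector center cross the
  # volume almost perpendicular to a face
  n <- 8
  grid <- tiny_grid(n)
  vol <- ct_volume(grid, 1)
  geom <- make_circular_geometry(1, 150, 2 * n, 0.1, 1e5, 2e5)  # near-parallel
  p <- forward_project(vol, geom)
  central <- p$values[n, 1, 1]
  expect_equal(central, n * grid$voxel_size, tolerance = 1e-6)
})

test_that("doubling voxel_size doubles axis-aligned path integrals", {
  n <- 8
  g1 <- volume_grid(n, n, 1, 1)
  g2 <- volume_grid(n, n, 1, 2)
  geom1 <- make_circular_geometry(1, 150, 2 * n, 0.1, 1e5, 2e5)
  geom2 <- make_circular_geometry(1, 150, 2 * n, 0.2, 1e5, 2e5)
  p1 <- forward_project(ct_volume(g1, 1), geom1)$values[n, 1, 1]
  p2 <- forward_project(ct_volume(g2, 1), geom2)$values[n, 1, 1]
  expect_equal(p2 / p1, 2, tolerance = 1e-6)
})

test_that("dense system matrix reproduces the operator and is non-negative", {
  grid <- tiny_grid(8)
  geom <- tiny_geom(8, num_proj = 5)
  A <- dense_system_matrix(geom, grid)
  expect_true(all(A >= 0))
  set.seed(3)
  for (i in 1:3) {
    x <- runif(grid$nx * grid$ny)
    px <- as.vector(forward_project(
      ct_volume(grid, array(x, c(8, 8, 1))), geom)$values)
    expect_lt(max(abs(A %*% x - px)) / max(abs(px)), 1e-10)
  }
  expect_error(dense_system_matrix(geom, volume_grid(64, 64, 64)), "cap")
})

test_that("impulse volume projects to the matching dense-matrix column", {
  grid <- tiny_grid(8)
  geom <- tiny_geom(8, num_proj = 4)
  A <- dense_system_matrix(geom, grid)
  e <- array(0, c(8, 8, 1)); e[3, 5, 1] <- 1
  col <- as.vector(forward_project(ct_volume(grid, e), geom)$values)
  j <- 3 + 8 * (5 - 1)
  expect_equal(col, A[, j])
})

test_that("backprojection modes are linear, zero on zero, and match impulse probing", {
  grid <- tiny_grid(8)
  geom <- tiny_geom(8, num_proj = 4)
  for (mode in c("voxel", "matched")) {
    z <- back_project(projection_stack(geom, 0), grid, mode = mode)
    expect_true(all(z$values == 0))
    B <- dense_backprojection_matrix(geom, grid, mode)
    set.seed(4)
    y <- runif(geom$det_pixels_u * length(geom$angles))
    dims <- c(geom$det_pixels_u, 1, length(geom$angles))
    by <- as.vector(back_project(projection_stack(geom, array(y, dims)),
                                 grid, mode = mode)$values)
    expect_lt(max(abs(B %*% y - by)) / max(abs(by)), 1e-10)
  }
})

test_that("matched backprojection is the exact transpose of the projector", {
  grid <- tiny_grid(8)
  geom <- tiny_geom(8, num_proj = 5)
  A <- dense_system_matrix(geom, grid)
  B <- dense_backprojection_matrix(geom, grid, "matched")
  expect_lt(max(abs(B - t(A))), 1e-12)
})

test_that("single detector impulse backprojects only onto its ray footprint", {
  grid <- tiny_grid(8)
  geom <- tiny_geom(8, num_proj = 3)
  e <- array(0, c(geom$det_pixels_u, 1, 3)); e[8, 1, 1] <- 1
  v <- back_project(projection_stack(geom, e), grid, mode = "matched")$values
  expect_gt(sum(v != 0), 0)
  A <- dense_system_matrix(geom, grid)
  footprint <- A[8, ] > 0     # row of the projector = ray footprint
  expect_true(all(v[!footprint] == 0))
})

test_that("adjoint identity holds in matched mode on random instances", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    grid <- volume_grid(n, n, 1, 1)
    geom <- default_geometry(grid, sample(3:8, 1), sample(c(360, 180, 120), 1),
                             2 * n)
    x <- random_volume(grid, i)
    y <- random_stack(geom, i + 100)
    Ax <- forward_project(x, geom)$values
    Aty <- back_project(y, grid, mode = "matched")$values
    gap <- abs(sum(Ax * y$values) - sum(x$values * Aty)) /
      (sqrt(sum(Ax^2)) * sqrt(sum(y$values^2)))
    expect_lt(gap, 1e-6)
  }
})

test_that("chunk planning is deterministic, covering, and budget-respecting", {
  p <- plan_chunks(c(16, 16, 10), 16 * 16 * 10 * 8)
  expect_equal(p$chunk_sizes, 10L)
  p2 <- plan_chunks(c(16, 16, 10), 16 * 16 * 5 * 8)
  expect_equal(sum(p2$chunk_sizes), 10L)
  expect_equal(length(p2$chunk_sizes), 2L)
  expect_true(all(p2$chunk_sizes * 16 * 16 * 8 <= p2$memory_budget))
  expect_error(plan_chunks(c(16, 16, 10), 100), "budget")
})

test_that("chunked operators reproduce the unchunked result exactly", {
  grid <- volume_grid(12, 12, 4, 1)
  geom <- default_geometry(grid, 7, 360, 24, mode = "conebeam3d")
  vol <- random_volume(grid, 7)
  ref_fp <- forward_project(vol, geom)$values
  stack <- random_stack(geom, 8)
  ref_bp_v <- back_project(stack, grid, mode = "voxel")$values
  ref_bp_m <- back_project(stack, grid, mode = "matched")$values
  set.seed(9)
  slab_p <- 24 * 24 * 8          # one projection page
  slab_v <- 12 * 12 * 8          # one volume z-slice
  for (budget_mult in sample(1:5, 3)) {
    fp <- forward_project(vol, geom, chunk_budget = budget_mult * slab_p)$values
    expect_lt(max(abs(fp - ref_fp)), 1e-12 * max(abs(ref_fp)))
    bpv <- back_project(stack, grid, mode = "voxel",
                        chunk_budget = budget_mult * slab_v)$values
    expect_lt(max(abs(bpv - ref_bp_v)), 1e-12 * max(abs(ref_bp_v)))
    bpm <- back_project(stack, grid, mode = "matched",
                        chunk_budget = budget_mult * slab_v)$values
    expect_lt(max(abs(bpm - ref_bp_m)), 1e-12 * max(abs(ref_bp_m)))
  }
})

test_that("ray-driven integrals agree with a fine-sampling quadrature oracle", {
  # independent check of the Siddon traversal: sample the ray densely and
  # sum value * step
  grid <- tiny_grid(8)
  geom <- tiny_geom(8, num_proj = 2)
  vol <- random_volume(grid, 5)
  p <- forward_project(vol, geom)$values
  th <- geom$angles[2] * pi / 180
  sid <- geom$source_to_isocenter; sdd <- geom$source_to_detector
  nu <- geom$det_pixels_u; pu <- geom$det_pitch_u
  for (iu in c(5, 8, 12)) {
    src <- c(sid * cos(th), sid * sin(th))
    off <- (iu - 1 - (nu - 1) / 2) * pu
    det <- c(-(sdd - sid) * cos(th) - off * sin(th),
             -(sdd - sid) * sin(th) + off * cos(th))
    tt <- seq(0, 1, length.out = 200000)
    pts <- cbind(src[1] + tt * (det[1] - src[1]), src[2] + tt * (det[2] - src[2]))
    ix <- floor((pts[, 1] + 4) / 1) + 1
    iy <- floor((pts[, 2] + 4) / 1) + 1
    ok <- ix >= 1 & ix <= 8 & iy >= 1 & iy <= 8
    step <- sqrt(sum((det - src)^2)) / (length(tt) - 1)
    est <- sum(vol$values[cbind(ix[ok], iy[ok], 1)]) * step
    expect_equal(p[iu, 1, 2], est, tolerance = 1e-3)
  }
})
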