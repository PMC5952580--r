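#' Projection stack
#'
#' Line-integral data (dimensionless optical depth, i.e. mm of attenuation
#' path) on the detector grid for every projection angle.
#'
#' @param geometry A \code{scan_geometry}.
#' @param values Array of shape det_pixels_u x det_pixels_v x n_angles;
#'   a scalar is recycled.
#' @return A \code{projection_stack}.
#' @export
projection_stack <- function(geometry, values = 0) {
  stopifnot(inherits(geometry, "scan_geometry"))
  dims <- c(geometry$det_pixels_u, geometry$det_pixels_v,
            length(geometry$angles))
  if (length(values) == 1) values <- array(values, dims)
  values <- as.array(values)
  if (length(dim(values)) == 2) dim(values) <- c(dim(values)[1], 1L, dim(values)[2])
  if (!identical(as.integer(dim(values)), as.integer(dims)))
    stop("projection values shape inconsistent with geometry", call. = FALSE)
  if (!all(is.finite(values)))
    stop("projection values must be finite", call. = FALSE)
  structure(list(geometry = geometry, values = values),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<projection_stack> %dx%d detector, %d angles, range [%g, %g]\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Plan memory-bounded chunks along one axis
#'
#' Partitions an array along \code{axis} into the fewest contiguous chunks
#' such that each chunk (double precision) fits in \code{budget} bytes.
#' Deterministic: all chunks take the maximal admissible size except a
#' possibly smaller last one.
#'
#' @param shape Integer vector of array dimensions.
#' @param budget Memory budget in bytes.
#' @param axis Axis (1-based) along which to partition.
#' @return A \code{chunk_plan} with fields \code{axis}, \code{chunk_sizes},
#'   \code{memory_budget}.
#' @export
plan_chunks <- function(shape, budget, axis = length(shape)) {
  shape <- as.integer(shape)
  slab_bytes <- prod(shape[-axis]) * 8
  per_chunk <- floor(budget / slab_bytes)
  if (per_chunk < 1)
    stop(sprintf("chunk budget %d bytes below one slab (%d bytes)",
                 budget, slab_bytes), call. = FALSE)
  n <- shape[axis]
  per_chunk <- min(per_chunk, n)
  k <- ceiling(n / per_chunk)
  sizes <- rep(per_chunk, k)
  sizes[k] <- n - per_chunk * (k - 1)
  structure(list(axis = axis, chunk_sizes = as.integer(sizes),
                 memory_budget = budget),
            class = "chunk_plan")
}

# cumulative wall-clock spent in the two operators, for the per-stage
# timing breakdown logged by the CLI
.timers <- new.env(parent = emptyenv())
.timers$projection <- 0
.timers$backprojection <- 0

reset_timers <- function() {
  .timers$projection <- 0
  .timers$backprojection <- 0
}

get_timers <- function() {
  list(projection = .timers$projection,
       backprojection = .timers$backprojection)
}

chunk_ranges <- function(plan) {
  ends <- cumsum(plan$chunk_sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(c, starts, ends)
}

deg2rad <- function(x) x * pi / 180

#' Ray-driven forward projection
#'
#' Applies the system operator A: each detector pixel receives the exact
#' radiological path integral (Siddon length-weighted traversal) of the
#' volume along the source-pixel ray. Rays that miss the volume contribute
#' exactly 0. The computation is partitioned over the projection axis; the
#' result is independent of the chunking.
#'
#' @param vol A \code{ct_volume}.
#' @param geom A \code{scan_geometry}.
#' @param chunk_budget Memory budget in bytes for one projection chunk, or
#'   \code{NULL} for a single chunk.
#' @return A \code{projection_stack}.
#' @export
forward_project <- function(vol, geom, chunk_budget = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(geom, "scan_geometry"))
  check_fan_mode(vol$grid, geom)
  na <- length(geom$angles)
  shape <- c(geom$det_pixels_u, geom$det_pixels_v, na)
  plan <- if (is.null(chunk_budget)) plan_chunks(shape, prod(shape) * 8, 3L)
          else plan_chunks(shape, chunk_budget, 3L)
  out <- array(0, shape)
  t0 <- proc.time()[3]
  for (rg in chunk_ranges(plan)) {
    idx <- rg[1]:rg[2]
    out[, , idx] <- cpp_forward_project(
      vol$values, dim(vol$values), vol$grid$voxel_size,
      deg2rad(geom$angles[idx]),
      geom$source_to_isocenter, geom$source_to_detector,
      geom$det_pixels_u, geom$det_pixels_v,
      geom$det_pitch_u, geom$det_pitch_v)
  }
  .timers$projection <- .timers$projection + (proc.time()[3] - t0)
  projection_stack(geom, out)
}

#' Backprojection
#'
#' Applies the transpose-like operator. The default \code{"voxel"} mode is
#' the voxel-driven backprojector: every voxel center is projected onto the
#' detector at every angle and the bilinearly interpolated value is
#' accumulated (scaled by voxel_size so its magnitude is commensurate with
#' the matched adjoint). \code{"matched"} is the exact discrete transpose of
#' the ray-driven projector, used for adjoint identities and
#' guaranteed-symmetric normal equations. Both are partitioned over volume
#' z-slabs; the result is independent of the chunking. Voxels projecting
#' outside the detector contribute 0.
#'
#' @param proj A \code{projection_stack}.
#' @param grid A \code{volume_grid}.
#' @param mode \code{"voxel"} (unmatched, default) or \code{"matched"}.
#' @param chunk_budget Bytes per volume z-slab chunk, or \code{NULL}.
#' @return A \code{ct_volume}.
#' @export
back_project <- function(proj, grid, mode = c("voxel", "matched"),
                         chunk_budget = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(proj, "projection_stack"), inherits(grid, "volume_grid"))
  geom <- proj$geometry
  check_fan_mode(grid, geom)
  shape <- c(grid$nx, grid$ny, grid$nz)
  plan <- if (is.null(chunk_budget)) plan_chunks(shape, prod(shape) * 8, 3L)
          else plan_chunks(shape, chunk_budget, 3L)
  out <- array(0, shape)
  fn <- if (mode == "matched") {
    function(z0, z1) cpp_back_project_matched(
      proj$values, as.integer(shape), grid$voxel_size,
      deg2rad(geom$angles),
      geom$source_to_isocenter, geom$source_to_detector,
      geom$det_pixels_u, geom$det_pixels_v,
      geom$det_pitch_u, geom$det_pitch_v, z0, z1)
  } else {
    function(z0, z1) cpp_back_project_voxel(
      proj$values, as.integer(shape), grid$voxel_size,
      deg2rad(geom$angles),
      geom$source_to_isocenter, geom$source_to_detector,
      geom$det_pixels_u, geom$det_pixels_v,
      geom$det_pitch_u, geom$det_pitch_v, z0, z1, 0L)
  }
  t0 <- proc.time()[3]
  for (rg in chunk_ranges(plan)) {
    slab <- fn(rg[1] - 1L, rg[2] - 1L)
    out[, , rg[1]:rg[2]] <- slab[, , rg[1]:rg[2], drop = FALSE]
  }
  .timers$backprojection <- .timers$backprojection + (proc.time()[3] - t0)
  ct_volume(grid, out)
}

check_fan_mode <- function(grid, geom) {
  if (geom$mode == "fanbeam2d" && (grid$nz != 1 || geom$det_pixels_v != 1))
    stop("fanbeam2d requires nz = 1 and det_pixels_v = 1", call. = FALSE)
  invisible(TRUE)
}

#' Dense system matrix (test oracle)
#'
#' Materializes the forward operator as an explicit matrix by probing with
#' voxel impulses: column j is the flattened projection of an impulse at
#' voxel j. Intended for verification on small grids only.
#'
#' @param geom A \code{scan_geometry}.
#' @param grid A \code{volume_grid}.
#' @param max_voxels Refuse to build beyond this many voxels.
#' @return A dense matrix of size (n_detector_pixels * n_angles) x n_voxels.
#' @export
dense_system_matrix <- function(geom, grid, max_voxels = 32^3) {
  nvox <- grid$nx * grid$ny * grid$nz
  if (nvox > max_voxels)
    stop(sprintf("grid has %d voxels, above the dense-matrix cap of %d",
                 nvox, max_voxels), call. = FALSE)
  nray <- geom$det_pixels_u * geom$det_pixels_v * length(geom$angles)
  A <- matrix(0, nray, nvox)
  e <- array(0, c(grid$nx, grid$ny, grid$nz))
  for (j in seq_len(nvox)) {
    e[j] <- 1
    A[, j] <- as.vector(forward_project(ct_volume(grid, e), geom)$values)
    e[j] <- 0
  }
  A
}
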