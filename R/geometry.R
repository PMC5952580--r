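#' Circular-trajectory scan geometry
#'
#' Describes a fan-beam (2D) or cone-beam (3D) CT acquisition on a circular
#' source trajectory: source-to-isocenter and source-to-detector distances,
#' the flat-detector grid, and the projection angles.
#'
#' Conventions shared by every operator in the package: right-handed
#' coordinates with the isocenter at the volume center; at angle theta the
#' source sits at \code{sid * (cos(theta), sin(theta), 0)}; the detector
#' u-axis lies in the rotation plane, the v-axis is parallel to z; voxel
#' values are sampled at voxel centers.
#'
#' @param source_to_isocenter Source-to-isocenter distance (mm).
#' @param source_to_detector Source-to-detector distance (mm), must exceed
#'   \code{source_to_isocenter}.
#' @param det_pixels_u,det_pixels_v Detector pixel counts along u (in-plane)
#'   and v (axial).
#' @param det_pitch_u,det_pitch_v Detector pixel pitch (mm).
#' @param angles Projection angles in degrees, strictly increasing.
#' @param mode Either \code{"fanbeam2d"} or \code{"conebeam3d"}.
#' @return An object of class \code{scan_geometry}.
#' @export
scan_geometry <- function(source_to_isocenter, source_to_detector,
                          det_pixels_u, det_pixels_v,
                          det_pitch_u, det_pitch_v,
                          angles, mode = c("fanbeam2d", "conebeam3d")) {
  mode <- match.arg(mode)
  if (!is.numeric(source_to_isocenter) || source_to_isocenter <= 0 ||
      !is.numeric(source_to_detector) ||
      source_to_detector <= source_to_isocenter)
    stop("invalid geometry: need source_to_detector > source_to_isocenter > 0",
         call. = FALSE)
  if (det_pitch_u <= 0 || det_pitch_v <= 0)
    stop("invalid geometry: detector pitch must be positive", call. = FALSE)
  if (det_pixels_u < 1 || det_pixels_v < 1)
    stop("invalid geometry: detector pixel counts must be >= 1", call. = FALSE)
  angles <- as.numeric(angles)
  if (length(angles) < 1 || anyNA(angles))
    stop("invalid geometry: angles must be non-empty and finite", call. = FALSE)
  if (length(angles) > 1 && any(diff(angles) <= 0))
    stop("invalid geometry: angles must be strictly increasing", call. = FALSE)
  structure(list(
    source_to_isocenter = as.numeric(source_to_isocenter),
    source_to_detector = as.numeric(source_to_detector),
    det_pixels_u = as.integer(det_pixels_u),
    det_pixels_v = as.integer(det_pixels_v),
    det_pitch_u = as.numeric(det_pitch_u),
    det_pitch_v = as.numeric(det_pitch_v),
    angles = angles,
    mode = mode
  ), class = "scan_geometry")
}

#' Build a uniform circular geometry from scan-design parameters
#'
#' Angles are uniformly spaced over \code{span} degrees starting at 0. For a
#' full turn (\code{span == 360}) the endpoint is excluded (step
#' \code{span/num_proj}); for a partial span both endpoints are included
#' (step \code{span/(num_proj - 1)}; a single projection sits at 0).
#'
#' @param num_proj Number of projections.
#' @param span Angular span in degrees, in (0, 360].
#' @param dim_proj Detector size in pixels (square detector in 3D; in
#'   fan-beam mode the v dimension collapses to a single row).
#' @param pitch Detector pixel pitch (mm).
#' @param sid,sdd Source-to-isocenter and source-to-detector distances (mm).
#' @param mode \code{"fanbeam2d"} or \code{"conebeam3d"}.
#' @return A \code{scan_geometry}.
#' @export
make_circular_geometry <- function(num_proj, span, dim_proj, pitch,
                                   sid, sdd,
                                   mode = c("fanbeam2d", "conebeam3d")) {
  mode <- match.arg(mode)
  if (num_proj < 1) stop("num_proj must be >= 1", call. = FALSE)
  if (!is.numeric(span) || span <= 0 || span > 360)
    stop("invalid geometry: span must lie in (0, 360]", call. = FALSE)
  if (dim_proj < 2) stop("dim_proj must be >= 2", call. = FALSE)
  angles <- if (span == 360) {
    seq(0, span, by = span / num_proj)[seq_len(num_proj)]
  } else if (num_proj == 1) {
    0
  } else {
    seq(0, span, length.out = num_proj)
  }
  nv <- if (mode == "fanbeam2d") 1L else as.integer(dim_proj)
  scan_geometry(sid, sdd, dim_proj, nv, pitch, pitch, angles, mode)
}

#' Default geometry for a volume grid
#'
#' Picks magnification-2 distances and a detector pitch with a 10% margin so
#' the whole field of view of \code{grid} is seen by every projection.
#'
#' @param grid A \code{volume_grid}.
#' @inheritParams make_circular_geometry
#' @return A \code{scan_geometry}.
#' @export
default_geometry <- function(grid, num_proj, span, dim_proj = NULL,
                             mode = c("fanbeam2d", "conebeam3d")) {
  mode <- match.arg(mode)
  if (is.null(dim_proj)) dim_proj <- max(grid$nx, grid$ny)
  extent <- max(grid$nx, grid$ny, if (mode == "conebeam3d") grid$nz else 0) *
    grid$voxel_size
  sid <- 2 * extent
  sdd <- 4 * extent   # magnification 2
  pitch <- 2 * extent * 1.1 / dim_proj
  make_circular_geometry(num_proj, span, dim_proj, pitch, sid, sdd, mode)
}

#' Voxel grid of a reconstruction volume
#'
#' @param nx,ny,nz Voxel counts; \code{nz = 1} for 2D slices.
#' @param voxel_size Isotropic voxel size (mm).
#' @return A \code{volume_grid}; physical extent \code{n * voxel_size}
#'   centered on the isocenter, values at voxel centers.
#' @export
volume_grid <- function(nx, ny, nz = 1L, voxel_size = 1) {
  if (nx < 1 || ny < 1 || nz < 1) stop("grid dims must be >= 1", call. = FALSE)
  if (voxel_size <= 0) stop("voxel_size must be positive", call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 voxel_size = as.numeric(voxel_size), origin = "isocenter"),
            class = "volume_grid")
}

#' Volume of attenuation values on a grid
#'
#' @param grid A \code{volume_grid}.
#' @param values Numeric array of attenuation values (1/mm); a scalar is
#'   recycled. Shape must match the grid.
#' @return A \code{ct_volume} with fields \code{grid} and \code{values}
#'   (an \code{nx x ny x nz} array).
#' @export
ct_volume <- function(grid, values = 0) {
  stopifnot(inherits(grid, "volume_grid"))
  dims <- c(grid$nx, grid$ny, grid$nz)
  if (length(values) == 1) values <- array(values, dims)
  values <- as.array(values)
  if (length(dim(values)) == 2) dim(values) <- c(dim(values), 1L)
  if (!identical(as.integer(dim(values)), as.integer(dims)))
    stop("values shape does not match grid", call. = FALSE)
  if (!all(is.finite(values)))
    stop("volume values must be finite", call. = FALSE)
  structure(list(grid = grid, values = values), class = "ct_volume")
}

#' Field-of-view mask
#'
#' Binary mask of the cylinder (axis z) inscribed in the x-y extent of the
#' grid: voxel centers within radius \code{(min(nx, ny) - 1)/2 * voxel_size}
#' of the axis are 1, all others 0. Reapplying the mask is a no-op.
#'
#' @param grid A \code{volume_grid}.
#' @return A binary \code{ct_volume}.
#' @export
fov_mask <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  vs <- grid$voxel_size
  x <- (seq_len(grid$nx) - (grid$nx + 1) / 2) * vs
  y <- (seq_len(grid$ny) - (grid$ny + 1) / 2) * vs
  r2 <- outer(x^2, y^2, "+")
  rad <- (min(grid$nx, grid$ny) - 1) / 2 * vs
  m <- array(as.numeric(r2 <= rad^2 + 1e-12), c(grid$nx, grid$ny, grid$nz))
  ct_volume(grid, m)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %s: %d angles [%g..%g deg], detector %dx%d @ %g mm, SID %g / SDD %g mm\n",
              x$mode, length(x$angles), min(x$angles), max(x$angles),
              x$det_pixels_u, x$det_pixels_v, x$det_pitch_u,
              x$source_to_isocenter, x$source_to_detector))
  invisible(x)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %dx%dx%d @ %g mm, range [%g, %g]\n",
              x$grid$nx, x$grid$ny, x$grid$nz, x$grid$voxel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

# geometry <-> plain list, for the YAML sidecar round-trip
geometry_to_list <- function(geom) {
  unclass(geom)
}

geometry_from_list <- function(lst) {
  scan_geometry(lst$source_to_isocenter, lst$source_to_detector,
                lst$det_pixels_u, lst$det_pixels_v,
                lst$det_pitch_u, lst$det_pitch_v,
                lst$angles, lst$mode)
}
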