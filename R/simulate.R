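#' Phantom specification
#'
#' Piecewise-constant synthetic objects standing in for a real scan:
#' \code{"shepp_logan"} (the modified Shepp-Logan head phantom, extended
#' with ellipsoid z-axes in 3D), \code{"discs"} (two off-center discs on a
#' faint background cylinder), or \code{"random_ellipsoids"} (seeded random
#' ellipses/ellipsoids inside the field of view).
#'
#' @param kind One of \code{"shepp_logan"}, \code{"discs"},
#'   \code{"random_ellipsoids"}.
#' @param dims Integer vector \code{c(nx, ny)} or \code{c(nx, ny, nz)}.
#' @param voxel_size Voxel size (mm).
#' @param n_objects Number of objects for \code{"random_ellipsoids"}.
#' @param amplitude Maximum attenuation amplitude.
#' @param seed Integer seed; the same seed always yields the same phantom.
#' @return A \code{phantom_spec}.
#' @export
phantom_spec <- function(kind = c("shepp_logan", "discs", "random_ellipsoids"),
                         dims = c(64, 64), voxel_size = 1,
                         n_objects = 4L, amplitude = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (any(dims <= 0)) stop("phantom dims must be positive", call. = FALSE)
  if (length(dims) == 2) dims <- c(dims, 1L)
  structure(list(kind = kind, dims = as.integer(dims),
                 voxel_size = voxel_size, n_objects = as.integer(n_objects),
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "phantom_spec")
}

# modified Shepp-Logan ellipses: intensity, a, b, x0, y0, phi(deg), and a
# z semi-axis/center pair for the 3D extension
shepp_logan_table <- function() {
  m <- matrix(c(
     1.00, 0.69,  0.92,   0,     0,     0,   0.90,  0,
    -0.80, 0.6624, 0.874, 0,    -0.0184, 0,  0.88,  0,
    -0.20, 0.11,  0.31,   0.22,  0,   -18,   0.21, -0.25,
    -0.20, 0.16,  0.41,  -0.22,  0,    18,   0.22, -0.25,
     0.10, 0.21,  0.25,   0,     0.35,  0,   0.35, -0.25,
     0.10, 0.046, 0.046,  0,     0.10,  0,   0.046,-0.25,
     0.10, 0.046, 0.046,  0,    -0.10,  0,   0.02, -0.25,
     0.10, 0.046, 0.023, -0.08, -0.605, 0,   0.02, -0.25,
     0.10, 0.023, 0.023,  0,    -0.606, 0,   0.10, -0.25,
     0.10, 0.023, 0.046,  0.06, -0.605, 0,   0.10, -0.25), ncol = 8, byrow = TRUE)
  colnames(m) <- c("A", "a", "b", "x0", "y0", "phi", "c", "z0")
  m
}

#' Build a phantom volume
#'
#' All structures lie inside the cylindrical field of view; values are
#' clamped to \code{[0, amplitude]}.
#'
#' @param spec A \code{phantom_spec}.
#' @return A \code{ct_volume}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  grid <- volume_grid(d[1], d[2], d[3], spec$voxel_size)
  # normalized coordinates in [-1, 1] on the shorter x-y half-extent
  half <- (min(d[1], d[2]) - 1) / 2
  x <- (seq_len(d[1]) - (d[1] + 1) / 2) / half
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) / half
  z <- if (d[3] > 1) (seq_len(d[3]) - (d[3] + 1) / 2) / ((d[3] - 1) / 2) else 0

  vals <- array(0, d)
  add_ellipsoid <- function(vals, A, a, b, x0, y0, phi, cc = 1, z0 = 0) {
    ph <- phi * pi / 180
    for (iz in seq_len(d[3])) {
      zz <- if (d[3] > 1) ((z[iz] - z0) / cc)^2 else 0
      if (zz >= 1) next
      xr <- outer(x - x0, rep(1, d[2])) * cos(ph) +
            outer(rep(1, d[1]), y - y0) * sin(ph)
      yr <- -outer(x - x0, rep(1, d[2])) * sin(ph) +
            outer(rep(1, d[1]), y - y0) * cos(ph)
      inside <- (xr / a)^2 + (yr / b)^2 + zz <= 1
      vals[, , iz] <- vals[, , iz] + A * inside
    }
    vals
  }

  if (spec$kind == "shepp_logan") {
    tb <- shepp_logan_table()
    for (i in seq_len(nrow(tb)))
      vals <- add_ellipsoid(vals, tb[i, "A"], tb[i, "a"], tb[i, "b"],
                            tb[i, "x0"], tb[i, "y0"], tb[i, "phi"],
                            tb[i, "c"], tb[i, "z0"])
    vals <- pmin(pmax(vals, 0), 1) * spec$amplitude
  } else if (spec$kind == "discs") {
    vals <- add_ellipsoid(vals, 0.2, 0.85, 0.85, 0, 0, 0, 1, 0)
    vals <- add_ellipsoid(vals, 0.6, 0.25, 0.25, -0.35, 0.2, 0, 0.6, 0)
    vals <- add_ellipsoid(vals, 0.8, 0.18, 0.18, 0.3, -0.3, 0, 0.5, 0)
    vals <- pmin(vals, 1) * spec$amplitude
  } else {
    rng <- local_rng(spec$seed)
    for (i in seq_len(spec$n_objects)) {
      a <- rng$runif(1, 0.08, 0.35); b <- rng$runif(1, 0.08, 0.35)
      r <- 0.9 - max(a, b)
      th <- rng$runif(1, 0, 2 * pi); rad <- rng$runif(1, 0, r)
      A <- rng$runif(1, 0.2, 1)
      cc <- if (d[3] > 1) rng$runif(1, 0.2, 0.8) else 1
      z0 <- if (d[3] > 1) rng$runif(1, -0.4, 0.4) else 0
      vals <- add_ellipsoid(vals, A, a, b, rad * cos(th), rad * sin(th),
                            rng$runif(1, 0, 180), cc, z0)
    }
    vals <- pmin(vals, 1) * spec$amplitude
  }
  ct_volume(grid, vals)
}

# seeded RNG that restores the caller's random state on exit
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  state <- new.env()
  state$snapshot <- get(".Random.seed", envir = globalenv())
  restore <- function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
  use <- function(f) function(...) {
    assign(".Random.seed", state$snapshot, envir = globalenv())
    out <- f(...)
    state$snapshot <- get(".Random.seed", envir = globalenv())
    restore()
    out
  }
  list(runif = use(stats::runif), rpois = use(stats::rpois))
}

#' Simulate a limited-data acquisition
#'
#' Forward-projects the object and optionally applies Poisson counting
#' noise: transmitted counts \code{~ Poisson(I0 * exp(-p))} are converted
#' back to line integrals \code{-log(counts / I0)}; zero counts are clamped
#' to one count. With \code{supersample = TRUE} the object is projected on a
#' 2x-refined grid (linear interpolation) so the simulation does not share
#' the reconstruction forward model exactly (inverse-crime avoidance).
#'
#' @param vol Ground-truth \code{ct_volume}.
#' @param geom A \code{scan_geometry}.
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param i0 Incident photon count per detector pixel (Poisson noise).
#' @param seed Integer seed for the noise.
#' @param supersample Project a 2x-refined copy of the object.
#' @return A \code{projection_stack}.
#' @export
simulate_acquisition <- function(vol, geom, noise = c("none", "poisson"),
                                 i0 = 1e5, seed = 1L, supersample = FALSE) {
  noise <- match.arg(noise)
  stopifnot(inherits(vol, "ct_volume"))
  if (noise == "poisson" && i0 <= 0) stop("i0 must be positive", call. = FALSE)
  pv <- if (supersample) forward_project(refine2x(vol), geom)
        else forward_project(vol, geom)
  if (noise == "none") return(pv)
  rng <- local_rng(seed)
  p <- pv$values
  counts <- rng$rpois(length(p), i0 * exp(-p))
  counts <- pmax(counts, 1)
  projection_stack(geom, array(-log(counts / i0), dim(p)))
}

# 2x in-plane grid refinement by bilinear interpolation (nearest in z)
refine2x <- function(vol) {
  g <- vol$grid
  g2 <- volume_grid(2L * g$nx, 2L * g$ny, g$nz, g$voxel_size / 2)
  v <- vol$values
  out <- array(0, c(g2$nx, g2$ny, g2$nz))
  # fine voxel centers in coarse index coordinates
  fx <- ((seq_len(g2$nx) - (g2$nx + 1) / 2) / 2) + (g$nx + 1) / 2
  fy <- ((seq_len(g2$ny) - (g2$ny + 1) / 2) / 2) + (g$ny + 1) / 2
  i0x <- pmin(pmax(floor(fx), 1), g$nx - 1); ax <- fx - i0x
  i0y <- pmin(pmax(floor(fy), 1), g$ny - 1); ay <- fy - i0y
  for (iz in seq_len(g$nz)) {
    sl <- v[, , iz]
    p00 <- sl[cbind(rep(i0x, g2$ny), rep(i0y, each = g2$nx))]
    p10 <- sl[cbind(rep(i0x + 1, g2$ny), rep(i0y, each = g2$nx))]
    p01 <- sl[cbind(rep(i0x, g2$ny), rep(i0y + 1, each = g2$nx))]
    p11 <- sl[cbind(rep(i0x + 1, g2$ny), rep(i0y + 1, each = g2$nx))]
    wx <- rep(ax, g2$ny); wy <- rep(ay, each = g2$nx)
    out[, , iz] <- array((1 - wx) * (1 - wy) * p00 + wx * (1 - wy) * p10 +
                         (1 - wx) * wy * p01 + wx * wy * p11,
                         c(g2$nx, g2$ny))
  }
  ct_volume(g2, out)
}
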