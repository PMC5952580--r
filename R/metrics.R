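#' Root-mean-square error between two volumes
#'
#' \code{sqrt(mean((u - ref)^2))}, optionally restricted to a binary mask
#' (e.g. the field of view). Computed on the raw intensity scale without
#' normalization.
#'
#' @param u,ref \code{ct_volume}s of identical shape.
#' @param mask Optional binary \code{ct_volume} restricting the average.
#' @return Non-negative scalar.
#' @export
rmse <- function(u, ref, mask = NULL) {
  stopifnot(inherits(u, "ct_volume"), inherits(ref, "ct_volume"))
  if (!identical(dim(u$values), dim(ref$values)))
    stop("volume shapes differ", call. = FALSE)
  d2 <- (u$values - ref$values)^2
  if (is.null(mask)) return(sqrt(mean(d2)))
  m <- mask$values > 0
  sqrt(mean(d2[m]))
}

#' Circular region of interest
#'
#' A disc of voxels on one z-slice, used for SNR measurement in a
#' homogeneous area.
#'
#' @param center Voxel coordinates \code{c(cx, cy)} (1-based).
#' @param radius Radius in voxels.
#' @param slice z-slice index (1-based).
#' @return An \code{roi_spec}.
#' @export
roi_spec <- function(center, radius, slice = 1L) {
  stopifnot(length(center) == 2, radius > 0, slice >= 1)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 slice = as.integer(slice)), class = "roi_spec")
}

#' Signal-to-noise ratio in a region of interest, in dB
#'
#' \code{20 * log10(mean(ROI) / sd(ROI))}. The SNR improvement of the
#' iterative method over FDK is the difference of the two values on the
#' same homogeneous ROI. A constant ROI has infinite SNR and is flagged.
#'
#' @param vol A \code{ct_volume}.
#' @param roi An \code{roi_spec}, fully inside the grid.
#' @return Scalar dB value; \code{Inf} with a warning when the ROI standard
#'   deviation is zero.
#' @export
snr_db <- function(vol, roi) {
  stopifnot(inherits(vol, "ct_volume"), inherits(roi, "roi_spec"))
  g <- vol$grid
  if (roi$center[1] - roi$radius < 1 || roi$center[1] + roi$radius > g$nx ||
      roi$center[2] - roi$radius < 1 || roi$center[2] + roi$radius > g$ny ||
      roi$slice > g$nz)
    stop("ROI not fully inside the grid", call. = FALSE)
  ix <- seq_len(g$nx); iy <- seq_len(g$ny)
  inside <- outer((ix - roi$center[1])^2, (iy - roi$center[2])^2, "+") <=
    roi$radius^2
  vals <- vol$values[, , roi$slice][inside]
  s <- stats::sd(vals)
  if (s == 0) {
    warning("ROI standard deviation is zero; SNR is infinite")
    return(Inf)
  }
  20 * log10(mean(vals) / s)
}
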