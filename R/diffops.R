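#' Forward-difference gradient along one axis
#'
#' Forward differences with a replicate-edge (Neumann) boundary: the last
#' difference along the axis is 0. Operates on the raw array of a volume;
#' the total-variation term couples to these gradients through the split
#' variables.
#'
#' @param x Numeric array (2D or 3D).
#' @param axis \code{"x"}, \code{"y"} or \code{"z"} (array dims 1..3).
#' @return Array of the same shape.
#' @export
grad_axis <- function(x, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  a <- match(axis, c("x", "y", "z"))
  if (a > length(d) || d[a] < 1)
    stop(sprintf("axis %s not available on this array", axis), call. = FALSE)
  n <- d[a]
  g <- shift_axis(x, a, 1L) - x
  # zero out the last slice along the axis (Neumann boundary)
  assign_slice(g, a, n, 0)
}

#' Adjoint of the forward-difference gradient
#'
#' The exact discrete adjoint: \code{<grad(u), v> == <u, grad_adjoint(v)>}
#' holds to floating-point exactness. With the Neumann forward difference
#' this is a backward difference with negated first/last boundary terms
#' (a discrete negative divergence).
#'
#' @inheritParams grad_axis
#' @export
grad_adjoint_axis <- function(x, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  d <- dim(x)
  a <- match(axis, c("x", "y", "z"))
  if (a > length(d) || d[a] < 1)
    stop(sprintf("axis %s not available on this array", axis), call. = FALSE)
  n <- d[a]
  # adjoint of (S_{-1} - I) restricted to first n-1 slices:
  # out_1 = -v_1; out_i = v_{i-1} - v_i (1<i<n); out_n = v_{n-1}
  v <- assign_slice(x, a, n, 0)
  shift_axis(v, a, -1L) - v
}

# zero-filled shift: out_i = x_{i+by} when in range, 0 otherwise
shift_axis <- function(x, a, by) {
  d <- dim(x)
  n <- d[a]
  src <- seq_len(n) + by
  keep <- src >= 1L & src <= n
  out <- array(0, d)
  idx_out <- lapply(d, seq_len)
  idx_in <- idx_out
  idx_out[[a]] <- which(keep)
  idx_in[[a]] <- src[keep]
  src_vals <- do.call(`[`, c(list(x), idx_in, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), idx_out, list(value = src_vals)))
}

assign_slice <- function(x, a, i, value) {
  idx <- lapply(dim(x), seq_len)
  idx[[a]] <- i
  do.call(`[<-`, c(list(x), idx, list(value = value)))
}

#' Gradient over a set of axes
#' @param x Numeric array.
#' @param axes Character vector of axes, e.g. \code{c("x", "y")}.
#' @return Named list of gradient arrays.
#' @export
grad_all <- function(x, axes = c("x", "y")) {
  stats::setNames(lapply(axes, function(a) grad_axis(x, a)), axes)
}

#' Sum of per-axis adjoints applied to a list of fields
#' @param fields Named list of arrays (one per axis).
#' @return Single array, \code{sum_a grad_adjoint_axis(fields[[a]], a)}.
#' @export
grad_adjoint_all <- function(fields) {
  out <- 0
  for (a in names(fields)) out <- out + grad_adjoint_axis(fields[[a]], a)
  out
}
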