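#' Reconstruction parameters for the Split Bregman solver
#'
#' The TV-constrained reconstruction
#' \deqn{\min \|\nabla u\|_1 \ \mathrm{s.t.}\ \|Au - f\|_2^2 \le \sigma^2,\
#'   u \ge 0,\ u \in \Omega}
#' is solved through its unconstrained splitting: at each outer iteration an
#' L2 sub-problem \code{K u = rhs} with
#' \code{K = mu * A^T A + lambda * grad^T grad + beta * I} is solved by
#' BiCGStab, the split gradient variables are updated by isotropic shrinkage
#' with threshold \code{alpha / lambda}, and Bregman updates re-inject the
#' data and gradient residuals.
#'
#' @param alpha Shrinkage (TV) weight; threshold is \code{alpha / lambda}.
#' @param mu Data-fidelity weight.
#' @param lam TV coupling weight.
#' @param beta Stabilization weight (additive \code{beta * I} in K).
#' @param outer_iterations Maximum outer (Bregman) iterations.
#' @param krylov_tol,krylov_max Inner BiCGStab relative tolerance and
#'   iteration cap per outer iteration.
#' @param tv_axes Axes carrying TV split variables; default \code{c("x","y")}
#'   (applied per z-slice in 3D), with \code{"z"} opt-in.
#' @param apply_fov_mask Constrain the solution to the cylindrical field of
#'   view (the \eqn{\Omega} constraint).
#' @param stop_rel_change Early-stopping threshold on the relative change of
#'   u between outer iterations (default 1\%).
#' @param backproject_mode Backprojector used for A^T: \code{"matched"}
#'   (exact adjoint of the ray-driven projector, default) or \code{"voxel"}
#'   (unmatched voxel-driven). The matched adjoint keeps K symmetric
#'   positive definite so the inner solves — and with them the Bregman outer
#'   loop — converge reliably; the unmatched pair is retained for
#'   comparison but can destabilize long outer runs.
#' @param chunk_budget Optional memory budget in bytes for the chunked
#'   operators.
#' @return A \code{recon_params} object.
#' @export
recon_params <- function(alpha = 0.003, mu = 20, lam = 2, beta = 3,
                         outer_iterations = 35L,
                         krylov_tol = 1e-4, krylov_max = 30L,
                         tv_axes = c("x", "y"),
                         apply_fov_mask = TRUE,
                         stop_rel_change = 0.01,
                         backproject_mode = c("matched", "voxel"),
                         chunk_budget = NULL) {
  backproject_mode <- match.arg(backproject_mode)
  if (mu <= 0 || lam <= 0) stop("mu and lam must be positive", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (outer_iterations < 1) stop("outer_iterations must be >= 1", call. = FALSE)
  if (stop_rel_change <= 0 || stop_rel_change > 1)
    stop("stop_rel_change must lie in (0, 1]", call. = FALSE)
  stopifnot(all(tv_axes %in% c("x", "y", "z")))
  structure(list(alpha = alpha, mu = mu, lam = lam, beta = beta,
                 outer_iterations = as.integer(outer_iterations),
                 krylov_tol = krylov_tol, krylov_max = as.integer(krylov_max),
                 tv_axes = tv_axes, apply_fov_mask = apply_fov_mask,
                 stop_rel_change = stop_rel_change,
                 backproject_mode = backproject_mode,
                 chunk_budget = chunk_budget),
            class = "recon_params")
}

#' Isotropic shrinkage (soft-thresholding)
#'
#' Closed-form minimizer of \code{|d| + (lam/2)(d - s)^2} applied jointly
#' over the TV axes: with pointwise magnitude
#' \code{m = sqrt(sum_a s_a^2)}, each output component is
#' \code{(s_a / m) * max(m - threshold, 0)}, and 0 where \code{m = 0}.
#'
#' @param s Named list of arrays, one per axis (or a single array).
#' @param threshold Positive shrinkage threshold.
#' @return Same structure as \code{s}.
#' @export
shrink <- function(s, threshold) {
  stopifnot(threshold > 0)
  single <- !is.list(s)
  if (single) s <- list(s)
  m <- sqrt(Reduce(`+`, lapply(s, function(a) a^2)))
  scale <- ifelse(m > 0, pmax(m - threshold, 0) / pmax(m, .Machine$double.xmin), 0)
  out <- lapply(s, function(a) a * scale)
  if (single) out[[1]] else out
}

#' Normal-equation operator K
#'
#' Applies \code{K u = mu * A^T(A u) + lam * grad^T grad u + beta * u}, the
#' operator of the inner L2 sub-problem, in a matrix-free fashion. This is
#' the callback handed to the Krylov solver.
#'
#' @param u A \code{ct_volume}.
#' @param geom A \code{scan_geometry}.
#' @param params A \code{recon_params}.
#' @return A \code{ct_volume} holding K u.
#' @export
apply_K <- function(u, geom, params) {
  stopifnot(inherits(u, "ct_volume"))
  ata <- back_project(forward_project(u, geom, params$chunk_budget), u$grid,
                      mode = params$backproject_mode,
                      chunk_budget = params$chunk_budget)$values
  gtg <- grad_adjoint_all(grad_all(u$values, params$tv_axes))
  ct_volume(u$grid, params$mu * ata + params$lam * gtg + params$beta * u$values)
}

#' Right-hand side of the inner sub-problem
#'
#' \code{rhs = mu * A^T f^k + lam * sum_a grad_a^T (d_a - b_a)}.
#'
#' @param fk A \code{projection_stack}, the Bregman-augmented data.
#' @param d,b Named lists of split-variable arrays per TV axis.
#' @param grid Target \code{volume_grid}.
#' @param params A \code{recon_params}.
#' @return A \code{ct_volume}.
#' @export
compute_rhs <- function(fk, d, b, grid, params) {
  atf <- back_project(fk, grid, mode = params$backproject_mode,
                      chunk_budget = params$chunk_budget)$values
  db <- stats::setNames(lapply(names(d), function(a) d[[a]] - b[[a]]), names(d))
  ct_volume(grid, params$mu * atf + params$lam * grad_adjoint_all(db))
}

#' Bregman update of the augmented data
#'
#' \code{f^{k+1} = f^k + f - A u^{k+1}}: re-injects the data residual so the
#' fidelity constraint is enforced progressively across outer iterations.
#'
#' @param fk Current augmented \code{projection_stack}.
#' @param f Measured \code{projection_stack}.
#' @param u Current \code{ct_volume} iterate.
#' @param geom A \code{scan_geometry}.
#' @param chunk_budget Optional chunk budget (bytes).
#' @return Updated \code{projection_stack}.
#' @export
bregman_update_data <- function(fk, f, u, geom, chunk_budget = NULL) {
  au <- forward_project(u, geom, chunk_budget)
  # grouped so that Au == f is a bitwise-exact fixed point
  projection_stack(geom, fk$values + (f$values - au$values))
}

#' Bregman update of a TV split variable
#'
#' \code{b^{k+1} = b^k + grad(u^{k+1}) - d^{k+1}} for one axis.
#'
#' @param b Current Bregman variable (array).
#' @param u Current iterate values (array).
#' @param d Current split gradient surrogate (array).
#' @param axis TV axis tag.
#' @return Updated array.
#' @export
bregman_update_b <- function(b, u, d, axis) {
  # grouped so that d == grad(u) is a bitwise-exact fixed point
  b + (grad_axis(u, axis) - d)
}

#' Split Bregman TV reconstruction
#'
#' Outer loop: per iteration (1) solve \code{K u = rhs} with BiCGStab;
#' (2) project onto the constraints (clip to \code{u >= 0}; zero outside the
#' cylindrical field of view when masking is enabled); (3) shrink
#' \code{grad(u) + b} per axis; (4) Bregman updates of b and of the
#' augmented data f^k. Stops after \code{outer_iterations} or at the first
#' iteration whose relative change of u falls below
#' \code{stop_rel_change}.
#'
#' @param data A \code{projection_stack} of measured line integrals.
#' @param grid Target \code{volume_grid}.
#' @param params A \code{recon_params}.
#' @param reference Optional \code{ct_volume}; when given, the per-iteration
#'   RMSE against it is recorded in the trace.
#' @param warm_start Optional: \code{"fdk"} initializes u from the FDK
#'   baseline instead of zero.
#' @return List with \code{volume} (the reconstruction) and \code{trace},
#'   a data frame with one row per completed outer iteration: data residual
#'   \code{||Au - f||_2}, relative change of u, inner-solver iterations, and
#'   RMSE versus the reference if supplied.
#' @export
reconstruct_tv <- function(data, grid, params = recon_params(),
                           reference = NULL, warm_start = c("zero", "fdk")) {
  warm_start <- match.arg(warm_start)
  stopifnot(inherits(data, "projection_stack"), inherits(grid, "volume_grid"),
            inherits(params, "recon_params"))
  if (!all(is.finite(data$values))) stop("non-finite projection data", call. = FALSE)
  geom <- data$geometry
  dims <- c(grid$nx, grid$ny, grid$nz)
  zero <- array(0, dims)
  axes <- params$tv_axes
  mask <- if (params$apply_fov_mask) fov_mask(grid)$values else NULL

  u <- if (warm_start == "fdk") pmax(reconstruct_fdk(data, grid)$values, 0)
       else zero
  if (!is.null(mask) && warm_start == "fdk") u <- u * mask
  d <- b <- stats::setNames(rep(list(zero), length(axes)), axes)
  fk <- data
  thresh <- params$alpha / params$lam

  trace <- vector("list", params$outer_iterations)
  nf <- sqrt(sum(data$values^2))
  for (k in seq_len(params$outer_iterations)) {
    rhs <- compute_rhs(fk, d, b, grid, params)
    op <- function(v) {
      as.vector(apply_K(ct_volume(grid, array(v, dims)), geom, params)$values)
    }
    sol <- bicgstab(op, as.vector(rhs$values), x0 = as.vector(u),
                    tol = params$krylov_tol, max_iter = params$krylov_max)
    u_new <- array(sol$x, dims)
    # constraint projection: u >= 0, u in Omega
    u_new <- pmax(u_new, 0)
    if (!is.null(mask)) u_new <- u_new * mask

    s <- stats::setNames(lapply(axes, function(a) grad_axis(u_new, a) + b[[a]]),
                         axes)
    d <- shrink(s, thresh)
    for (a in axes) b[[a]] <- bregman_update_b(b[[a]], u_new, d[[a]], a)
    au <- forward_project(ct_volume(grid, u_new), geom, params$chunk_budget)
    fk <- projection_stack(geom, fk$values + (data$values - au$values))
    resid <- sqrt(sum((au$values - data$values)^2))
    denom <- sqrt(sum(u_new^2))
    rel_change <- if (denom > 0) sqrt(sum((u_new - u)^2)) / denom else Inf
    rec <- data.frame(iteration = k, residual = resid,
                      rel_residual = if (nf > 0) resid / nf else NA_real_,
                      rel_change = rel_change,
                      krylov_iterations = sol$report$iterations)
    if (!is.null(reference))
      rec$rmse <- rmse(ct_volume(grid, u_new), reference)
    trace[[k]] <- rec
    u <- u_new
    if (rel_change < params$stop_rel_change) break
  }
  list(volume = ct_volume(grid, u), trace = do.call(rbind, trace))
}
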