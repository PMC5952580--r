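#' Matrix-free BiCGStab
#'
#' Biconjugate gradient stabilized solver for \code{K x = rhs} where K is
#' available only as a linear callback. Used for the inner L2 sub-problem of
#' the Split Bregman outer loop, where K is applied through forward
#' projection, backprojection and gradient operators.
#'
#' On a (near-)breakdown of the recurrence the solver restarts once from the
#' current iterate; if it breaks down again it returns the current iterate
#' flagged as non-converged.
#'
#' @param apply_op Function mapping a numeric vector to a numeric vector of
#'   the same length; must be linear.
#' @param rhs Right-hand side vector.
#' @param x0 Initial guess (defaults to zero).
#' @param tol Relative residual tolerance, \code{||rhs - K x|| <= tol * ||rhs||}.
#' @param max_iter Maximum iterations.
#' @return List with \code{x} (solution) and \code{report}, a
#'   \code{krylov_report} holding \code{iterations},
#'   \code{final_relative_residual} and \code{converged}.
#' @export
bicgstab <- function(apply_op, rhs, x0 = NULL, tol = 1e-4, max_iter = 30L) {
  stopifnot(is.function(apply_op), tol > 0, max_iter >= 1)
  rhs <- as.numeric(rhs)
  n <- length(rhs)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  nrm_b <- sqrt(sum(rhs^2))
  report <- function(it, rr, conv) structure(
    list(iterations = it, final_relative_residual = rr, converged = conv),
    class = "krylov_report")
  if (nrm_b == 0)
    return(list(x = numeric(n), report = report(0L, 0, TRUE)))

  op <- function(v) {
    out <- apply_op(v)
    if (anyNA(out) || !all(is.finite(out)))
      stop("operator returned non-finite values", call. = FALSE)
    as.numeric(out)
  }

  restarted <- FALSE
  it <- 0L
  repeat {
    r <- rhs - op(x)
    rr <- sqrt(sum(r^2)) / nrm_b
    if (rr <= tol) return(list(x = x, report = report(it, rr, TRUE)))
    r0 <- r
    rho <- alpha <- omega <- 1
    v <- p <- numeric(n)
    broke <- FALSE
    while (it < max_iter) {
      rho1 <- sum(r0 * r)
      if (abs(rho1) < 1e-300) { broke <- TRUE; break }
      beta <- (rho1 / rho) * (alpha / omega)
      rho <- rho1
      p <- r + beta * (p - omega * v)
      v <- op(p)
      den <- sum(r0 * v)
      if (abs(den) < 1e-300) { broke <- TRUE; break }
      alpha <- rho / den
      s <- r - alpha * v
      it <- it + 1L
      if (sqrt(sum(s^2)) / nrm_b <= tol) {
        x <- x + alpha * p
        return(list(x = x, report = report(it, sqrt(sum(s^2)) / nrm_b, TRUE)))
      }
      t <- op(s)
      tt <- sum(t * t)
      if (tt < 1e-300) { x <- x + alpha * p; broke <- TRUE; break }
      omega <- sum(t * s) / tt
      x <- x + alpha * p + omega * s
      r <- s - omega * t
      rr <- sqrt(sum(r^2)) / nrm_b
      if (rr <= tol) return(list(x = x, report = report(it, rr, TRUE)))
    }
    if (broke && !restarted) { restarted <- TRUE; next }
    r <- rhs - op(x)
    rr <- sqrt(sum(r^2)) / nrm_b
    return(list(x = x, report = report(it, rr, rr <= tol)))
  }
}

#' @export
print.krylov_report <- function(x, ...) {
  cat(sprintf("<krylov_report> %d iterations, rel. residual %.3e, %s\n",
              x$iterations, x$final_relative_residual,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
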