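#' Rigid point-cloud registration by iterative closest point
#'
#' Point-to-point ICP aligning `moving` onto `fixed`: nearest-neighbour
#' correspondences, a Kabsch (SVD) rigid update, iterated from an identity
#' initialisation until the RMS residual changes by less than `tol` mm or
#' `max_iter` is reached. Used to bring the pre-operative shaft into the
#' post-operative coordinate system via the intact proximal shaft, so both
#' stages can be evaluated in one frame.
#'
#' @param moving n x 3 matrix (n >= 10) to be transformed.
#' @param fixed m x 3 matrix (m >= 10) held fixed; must overlap `moving`.
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence threshold on the change in RMS residual, mm.
#' @return a [rigid_transform()] mapping moving -> fixed, with attributes
#'   `rms` (final RMS nearest-neighbour distance, mm), `iterations`, and
#'   `converged` (FALSE flags non-convergence within `max_iter`).
#' @export
register_rigid <- function(moving, fixed, max_iter = 200, tol = 1e-6) {
  m <- as_points(moving, "moving")
  f <- as_points(fixed, "fixed")
  if (nrow(m) < 10L || nrow(f) < 10L)
    stop("both clouds need at least 10 points")

  f_sq <- rowSums(f^2)
  nearest <- function(pts) {
    # argmin_j |p_i - f_j|^2 = argmin_j (|f_j|^2 - 2 p_i . f_j)
    d <- matrix(f_sq, nrow(pts), nrow(f), byrow = TRUE) - 2 * pts %*% t(f)
    j <- max.col(-d, ties.method = "first")
    list(idx = j, d2 = d[cbind(seq_len(nrow(pts)), j)] + rowSums(pts^2))
  }

  R <- diag(3)
  tr <- c(0, 0, 0)
  cur <- m
  rms_prev <- Inf
  rms <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    nn <- nearest(cur)
    tgt <- f[nn$idx, , drop = FALSE]
    rms <- sqrt(mean(pmax(nn$d2, 0)))
    if (abs(rms_prev - rms) < tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    # Kabsch on current correspondences
    cm <- colMeans(cur)
    ct <- colMeans(tgt)
    H <- crossprod(sweep(cur, 2L, cm), sweep(tgt, 2L, ct))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    Rk <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    tk <- ct - drop(Rk %*% cm)
    cur <- sweep(cur %*% t(Rk), 2L, tk, "+")
    R <- Rk %*% R
    tr <- drop(Rk %*% tr) + tk
  }
  out <- rigid_transform(R, tr)
  attr(out, "rms") <- rms
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  if (!converged)
    warning("ICP did not converge within ", max_iter,
            " iterations (final rms ", format(rms), " mm)")
  out
}
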