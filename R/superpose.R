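#' Least-squares rigid-body superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimizing the RMSD between
#' two paired point sets, via SVD of the cross-covariance matrix with the
#' reflection branch excluded (determinant forced to +1).
#'
#' @param moving n x 3 matrix of points to move (e.g. model coordinates).
#' @param fixed n x 3 matrix of reference points, same row order.
#' @return List of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), centers of both sets, and `rmsd` of the fit.
#'   A fitted point is `rotation %*% (p - center_moving) + center_fixed +
#'   translation` (translation is zero here; kept for generality).
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)) || ncol(moving) != 3) {
    abort("superpose() needs two n x 3 matrices of equal size")
  }
  n <- nrow(moving)
  if (n < 3) abort("superpose() needs at least 3 points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  M <- sweep(moving, 2, cm); F <- sweep(fixed, 2, cf)
  # degenerate (collinear) sets have rank < 2 cross-covariance
  if (svd(F)$d[2] < 1e-8 && svd(M)$d[2] < 1e-8) {
    abort("degenerate (collinear) point set; superposition not unique")
  }
  H <- t(M) %*% F
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- M %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - F)^2)))
  structure(list(rotation = R, translation = c(0, 0, 0),
                 center_moving = cm, center_fixed = cf, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param x n x 3 matrix.
#' @param sp a `superposition`.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(x, sp) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, sp$center_moving) %*% t(sp$rotation), 2,
        sp$center_fixed + sp$translation, FUN = "+")
}

rmsd_pts <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
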