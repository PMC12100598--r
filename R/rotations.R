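#' Tait-Bryan rotation matrix
#'
#' Composes the rotation \eqn{A(\alpha,\beta,\gamma) =
#' A_x(\alpha) A_y(\beta) A_z(\gamma)} from the three Tait-Bryan angles about
#' the x, y and z axes. This is the convention used throughout the package to
#' store subunit orientations: a subunit's body-frame coordinates `v` are
#' mapped to the laboratory frame as `A %*% v + center`.
#'
#' @param alpha,beta,gamma rotation angles about the x, y and z axes, degrees.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' tait_bryan_matrix(0, 0, 0)        # identity
#' tait_bryan_matrix(180, 0, 0)      # diag(1, -1, -1)
#' @export
tait_bryan_matrix <- function(alpha, beta, gamma) {
  if (!all(is.finite(c(alpha, beta, gamma)))) {
    stop("tait_bryan_matrix: angles must be finite numbers", call. = FALSE)
  }
  a <- alpha * pi / 180
  b <- beta * pi / 180
  g <- gamma * pi / 180
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  matrix(c(
    cb * cg,                 -cb * sg,                  sb,
    ca * sg + cg * sa * sb,   ca * cg - sa * sb * sg,  -cb * sa,
    sa * sg - ca * cg * sb,   cg * sa + ca * sb * sg,   ca * cb
  ), nrow = 3, byrow = TRUE)
}

#' Recover Tait-Bryan angles from a rotation matrix
#'
#' Inverse of [tait_bryan_matrix()]: factor an orthonormal matrix back into
#' angles (degrees) about x, y, z. beta is returned in \[-90, 90\]; at the
#' gimbal-lock singularity (|sin beta| = 1) gamma is set to 0 and the full
#' x/z rotation is folded into alpha.
#'
#' @param A 3x3 rotation matrix.
#' @return Named numeric vector `c(alpha, beta, gamma)`, degrees.
#' @export
tait_bryan_angles <- function(A) {
  stopifnot(is.matrix(A), all(dim(A) == c(3L, 3L)))
  s <- max(-1, min(1, A[1, 3]))
  if (abs(s) > 1 - 1e-12) {
    # gimbal lock: A reduces to Ax(alpha -/+ gamma) composed with Ay(+/-90)
    beta <- 90 * sign(s)
    alpha <- atan2(A[2, 1], A[2, 2]) * 180 / pi * sign(s)
    gamma <- 0
  } else {
    beta <- asin(s) * 180 / pi
    alpha <- atan2(-A[2, 3], A[3, 3]) * 180 / pi
    gamma <- atan2(-A[1, 2], A[1, 1]) * 180 / pi
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

# Compose an outer rigid transform (rotation R_out, translation t_out) with a
# pose table: new position = R_out %*% p + t_out, new orientation matrix
# R_out %*% A(pose). Returns the transformed pose data frame with angles
# re-extracted in the Tait-Bryan convention.
compose_poses <- function(poses, R_out, t_out) {
  pos <- t(R_out %*% t(as.matrix(poses[, c("x", "y", "z")])))
  pos <- sweep(pos, 2, -as.numeric(t_out))
  out <- poses
  out$x <- pos[, 1]; out$y <- pos[, 2]; out$z <- pos[, 3]
  for (i in seq_len(nrow(poses))) {
    A <- R_out %*% tait_bryan_matrix(poses$alpha[i], poses$beta[i], poses$gamma[i])
    ang <- tait_bryan_angles(A)
    out$alpha[i] <- ang[["alpha"]]
    out$beta[i] <- ang[["beta"]]
    out$gamma[i] <- ang[["gamma"]]
  }
  out
}
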