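#' Arc length of one helical turn
#'
#' Length of a single turn of a circular helix of radius `r` and vertical
#' pitch `p`, measured along the line connecting the dimer centers:
#' \eqn{L_{turn} = \sqrt{4\pi^2 r^2 + p^2}}.
#'
#' @param r helix radius to the dimer center of mass, nm.
#' @param p vertical pitch (rise per turn), nm.
#' @return Turn length, nm.
#' @export
turn_length <- function(r, p) {
  stopifnot(is.finite(r), is.finite(p), r >= 0, p >= 0)
  if (r == 0 && p == 0) {
    stop("turn_length: degenerate geometry, r and p cannot both be zero",
         call. = FALSE)
  }
  sqrt(4 * pi^2 * r^2 + p^2)
}

#' Build an inverted helical tubule
#'
#' Places tubulin dimers along a single helix of radius `r` and pitch `p` up
#' to total height `h`, one dimer every `L_dim` of arc. Dimer `i` sits at
#' \eqn{(r\cos\theta_i, r\sin\theta_i, i\,p\,L_{dim}/L_{turn})} with azimuth
#' step \eqn{\theta_{dim} = 2\pi L_{dim}/L_{turn}}, the azimuthal advance of
#' an arc step `L_dim` along the helix (this reduces to `L_dim / r` for a
#' flat ring and keeps the builder the exact cylinder limit of the conical
#' spiral builder). The tilt angle
#' \eqn{\alpha_i = 90° - (180/\pi)\arcsin(p/L_{turn})} is constant, the spin
#' \eqn{\beta_i = (180/\pi)\theta_i} follows the azimuth and \eqn{\gamma_i = 0}.
#' The dimer count is \eqn{i_{max} = \lfloor (h/p)(L_{turn}/L_{dim}) + 1 \rfloor}
#' with subunits indexed 0..i_max; for the flat ring limit `p = 0` a single
#' closed ring of `floor(2*pi*r/L_dim)` dimers is produced instead.
#'
#' The tubules are "inverted" relative to microtubule geometry: the surface
#' of the dimer that faces the microtubule lumen faces outward. The builder
#' encodes left-handed chirality by advancing the azimuth in the positive
#' mathematical sense combined with the printed alpha formula; setting
#' `handedness = "right"` mirrors the y coordinates (and flips beta's sign).
#'
#' @param r helix radius to dimer centers, nm (> 0).
#' @param p vertical pitch per turn, nm (>= 0; 0 gives a flat ring).
#' @param h total height of the tubule, nm (> 0; ignored when `p = 0`).
#' @param L_dim dimer length, nm (> 0).
#' @param T_dim dimer thickness, nm (> 0); carried in the parameter record
#'   for non-penetration checks in bundle building.
#' @param handedness `"left"` (default) or `"right"`.
#' @return An `assembly` of kind `"helical_tubule"`. Its `derived` element
#'   holds `L_turn` (nm), `theta_dim` (rad), `i_max`, and `theta_i` (rad).
#' @export
build_inverted_helical_tubule <- function(r, p, h, L_dim, T_dim = 5,
                                          handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  stopifnot(r > 0, p >= 0, L_dim > 0, T_dim > 0)
  if (L_dim > 2 * pi * r) {
    stop("build_inverted_helical_tubule: dimer length ", L_dim,
         " nm exceeds the helix circumference ", round(2 * pi * r, 3),
         " nm", call. = FALSE)
  }
  L_turn <- turn_length(r, p)
  theta_dim <- 2 * pi * L_dim / L_turn
  if (p == 0) {
    # flat ring: one full turn, closed when 2*pi*r is a multiple of L_dim
    i_max <- floor(2 * pi * r / L_dim + 1e-9) - 1L
    if (i_max < 0) i_max <- 0L
  } else {
    stopifnot(h > 0)
    i_max <- floor((h / p) * (L_turn / L_dim) + 1)
  }
  i <- 0:i_max
  theta_i <- (i * theta_dim) %% (2 * pi)
  x <- r * cos(theta_i)
  y <- r * sin(theta_i)
  z <- i * p * L_dim / L_turn
  alpha <- 90 - (180 / pi) * asin(p / L_turn)
  beta <- (180 / pi) * theta_i
  poses <- data.frame(x = x, y = y, z = z,
                      alpha = alpha, beta = beta, gamma = 0)
  if (handedness == "right") {
    poses$y <- -poses$y
    poses$beta <- -poses$beta
  }
  assembly(poses, kind = "helical_tubule",
           spec = list(r = r, p = p, h = h, L_dim = L_dim, T_dim = T_dim,
                       handedness = handedness),
           derived = list(L_turn = L_turn, theta_dim = theta_dim,
                          i_max = i_max, theta_i = theta_i))
}
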