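#' Arc length along a conical spiral
#'
#' Total arc length from the start (t = 0) to azimuthal parameter `t` along
#' the conical helix `((R_max - C t) cos t, (R_max - C t) sin t, A t)`, where
#' `C` is the radius decrease per radian and `A = p / (2 pi)` the vertical
#' rise per radian. The integrand is
#' \eqn{\sqrt{(Ct - R_{max})^2 + C^2 + A^2}}; for `C > 0` the closed form
#' \deqn{S(t) = \frac{1}{2C}\left[(C^2+A^2)\,\mathrm{asinh}\frac{u}{\sqrt{C^2+A^2}}
#'   + u\sqrt{u^2 + C^2 + A^2}\right]_{u=-R_{max}}^{u=Ct-R_{max}}}
#' is used; `C = 0` is the removable circular-helix limit
#' `t * sqrt(R_max^2 + A^2)`.
#'
#' @param t azimuthal parameter, radians (>= 0); vectorized.
#' @param R_max starting (maximal) radius, nm.
#' @param C radius decrease per radian, nm/rad (>= 0).
#' @param A vertical rise per radian, nm/rad.
#' @return Arc length(s), nm.
#' @export
conical_arc_length <- function(t, R_max, C, A) {
  stopifnot(is.finite(R_max), is.finite(C), is.finite(A), C >= 0, R_max > 0)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("conical_arc_length: t must be finite and >= 0", call. = FALSE)
  }
  .cone_arc_between(0, t, R_max, C, A)
}

# arc length between parameters t0 and t1 (t1 >= t0), evaluated without the
# catastrophic cancellation of differencing the raw antiderivative: the
# asinh difference goes through log1p and the u*sqrt(u^2+k^2) difference is
# factored so the exact increment C*(t1 - t0) appears explicitly
.cone_arc_between <- function(t0, t1, R_max, C, A) {
  if (C == 0) {
    return((t1 - t0) * sqrt(R_max^2 + A^2))
  }
  k2 <- C^2 + A^2
  k <- sqrt(k2)
  u0 <- C * t0 - R_max
  u1 <- C * t1 - R_max
  a <- u1 / k
  b <- u0 / k
  sa <- sqrt(a^2 + 1)
  sb <- sqrt(b^2 + 1)
  if (any(a > 0)) {
    # past the cone apex extrapolation; plain antiderivative difference
    dasinh <- asinh(a) - asinh(b)
  } else {
    dasinh <- log1p((a - b) * (1 - (a + b) / (sa + sb)) / (sa - a))
  }
  dprod <- C * (t1 - t0) * (u1 + u0) * (u1^2 + u0^2 + k2) /
    (u1 * k * sa + u0 * k * sb)
  (k2 * dasinh + dprod) / (2 * C)
}

# d(arc length)/dt, used for Newton polishing in the angle solver
.cone_arc_speed <- function(t, R_max, C, A) {
  sqrt((C * t - R_max)^2 + C^2 + A^2)
}

#' Place dimers along a conical spiral at equal arc spacing
#'
#' Finds the azimuthal parameters `t_i` in `[0, 2 pi n]` at which successive
#' dimer centers sit, such that each arc increment
#' `S(t_i) - S(t_{i-1})` equals the dimer length `L_dim`. `t_0 = 0`; each
#' subsequent `t_i` is located by a bracketed binary search (bracket
#' `[t_{i-1}, t_{i-1} + 2 L_dim / r_local]`, doubled while needed) followed by
#' a Newton polish on the closed-form arc length. The number of dimers equals
#' `floor(S(2 pi n) / L_dim) + 1`.
#'
#' The default arc-length tolerance of 1e-14 nm sits at the resolution of
#' double precision; the solver evaluates each increment with a
#' cancellation-free form of the closed-form arc length and accepts a step
#' once the residual is below `max(tol, 8 eps L_dim)`, i.e. it never demands
#' better than machine-representable agreement.
#'
#' @param R_max,R_min maximal and minimal radii to dimer centers, nm.
#' @param p pitch per helical turn, nm.
#' @param n number of helical turns in one conical spiral (>= 1).
#' @param L_dim dimer length, nm.
#' @param tol arc-length convergence tolerance, nm.
#' @param max_iter bisection iteration cap per dimer.
#' @return List of class `cone_derived`: `C` and `A` (nm/rad), `theta_cone`
#'   = NA until `V_h` is known, `t_i` (rad, increasing from 0), `dt_i`
#'   (increments, last one repeated), `S_total` (nm), `residuals` (nm).
#' @export
solve_dimer_angles <- function(R_max, R_min, p, n, L_dim,
                               tol = 1e-14, max_iter = 200L) {
  stopifnot(R_max >= R_min, R_min > 0, p >= 0, n >= 1, L_dim > 0, tol > 0)
  C <- (R_max - R_min) / (2 * pi * n)
  A <- p / (2 * pi)
  t_end <- 2 * pi * n
  S <- function(t) conical_arc_length(t, R_max, C, A)
  S_total <- S(t_end)
  if (L_dim >= S(2 * pi)) {
    stop("solve_dimer_angles: L_dim exceeds the arc length of one turn",
         call. = FALSE)
  }
  n_dimers <- floor(S_total / L_dim) + 1L
  t_i <- numeric(n_dimers)
  resid <- numeric(n_dimers)
  eps <- .Machine$double.eps
  for (i in seq_len(n_dimers - 1L)) {
    t_prev <- t_i[i]
    g <- function(t) .cone_arc_between(t_prev, t, R_max, C, A) - L_dim
    r_local <- max(R_max - C * t_prev, R_min)
    lo <- t_prev
    hi <- min(t_prev + 2 * L_dim / r_local, t_end)
    while (g(hi) < 0 && hi < t_end) {
      hi <- min(t_prev + 2 * (hi - t_prev), t_end)
    }
    # residual floor grows with the arc travelled: the increment is
    # evaluated from t_prev, whose own rounding carries eps * S_prev
    accept <- max(tol, 8 * eps * L_dim * (i + 1))
    it <- 0L
    mid <- 0.5 * (lo + hi)
    repeat {
      it <- it + 1L
      mid <- 0.5 * (lo + hi)
      gm <- g(mid)
      if (abs(gm) <= tol) break
      if (gm > 0) hi <- mid else lo <- mid
      if (hi - lo <= eps * max(1, hi)) break
      if (it >= max_iter) break
    }
    # Newton polish on the analytic speed
    for (k in 1:2) {
      gm <- g(mid)
      if (abs(gm) <= tol) break
      mid <- mid - gm / .cone_arc_speed(mid, R_max, C, A)
      if (mid < lo || mid > t_end) mid <- 0.5 * (lo + hi)
    }
    resid[i + 1L] <- g(mid)
    if (abs(resid[i + 1L]) > accept) {
      stop(sprintf(paste0("solve_dimer_angles: dimer %d did not converge ",
                          "(residual %.3e nm > %.3e nm)"),
                   i, abs(resid[i + 1L]), accept), call. = FALSE)
    }
    t_i[i + 1L] <- mid
  }
  if (n_dimers > 1L) {
    d <- diff(t_i)
    dt_i <- c(d, d[length(d)])  # last dimer reuses the previous increment
  } else {
    dt_i <- L_dim / R_max
  }
  structure(list(C = C, A = A, t_i = t_i, dt_i = dt_i,
                 S_total = S_total, residuals = resid),
            class = "cone_derived")
}

#' Build a conical spiral tubule
#'
#' A conical spiral places dimers along a left-handed conical helix whose
#' radius shrinks linearly from `R_max` to `R_min` over `n` turns with pitch
#' `p` per turn: dimer `i` sits at `((R_max - C t_i) cos t_i,
#' (R_max - C t_i) sin t_i, A t_i)` with the equal-arc-length azimuths `t_i`
#' from [solve_dimer_angles()]. Orientations are
#' \eqn{\alpha_i = 90° - (180/\pi)\arcsin(p\,\Delta t_i / (2\pi L_{dim}))},
#' \eqn{\beta_i = (180/\pi) t_i}, \eqn{\gamma_i = 0}. The spiral is then
#' stacked `N_spirals` times along z with vertical repeat `V_h`, and the whole
#' tubule is shifted by `-z_max/2` so it is centered on the origin.
#'
#' @inheritParams solve_dimer_angles
#' @param V_h vertical distance between successive conical spirals, nm (> 0).
#' @param N_spirals number of conical repeats per tubule (>= 1).
#' @param T_dim dimer thickness, nm (metadata for bundle non-penetration).
#' @param handedness `"left"` (default) or `"right"` (mirrors y).
#' @return An `assembly` of kind `"conical_spiral_tubule"`; `derived` holds
#'   the `cone_derived` record plus `theta_cone` (degrees).
#' @export
build_conical_spiral_tubule <- function(R_max, R_min, p, n, V_h,
                                        N_spirals = 1L, L_dim = 8, T_dim = 5,
                                        tol = 1e-14,
                                        handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  stopifnot(V_h > 0, N_spirals >= 1)
  der <- solve_dimer_angles(R_max, R_min, p, n, L_dim, tol = tol)
  t_i <- der$t_i
  radius <- R_max - der$C * t_i
  arg <- der$A * der$dt_i / L_dim
  arg <- pmax(-1, pmin(1, arg))
  alpha <- 90 - (180 / pi) * asin(arg)
  beta <- (180 / pi) * t_i
  one <- data.frame(x = radius * cos(t_i), y = radius * sin(t_i),
                    z = der$A * t_i, alpha = alpha, beta = beta, gamma = 0)
  reps <- lapply(seq_len(N_spirals) - 1L, function(k) {
    cp <- one
    cp$z <- cp$z + k * V_h
    cp
  })
  poses <- do.call(rbind, reps)
  z_max <- max(poses$z)
  poses$z <- poses$z - z_max / 2
  if (handedness == "right") {
    poses$y <- -poses$y
    poses$beta <- -poses$beta
  }
  der$theta_cone <- cone_angle(R_max, R_min, V_h)
  assembly(poses, kind = "conical_spiral_tubule",
           spec = list(R_max = R_max, R_min = R_min, p = p, n = n, V_h = V_h,
                       N_spirals = N_spirals, L_dim = L_dim, T_dim = T_dim,
                       handedness = handedness),
           derived = der)
}

#' Opening angle of a conical spiral
#'
#' The cone angle formed by the spiral envelope,
#' \eqn{\theta = \arctan((R_{max} - R_{min}) / V_h)}, where `V_h` is the
#' vertical repeat between successive conical spirals.
#'
#' @param R_max,R_min maximal and minimal spiral radii, nm (`R_max >= R_min`).
#' @param V_h vertical repeat distance, nm (> 0).
#' @return Cone angle, degrees.
#' @examples
#' cone_angle(12, 12, 8)   # cylinder: 0 degrees
#' cone_angle(16, 8, 8)    # unit slope: 45 degrees
#' @export
cone_angle <- function(R_max, R_min, V_h) {
  if (!is.finite(V_h) || V_h <= 0) {
    stop("cone_angle: V_h must be positive", call. = FALSE)
  }
  stopifnot(R_max >= R_min)
  atan((R_max - R_min) / V_h) * 180 / pi
}
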