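#' Center-to-center distances between parallel tubules in an oblique lattice
#'
#' Law-of-cosines distances across the two diagonals of an oblique lattice
#' cell with side `a` and angle `gamma_obl`:
#' \eqn{b_1 = \sqrt{2a^2(1 - \cos\gamma)}} and
#' \eqn{b_2 = \sqrt{2a^2(1 - \cos(180° - \gamma))}}. At the oblique bundle
#' angle of 105 degrees these evaluate to 1.59a and 1.22a.
#'
#' @param a lattice constant (center-to-center distance between neighboring
#'   tubules), nm.
#' @param gamma_obl angle between the lattice vectors, degrees (0 < gamma <
#'   180). Default 105.
#' @return Named numeric vector `c(b1, b2)`, nm.
#' @examples
#' lattice_distances(1, 105)   # c(b1 = 1.59, b2 = 1.22) to 2 decimals
#' lattice_distances(1, 120)   # sqrt(3) and 1
#' @export
lattice_distances <- function(a, gamma_obl = 105) {
  stopifnot(a > 0, gamma_obl > 0, gamma_obl < 180)
  g <- gamma_obl * pi / 180
  c(b1 = sqrt(2 * a^2 * (1 - cos(g))),
    b2 = sqrt(2 * a^2 * (1 - cos(pi - g))))
}

#' Replicate a tubule on a 2-D bundle lattice
#'
#' Builds a bundle by placing copies of `unit` at the lattice sites
#' \eqn{\vec R_n = n_1 \vec a_1 + n_2 \vec a_2} with
#' \eqn{\vec a_1 = a(1, 0)} and
#' \eqn{\vec a_2 = a(\cos\gamma, \sin\gamma)}.
#'
#' In `"hexagonal"` mode (gamma = 120 degrees) indices run over
#' `-n_max..n_max` in both directions and only sites inside the disc
#' \eqn{\|\vec R_n\| \le} `disc_cutoff` (default `a * n_max`, boundary ties
#' included) are kept; all copies are parallel translations of the unit.
#'
#' In `"oblique_antiparallel"` mode (gamma = 105 degrees) the lattice
#' decomposes into two interleaved parallel sublattices, the even and odd
#' parity classes of `n1 + n2` (equivalently: one parallel lattice with
#' vectors `2 a_1` and `a_2 - a_1`, plus its copy shifted by `(a, 0)`). The
#' odd class is flipped antiparallel by an outer rotation of 180 degrees
#' about x, and every off-center copy additionally receives the alignment
#' correction \eqn{\gamma_n = \mathrm{atan2}(R_{n,y}, R_{n,x})} (degrees)
#' about z. In a 3x3 patch the central tubule is surrounded by four
#' antiparallel neighbors at distance `a` and two parallel neighbors at
#' `b2 = 1.22a`.
#'
#' Non-penetration is enforced when the unit's spec carries the needed
#' radii: hexagonal bundles require `a >= 2 r + T_dim`, oblique bundles
#' `a >= R_max + R_min + T_dim`.
#'
#' @param unit an `assembly`, the tubule to replicate.
#' @param a lattice constant, nm.
#' @param mode `"hexagonal"` or `"oblique_antiparallel"`.
#' @param n1_range,n2_range integer index vectors for the two lattice
#'   directions. Hexagonal default `-1:1`; oblique default `0:2` (a 3x3
#'   patch).
#' @param disc_cutoff hexagonal-mode norm bound on kept sites, nm; default
#'   `a * max(abs(c(n1_range, n2_range)))`. Ignored in oblique mode.
#' @param gamma_lattice lattice angle, degrees; defaults 120 (hexagonal) or
#'   105 (oblique).
#' @return An `assembly` of kind `"bundle"`; `derived$sites` records the kept
#'   lattice sites and each copy's parity flip.
#' @export
build_bundle <- function(unit, a, mode = c("hexagonal", "oblique_antiparallel"),
                         n1_range = NULL, n2_range = NULL, disc_cutoff = NULL,
                         gamma_lattice = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(unit, "assembly"), a > 0)
  if (is.null(gamma_lattice)) {
    gamma_lattice <- if (mode == "hexagonal") 120 else 105
  }
  if (is.null(n1_range)) n1_range <- if (mode == "hexagonal") -1:1 else 0:2
  if (is.null(n2_range)) n2_range <- if (mode == "hexagonal") -1:1 else 0:2
  .check_penetration(unit, a, mode)
  g <- gamma_lattice * pi / 180
  a1 <- a * c(1, 0)
  a2 <- a * c(cos(g), sin(g))
  grid <- expand.grid(n1 = as.integer(n1_range), n2 = as.integer(n2_range))
  Rn <- cbind(grid$n1 * a1[1] + grid$n2 * a2[1],
              grid$n1 * a1[2] + grid$n2 * a2[2])
  if (mode == "hexagonal") {
    if (is.null(disc_cutoff)) disc_cutoff <- a * max(abs(c(n1_range, n2_range)))
    keep <- sqrt(rowSums(Rn^2)) <= disc_cutoff + 1e-9 * a
    if (!any(keep)) stop("build_bundle: no lattice site within disc_cutoff",
                         call. = FALSE)
    grid <- grid[keep, , drop = FALSE]
    Rn <- Rn[keep, , drop = FALSE]
    flip <- rep(FALSE, nrow(grid))
  } else {
    flip <- (grid$n1 + grid$n2) %% 2L == 1L
  }
  copies <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    if (mode == "hexagonal") {
      cp <- unit$poses
      cp$x <- cp$x + Rn[k, 1]
      cp$y <- cp$y + Rn[k, 2]
    } else {
      alpha_n <- if (flip[k]) 180 else 0
      gamma_n <- if (all(Rn[k, ] == 0)) 0 else
        atan2(Rn[k, 2], Rn[k, 1]) * 180 / pi
      R_out <- tait_bryan_matrix(alpha_n, 0, gamma_n)
      cp <- compose_poses(unit$poses, R_out, c(Rn[k, ], 0))
    }
    copies[[k]] <- cp
  }
  sites <- data.frame(n1 = grid$n1, n2 = grid$n2,
                      x = Rn[, 1], y = Rn[, 2], antiparallel = flip)
  assembly(do.call(rbind, copies), kind = "bundle",
           spec = c(list(a = a, mode = mode, gamma_lattice = gamma_lattice,
                         n_tubules = nrow(grid)),
                    list(unit_spec = unit$spec, unit_kind = unit$kind)),
           derived = list(sites = sites, unit_n = n_subunits(unit)))
}

.check_penetration <- function(unit, a, mode) {
  sp <- unit$spec
  T_dim <- sp$T_dim
  if (is.null(T_dim)) return(invisible(TRUE))
  if (mode == "hexagonal" && !is.null(sp$r)) {
    bound <- 2 * sp$r + T_dim
    if (a < bound - 1e-9) {
      stop(sprintf(paste0("build_bundle: lattice constant a = %.3f nm violates",
                          " the non-penetration bound a >= 2 r + T_dim = %.3f nm"),
                   a, bound), call. = FALSE)
    }
  }
  if (mode == "oblique_antiparallel" && !is.null(sp$R_max) &&
      !is.null(sp$R_min)) {
    bound <- sp$R_max + sp$R_min + T_dim
    if (a < bound - 1e-9) {
      stop(sprintf(paste0("build_bundle: lattice constant a = %.3f nm violates",
                          " the non-penetration bound a >= R_max + R_min +",
                          " T_dim = %.3f nm"), a, bound), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build a simple microtubule cylinder lattice
#'
#' `N_p` straight protofilaments equally spaced on a cylinder of radius `r`,
#' each a vertical stack of dimers with the given axial rise. Subunit `beta`
#' angles follow the protofilament azimuth. This is a geometric stand-in for
#' the ~25 nm microtubule: no lattice seam or helical rise is modeled.
#'
#' @param N_p protofilament count (>= 2); 13 is the canonical in-vivo number.
#' @param r cylinder radius to dimer centers, nm.
#' @param h microtubule length, nm (>= 0; `h = 0` gives one dimer layer).
#' @param axial_rise axial spacing between dimer centers along one
#'   protofilament, nm (the ~8 nm dimer repeat).
#' @return An `assembly` of kind `"microtubule"`.
#' @export
build_microtubule <- function(N_p = 13L, r = 11.2, h = 0, axial_rise = 8) {
  if (!is.finite(N_p) || N_p < 2) {
    stop("build_microtubule: N_p must be at least 2", call. = FALSE)
  }
  stopifnot(r > 0, h >= 0, axial_rise > 0)
  N_p <- as.integer(N_p)
  n_layers <- floor(h / axial_rise) + 1L
  phi <- 2 * pi * (seq_len(N_p) - 1L) / N_p
  grid <- expand.grid(k = seq_len(N_p), j = seq_len(n_layers) - 1L)
  poses <- data.frame(
    x = r * cos(phi[grid$k]),
    y = r * sin(phi[grid$k]),
    z = grid$j * axial_rise,
    alpha = 0,
    beta = phi[grid$k] * 180 / pi,
    gamma = 0
  )
  poses$z <- poses$z - max(poses$z) / 2
  assembly(poses, kind = "microtubule",
           spec = list(N_p = N_p, r = r, h = h, axial_rise = axial_rise))
}
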