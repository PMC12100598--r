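#' Sphere scattering amplitude
#'
#' Normalized form-factor amplitude of a homogeneous sphere,
#' \eqn{\phi(qR) = 3(\sin qR - qR\cos qR)/(qR)^3}, which tends to 1 as
#' `q -> 0`. Each bead in a Debye sum scatters with amplitude
#' `contrast * sphere_form_factor(q, radius)`.
#'
#' @param q scattering vector magnitude(s), 1/nm.
#' @param R sphere radius, nm.
#' @return Amplitude(s), dimensionless.
#' @export
sphere_form_factor <- function(q, R) {
  stopifnot(R > 0, all(q >= 0))
  x <- q * R
  out <- ifelse(x < 1e-4, 1 - x^2 / 10,
                3 * (sin(x) - x * cos(x)) / pmax(x, 1e-300)^3)
  as.numeric(out)
}

#' Debye-equation scattering intensity of a bead model
#'
#' Orientationally averaged solution scattering intensity
#' \deqn{I(q) = \sum_i \sum_j f_i(q) f_j(q) \frac{\sin q r_{ij}}{q r_{ij}}}
#' with per-bead amplitudes `f_i(q) = contrast_i * sphere_form_factor(q,
#' radius_i)`. The sum is exact up to `exact_limit` beads; larger models use
#' a weighted pair-distance histogram with bin width `bin_width` (nm), which
#' is accurate to the phase resolution `q * bin_width / 2`.
#'
#' `I(0)` equals the squared total excess electrons of the model; intensities
#' are in (excess electrons)^2, i.e. arbitrary units relative to measured
#' absolute scale.
#'
#' @param model a `bead_model`.
#' @param q q grid, 1/nm; default [default_q_grid()].
#' @param exact_limit bead count up to which the exact double sum is used.
#' @param bin_width histogram bin width for larger models, nm.
#' @return A `saxs_curve`.
#' @export
debye_intensity <- function(model, q = default_q_grid(), exact_limit = 5000,
                            bin_width = 0.05) {
  stopifnot(inherits(model, "bead_model"))
  b <- model$beads
  if (nrow(b) < 1) stop("debye_intensity: empty bead model", call. = FALSE)
  I <- debye_intensity_cpp(as.matrix(b[, c("x", "y", "z")]), b$contrast,
                           b$radius, q, as.integer(exact_limit), bin_width)
  saxs_curve(q, I)
}

#' Scattering intensity of a whole assembly
#'
#' Applies each pose's Tait-Bryan rotation and translation to the subunit
#' bead model, concatenates all copies and evaluates the Debye sum. With
#' `reduce = "com"` each subunit is collapsed to a single bead at its center
#' of mass carrying the total contrast and the volume-equivalent radius -- a
#' cheap approximation for very large bundles, valid at low q.
#'
#' @param assembly an `assembly`.
#' @param subunit a `bead_model` for one dimer, centered at the origin.
#' @param q q grid, 1/nm.
#' @param reduce `"none"` (default) or `"com"`.
#' @param exact_limit,bin_width passed to [debye_intensity()].
#' @return A `saxs_curve`.
#' @export
assembly_intensity <- function(assembly, subunit, q = default_q_grid(),
                               reduce = c("none", "com"), exact_limit = 5000,
                               bin_width = 0.05) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(assembly, "assembly"), inherits(subunit, "bead_model"))
  b <- subunit$beads
  if (reduce == "com") {
    wts <- abs(b$contrast)
    vol <- sum(4 / 3 * pi * b$radius^3)
    b <- data.frame(x = weighted.mean(b$x, wts), y = weighted.mean(b$y, wts),
                    z = weighted.mean(b$z, wts),
                    radius = (3 * vol / (4 * pi))^(1 / 3),
                    contrast = sum(b$contrast))
  }
  all_beads <- place_beads(assembly, b)
  model <- bead_model(all_beads, provenance = subunit$provenance,
                      solvent_density = subunit$solvent_density,
                      shell_density = subunit$shell_density,
                      shell_thickness = subunit$shell_thickness)
  debye_intensity(model, q, exact_limit = exact_limit, bin_width = bin_width)
}

#' Place subunit beads at every pose of an assembly
#'
#' @param assembly an `assembly`.
#' @param beads data frame of subunit beads (`x, y, z, radius, contrast`).
#' @return Data frame of all transformed beads.
#' @export
place_beads <- function(assembly, beads) {
  poses <- assembly$poses
  B <- t(as.matrix(beads[, c("x", "y", "z")]))
  out <- vector("list", nrow(poses))
  for (i in seq_len(nrow(poses))) {
    A <- tait_bryan_matrix(poses$alpha[i], poses$beta[i], poses$gamma[i])
    P <- A %*% B
    out[[i]] <- data.frame(x = P[1, ] + poses$x[i],
                           y = P[2, ] + poses$y[i],
                           z = P[3, ] + poses$z[i],
                           radius = beads$radius,
                           contrast = beads$contrast)
  }
  do.call(rbind, out)
}
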