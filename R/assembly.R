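#' Assembly objects
#'
#' An `assembly` is an ordered collection of subunit poses plus provenance:
#' the parameter record it was built from and the model kind. Each pose is one
#' tubulin dimer's center-of-mass position (x, y, z, nm) and Tait-Bryan
#' orientation (alpha, beta, gamma, degrees).
#'
#' @param poses data frame with columns `x, y, z, alpha, beta, gamma`.
#' @param kind one of `"helical_tubule"`, `"conical_spiral_tubule"`,
#'   `"bundle"`, `"microtubule"`, `"single_dimer"`.
#' @param spec list of the originating parameters.
#' @param derived optional list of derived quantities (turn length, azimuths,
#'   cone coefficients, ...).
#' @return Object of class `assembly`.
#' @export
assembly <- function(poses, kind, spec = list(), derived = list()) {
  kinds <- c("helical_tubule", "conical_spiral_tubule", "bundle",
             "microtubule", "single_dimer")
  kind <- match.arg(kind, kinds)
  poses <- as.data.frame(poses)
  need <- c("x", "y", "z", "alpha", "beta", "gamma")
  if (!all(need %in% names(poses))) {
    stop("assembly: poses must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(poses) == 0) stop("assembly: at least one pose required", call. = FALSE)
  if (!all(vapply(poses[need], function(v) all(is.finite(v)), logical(1)))) {
    stop("assembly: non-finite pose values", call. = FALSE)
  }
  structure(list(poses = poses[, need], kind = kind, spec = spec,
                 derived = derived),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("<assembly>", x$kind, "with", nrow(x$poses), "subunit poses\n")
  zr <- range(x$poses$z)
  rr <- range(sqrt(x$poses$x^2 + x$poses$y^2))
  cat(sprintf("  radial extent %.3f..%.3f nm, z %.3f..%.3f nm\n",
              rr[1], rr[2], zr[1], zr[2]))
  if (length(x$spec)) {
    scal <- x$spec[vapply(x$spec, function(v) is.numeric(v) && length(v) == 1,
                          logical(1))]
    if (length(scal)) {
      cat("  spec:", paste(names(scal), unlist(scal), sep = "=",
                           collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Number of subunits in an assembly
#' @param x an `assembly`.
#' @return Integer pose count.
#' @export
n_subunits <- function(x) {
  stopifnot(inherits(x, "assembly"))
  nrow(x$poses)
}

#' Single-dimer assembly at the origin
#'
#' Convenience builder: one pose at the origin with zero rotation, the
#' free-dimer component used in mixture fits.
#' @return An `assembly` of kind `"single_dimer"`.
#' @export
single_dimer <- function() {
  assembly(data.frame(x = 0, y = 0, z = 0, alpha = 0, beta = 0, gamma = 0),
           kind = "single_dimer")
}
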