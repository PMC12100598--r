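#' SAXS curve container
#'
#' A `saxs_curve` is a data frame with columns `q` (scattering-vector
#' magnitude, 1/nm, strictly increasing), `I` (intensity, arbitrary units)
#' and optionally `sigma` (per-point uncertainty, > 0).
#'
#' @param q scattering vector magnitudes, 1/nm.
#' @param I intensities.
#' @param sigma optional per-point uncertainties.
#' @return Object of classes `saxs_curve` and `data.frame`.
#' @export
saxs_curve <- function(q, I, sigma = NULL) {
  stopifnot(length(q) == length(I), all(is.finite(q)), all(is.finite(I)))
  if (any(q < 0)) stop("saxs_curve: q must be non-negative", call. = FALSE)
  if (is.unsorted(q, strictly = TRUE)) {
    stop("saxs_curve: q must be strictly increasing", call. = FALSE)
  }
  d <- data.frame(q = q, I = I)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q), all(is.finite(sigma)))
    if (any(sigma <= 0)) stop("saxs_curve: sigma must be positive", call. = FALSE)
    d$sigma <- sigma
  }
  class(d) <- c("saxs_curve", "data.frame")
  d
}

#' Default logarithmic q grid
#'
#' 400 log-spaced points over 0.02-3 1/nm, the range over which the tubule
#' models are informative at the coarse-grained level.
#'
#' @param q_min,q_max grid limits, 1/nm.
#' @param n number of points.
#' @return Numeric vector of q values.
#' @export
default_q_grid <- function(q_min = 0.02, q_max = 3, n = 400) {
  stopifnot(q_min > 0, q_max > q_min, n >= 2)
  exp(seq(log(q_min), log(q_max), length.out = n))
}

#' @export
plot.saxs_curve <- function(x, ..., log = "xy") {
  graphics::plot(x$q, x$I, type = "l", log = log,
                 xlab = expression(q ~ (nm^-1)), ylab = "I(q) (a.u.)", ...)
  invisible(x)
}

#' Family of SAXS curves on a shared q grid
#'
#' Holds a matrix of intensities (one row per curve) together with labels
#' (time stamps of a kinetic series, or condition labels such as ligand
#' concentrations) and optional per-point uncertainties.
#'
#' @param q shared q grid, 1/nm.
#' @param I matrix, curves in rows, `ncol(I) == length(q)`.
#' @param labels numeric or character labels, one per curve. Numeric labels
#'   of a kinetic family must be strictly increasing.
#' @param sigma optional uncertainty matrix, same shape as `I`.
#' @param kinetic logical: labels are time stamps.
#' @return Object of class `curve_family`.
#' @export
curve_family <- function(q, I, labels = NULL, sigma = NULL, kinetic = FALSE) {
  I <- as.matrix(I)
  stopifnot(ncol(I) == length(q), all(is.finite(I)))
  if (is.unsorted(q, strictly = TRUE)) {
    stop("curve_family: q must be strictly increasing", call. = FALSE)
  }
  if (is.null(labels)) labels <- seq_len(nrow(I))
  stopifnot(length(labels) == nrow(I))
  if (kinetic) {
    if (!is.numeric(labels) || is.unsorted(labels, strictly = TRUE)) {
      stop("curve_family: kinetic labels must be strictly increasing times",
           call. = FALSE)
    }
  }
  if (!is.null(sigma)) {
    sigma <- as.matrix(sigma)
    stopifnot(all(dim(sigma) == dim(I)), all(sigma > 0))
  }
  structure(list(q = q, I = I, labels = labels, sigma = sigma,
                 kinetic = kinetic),
            class = "curve_family")
}

#' @export
print.curve_family <- function(x, ...) {
  cat("<curve_family>", nrow(x$I), "curves x", length(x$q), "q points,",
      if (x$kinetic) "kinetic" else "static", "\n")
  invisible(x)
}

#' Extract one curve from a family
#' @param family a `curve_family`.
#' @param i curve index.
#' @return A `saxs_curve`.
#' @export
family_curve <- function(family, i) {
  stopifnot(inherits(family, "curve_family"))
  saxs_curve(family$q, family$I[i, ],
             sigma = if (!is.null(family$sigma)) family$sigma[i, ])
}

#' Background (supernatant) subtraction
#'
#' Subtracts a scaled background curve from a sample curve,
#' `I_out = I_sample - scale * I_background`, combining uncertainties in
#' quadrature. The background is linearly interpolated onto the sample's q
#' grid when the grids differ; the grids must overlap the full sample range.
#'
#' @param sample,background `saxs_curve` objects.
#' @param scale background scale factor (default 1).
#' @return A `saxs_curve` on the sample's q grid.
#' @export
subtract_background <- function(sample, background, scale = 1) {
  stopifnot(inherits(sample, "saxs_curve"), inherits(background, "saxs_curve"))
  if (min(background$q) > min(sample$q) + 1e-12 ||
      max(background$q) < max(sample$q) - 1e-12) {
    stop("subtract_background: background q range does not cover the sample",
         call. = FALSE)
  }
  if (identical(background$q, sample$q)) {
    Ib <- background$I
    sb <- background$sigma
  } else {
    Ib <- approx(background$q, background$I, xout = sample$q)$y
    sb <- if (!is.null(background$sigma)) {
      approx(background$q, background$sigma, xout = sample$q)$y
    }
  }
  Iout <- sample$I - scale * Ib
  sig <- NULL
  if (!is.null(sample$sigma) || !is.null(sb)) {
    s1 <- if (is.null(sample$sigma)) 0 else sample$sigma
    s2 <- if (is.null(sb)) 0 else sb
    sig <- sqrt(s1^2 + scale^2 * s2^2)
    if (any(sig <= 0)) sig <- NULL
  }
  d <- data.frame(q = sample$q, I = Iout)
  if (!is.null(sig)) d$sigma <- sig
  class(d) <- c("saxs_curve", "data.frame")
  d
}

#' Read / write 3-column SAXS text files
#'
#' Plain whitespace-delimited text with columns q (1/nm), I and optionally
#' sigma; lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_saxs` returns a `saxs_curve`.
#' @export
read_saxs <- function(path) {
  d <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(d) < 2) stop("read_saxs: expected at least 2 columns", call. = FALSE)
  saxs_curve(d[[1]], d[[2]], sigma = if (ncol(d) >= 3) d[[3]])
}

#' @param curve a `saxs_curve`.
#' @param header optional character vector written as `#` comment lines.
#' @rdname read_saxs
#' @export
write_saxs <- function(curve, path, header = NULL) {
  stopifnot(inherits(curve, "saxs_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines(paste("#", paste(names(curve), collapse = " ")), con)
  m <- as.matrix(as.data.frame(curve))
  writeLines(apply(format(m, digits = 15, trim = TRUE, scientific = TRUE),
                   1, paste, collapse = " "), con)
  invisible(path)
}
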