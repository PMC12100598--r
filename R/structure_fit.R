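#' Component library for mixture fitting
#'
#' A named set of model components (for instance: free dimer, short single
#' tubule, bundle of long tubules), each holding a precomputed scattering
#' curve and the number of tubulin dimers in the component. All curves must
#' share one q grid.
#'
#' @param ... named components, each `list(curve = <saxs_curve>,
#'   n_dimers = <count>)`.
#' @return Object of class `component_library`.
#' @export
component_library <- function(...) {
  comps <- list(...)
  if (length(comps) == 1 && is.null(names(comps)) && is.list(comps[[1]]) &&
      !inherits(comps[[1]]$curve, "saxs_curve")) {
    comps <- comps[[1]]
  }
  if (length(comps) == 0) stop("component_library: no components", call. = FALSE)
  if (is.null(names(comps)) || any(names(comps) == "")) {
    stop("component_library: components must be named", call. = FALSE)
  }
  q <- comps[[1]]$curve$q
  for (nm in names(comps)) {
    c_ <- comps[[nm]]
    if (!inherits(c_$curve, "saxs_curve") || is.null(c_$n_dimers)) {
      stop("component_library: each component needs a saxs_curve and n_dimers",
           call. = FALSE)
    }
    if (!isTRUE(all.equal(c_$curve$q, q))) {
      stop("component_library: component '", nm, "' is not on the shared q grid",
           call. = FALSE)
    }
    if (c_$n_dimers <= 0) stop("component_library: n_dimers must be positive",
                               call. = FALSE)
  }
  structure(comps, class = "component_library")
}

#' Non-negative mixture fit of model components to a SAXS curve
#'
#' Decomposes a target curve into a non-negative linear combination of the
#' library's component curves. Before fitting, every component curve is
#' divided by its dimer count, so the fitted coefficients weight tubulin
#' mass and, renormalized to sum to one, are the mass fractions of tubulin
#' in each component. The overall intensity scale is free (absorbed by the
#' coefficients before renormalization). Weighted by `1/sigma` when the
#' target carries uncertainties, otherwise by a relative 1 percent
#' pseudo-uncertainty.
#'
#' @param target a `saxs_curve` on the library's q grid.
#' @param library a `component_library`.
#' @return Object of class `structure_fit_result` with elements
#'   `mass_fractions` (named, summing to 1), `coefficients` (raw NNLS
#'   scale), `chi2`, `r_squared`, `fitted` (a `saxs_curve`).
#' @export
mixture_fit <- function(target, library) {
  stopifnot(inherits(target, "saxs_curve"), inherits(library, "component_library"))
  q <- library[[1]]$curve$q
  if (!isTRUE(all.equal(target$q, q))) {
    stop("mixture_fit: target and library q grids differ", call. = FALSE)
  }
  if (all(target$I == 0)) stop("mixture_fit: all-zero target", call. = FALSE)
  X <- vapply(library, function(c_) c_$curve$I / c_$n_dimers,
              numeric(length(q)))
  X <- matrix(X, ncol = length(library),
              dimnames = list(NULL, names(library)))
  sig <- if (!is.null(target$sigma)) target$sigma else
    0.01 * pmax(abs(target$I), max(abs(target$I)) * 1e-6)
  w <- 1 / sig
  co <- if (ncol(X) == 1) {
    max(0, sum(w^2 * X[, 1] * target$I) / sum(w^2 * X[, 1]^2))
  } else {
    pracma::lsqnonneg(X * w, target$I * w)$x
  }
  co <- as.numeric(co)
  names(co) <- names(library)
  if (sum(co) <= 0) {
    stop("mixture_fit: degenerate fit, all coefficients zero", call. = FALSE)
  }
  fit <- as.numeric(X %*% co)
  structure(list(
    mass_fractions = co / sum(co),
    coefficients = co,
    chi2 = sum(((target$I - fit) * w)^2),
    r_squared = r_squared(target$I, fit, w^2),
    fitted = saxs_curve(q, fit)),
    class = "structure_fit_result")
}

#' @export
print.structure_fit_result <- function(x, ...) {
  cat("<structure_fit_result>\n")
  if (!is.null(x$mass_fractions)) {
    cat("mass fractions:\n")
    print(round(x$mass_fractions, 4))
  }
  if (!is.null(x$best)) {
    cat("best-fit parameters:\n")
    print(unlist(x$best))
  }
  cat("chi2 =", signif(x$chi2, 5), " R^2 =", signif(x$r_squared, 5), "\n")
  invisible(x)
}

# scale-free weighted chi^2 between a model curve and data
.chi2_free_scale <- function(y, m, w) {
  s <- sum(w * m * y) / sum(w * m^2)
  list(chi2 = sum(w * (y - s * m)^2), scale = s)
}

#' Grid scan of structural parameters against a SAXS curve
#'
#' Builds an assembly and its scattering curve at every point of a parameter
#' grid, computes the scale-free weighted chi-squared against the target and
#' returns the arg-min together with the full objective profile (for
#' sensitivity reporting). Model curves are cached across calls keyed by the
#' parameter tuple and the subunit, so ladders of targets sharing one grid
#' reuse every curve. An optional Nelder-Mead refinement polishes the best
#' grid point for continuous parameters.
#'
#' @param target a `saxs_curve`.
#' @param recipe function taking the grid parameters by name and returning an
#'   `assembly` (e.g. `function(r, p) build_inverted_helical_tubule(r, p,
#'   h = 60, L_dim = 8)`).
#' @param grid named list of parameter value vectors; the scan covers their
#'   full cross product. Grid points violating geometric invariants should be
#'   avoided by construction (the recipe may also error; errors propagate).
#' @param subunit a `bead_model` for one dimer.
#' @param refine logical, run a Nelder-Mead polish from the best grid point.
#' @param cache environment used as curve cache; pass the same environment
#'   across calls to share work. `NULL` disables caching.
#' @param ... passed to [assembly_intensity()] (e.g. `reduce`,
#'   `exact_limit`).
#' @return A `structure_fit_result` with `best` (named parameter list),
#'   `chi2`, `r_squared`, `profile` (data frame: grid + chi2), `fitted`.
#' @export
scan_structure_params <- function(target, recipe, grid, subunit,
                                  refine = FALSE, cache = NULL, ...) {
  stopifnot(inherits(target, "saxs_curve"), is.function(recipe),
            is.list(grid), length(grid) >= 1, inherits(subunit, "bead_model"))
  if (!all(nzchar(names(grid)))) {
    stop("scan_structure_params: grid must be a named list", call. = FALSE)
  }
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(pts) == 0) stop("scan_structure_params: empty grid", call. = FALSE)
  q <- target$q
  sig <- if (!is.null(target$sigma)) target$sigma else
    0.01 * pmax(abs(target$I), max(abs(target$I)) * 1e-6)
  w <- 1 / sig^2
  sub_key <- paste0("sub", nrow(subunit$beads), "_",
                    signif(sum(subunit$beads$contrast), 10))
  model_curve <- function(pars) {
    key <- paste(sub_key, paste(names(pars), signif(unlist(pars), 12),
                                sep = "=", collapse = ";"),
                 paste(signif(range(q), 10), length(q), collapse = ","))
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    asm <- do.call(recipe, pars)
    cv <- assembly_intensity(asm, subunit, q = q, ...)$I
    if (!is.null(cache)) cache[[key]] <- cv
    cv
  }
  chi2 <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    m <- model_curve(as.list(pts[i, , drop = FALSE]))
    chi2[i] <- .chi2_free_scale(target$I, m, w)$chi2
  }
  best_i <- which.min(chi2)
  best <- as.list(pts[best_i, , drop = FALSE])
  if (refine) {
    obj <- function(x) {
      pars <- as.list(x)
      names(pars) <- names(grid)
      m <- tryCatch(model_curve(pars), error = function(e) NULL)
      if (is.null(m)) return(1e300)
      .chi2_free_scale(target$I, m, w)$chi2
    }
    op <- optim(unlist(best), obj, method = "Nelder-Mead",
                control = list(maxit = 100, reltol = 1e-6))
    if (op$value < chi2[best_i]) {
      best <- as.list(op$par)
      names(best) <- names(grid)
    }
  }
  m <- model_curve(best)
  sc <- .chi2_free_scale(target$I, m, w)
  structure(list(
    best = best,
    chi2 = sc$chi2,
    r_squared = r_squared(target$I, sc$scale * m, w),
    profile = cbind(pts, chi2 = chi2),
    fitted = saxs_curve(q, sc$scale * m)),
    class = "structure_fit_result")
}
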