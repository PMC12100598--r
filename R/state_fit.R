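#' Weighted coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with weighted sums; `SS_tot` is taken about
#' the weighted mean of the observations.
#'
#' @param observed,fitted numeric vectors of equal length.
#' @param weights optional non-negative weights (default uniform).
#' @return R-squared value; `NA` with a warning when the observations have
#'   zero total variance.
#' @export
r_squared <- function(observed, fitted, weights = NULL) {
  stopifnot(length(observed) == length(fitted))
  if (is.null(weights)) weights <- rep(1, length(observed))
  stopifnot(length(weights) == length(observed), all(weights >= 0))
  mu <- weighted.mean(observed, weights)
  ss_tot <- sum(weights * (observed - mu)^2)
  if (ss_tot == 0) {
    warning("r_squared: zero total variance, R^2 undefined")
    return(NA_real_)
  }
  1 - sum(weights * (observed - fitted)^2) / ss_tot
}

#' Two-state linear-combination fit of a curve family
#'
#' Fits every curve of the family as `I = f_A A(q) + f_B B(q)` against two
#' basis states (e.g. the initial tubulin-dimer-rich and the final MT-rich
#' scattering curves). With `closure = TRUE` (default) the fractions are
#' constrained to `f_A + f_B = 1`, leaving one free fraction per curve;
#' `nonneg = TRUE` clips fractions into `[0, 1]`. Weighted least squares with
#' weights `1/sigma^2` when the family carries uncertainties, uniform
#' otherwise.
#'
#' @param family a `curve_family`.
#' @param basis_A,basis_B `saxs_curve` objects on the family's q grid.
#' @param closure logical, constrain `f_A + f_B = 1`.
#' @param nonneg logical, constrain fractions to be non-negative.
#' @return Object of class `two_state_fit`: data frame `fractions`
#'   (label, f_A, f_B, r_squared), `r_squared_global`, and matrix
#'   `residuals` (curve x q).
#' @export
two_state_fit <- function(family, basis_A, basis_B, closure = TRUE,
                          nonneg = TRUE) {
  stopifnot(inherits(family, "curve_family"),
            inherits(basis_A, "saxs_curve"), inherits(basis_B, "saxs_curve"))
  if (!isTRUE(all.equal(basis_A$q, family$q)) ||
      !isTRUE(all.equal(basis_B$q, family$q))) {
    stop("two_state_fit: basis curves must be on the family's q grid",
         call. = FALSE)
  }
  A <- basis_A$I
  B <- basis_B$I
  dAB <- A - B
  if (sqrt(sum(dAB^2)) < 1e-12 * sqrt(sum(A^2))) {
    stop("two_state_fit: basis curves are collinear (identical shapes)",
         call. = FALSE)
  }
  n <- nrow(family$I)
  f_A <- f_B <- r2 <- numeric(n)
  resid <- matrix(NA_real_, n, length(family$q))
  for (i in seq_len(n)) {
    y <- family$I[i, ]
    w <- if (!is.null(family$sigma)) 1 / family$sigma[i, ]^2 else
      rep(1, length(y))
    if (closure) {
      # y - B = f_A (A - B): one free fraction
      fa <- sum(w * dAB * (y - B)) / sum(w * dAB^2)
      if (nonneg) fa <- max(0, min(1, fa))
      fb <- 1 - fa
    } else {
      X <- cbind(A, B)
      co <- tryCatch(
        solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), y * sqrt(w))),
        error = function(e) stop("two_state_fit: basis curves are degenerate",
                                 call. = FALSE))
      fa <- co[1]; fb <- co[2]
      if (nonneg) { fa <- max(0, fa); fb <- max(0, fb) }
    }
    fit <- fa * A + fb * B
    resid[i, ] <- y - fit
    f_A[i] <- fa; f_B[i] <- fb
    r2[i] <- r_squared(y, fit, w)
  }
  wall <- if (!is.null(family$sigma)) 1 / family$sigma^2 else
    matrix(1, n, length(family$q))
  fitall <- outer(f_A, A) + outer(f_B, B)
  structure(list(
    fractions = data.frame(label = family$labels, f_A = f_A, f_B = f_B,
                           r_squared = r2),
    r_squared_global = r_squared(as.numeric(family$I), as.numeric(fitall),
                                 as.numeric(wall)),
    residuals = resid, closure = closure, nonneg = nonneg),
    class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("<two_state_fit>", nrow(x$fractions), "curves, global R^2 =",
      signif(x$r_squared_global, 4), "\n")
  print(utils::head(x$fractions, 10))
  if (nrow(x$fractions) > 10) cat("...\n")
  invisible(x)
}

#' SVD rank analysis of a curve family
#'
#' Singular values of the (curve x q) intensity matrix and the effective
#' number of independent components. Two basis states mixing in varying
#' proportions give exactly rank 2; additional transient intermediates raise
#' the rank. The noise floor below which singular values are discarded is,
#' by default, 3 times the median of the trailing half of the singular-value
#' spectrum; when the family carries uncertainties the floor can instead be
#' propagated from them (`floor = "sigma"`: the random-matrix noise edge
#' `(sqrt(n_curve) + sqrt(n_q)) * rms sigma`, with a 20 percent margin).
#' For noisy data use `floor = "sigma"` together with `scale = "column"`.
#'
#' @param family a `curve_family` with at least 2 curves.
#' @param center `"none"` (default) or `"mean"` (subtract the mean curve
#'   before decomposing; the mixing then shows rank - 1 components).
#' @param floor `"trailing"` (default) or `"sigma"`.
#' @param scale `"none"` (default) or `"column"`: divide each q column by
#'   its mean absolute intensity before decomposing. Column scaling is
#'   rank-preserving and whitens the heteroscedastic (multiplicative) noise
#'   of SAXS curves spanning decades of intensity, so the trailing
#'   singular-value plateau reflects the noise level; recommended for noisy
#'   families.
#' @return List of class `svd_rank`: `singular_values`, `effective_rank`,
#'   `noise_floor`.
#' @export
svd_rank <- function(family, center = c("none", "mean"),
                     floor = c("trailing", "sigma"),
                     scale = c("none", "column")) {
  stopifnot(inherits(family, "curve_family"))
  center <- match.arg(center)
  floor <- match.arg(floor)
  scale <- match.arg(scale)
  M <- family$I
  if (nrow(M) < 2) stop("svd_rank: at least 2 curves required", call. = FALSE)
  sig <- family$sigma
  if (scale == "column") {
    cs <- colMeans(abs(M))
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (!is.null(sig)) sig <- sweep(sig, 2, cs, "/")
  }
  if (center == "mean") M <- sweep(M, 2, colMeans(M))
  sv <- svd(M, nu = 0, nv = 0)$d
  # never resolve components below numerical zero of the decomposition
  eps_floor <- sv[1] * 1e-10
  nf <- if (floor == "sigma" && !is.null(sig)) {
    # random-matrix edge of a pure-noise matrix, (sqrt n + sqrt m) sigma,
    # with a 20% safety margin for heteroscedasticity
    max(1.2 * (sqrt(nrow(M)) + sqrt(ncol(M))) * sqrt(mean(sig^2)), eps_floor)
  } else {
    i0 <- ceiling(length(sv) / 2) + 1L
    if (i0 > length(sv)) {
      eps_floor
    } else {
      max(3 * median(sv[seq.int(i0, length(sv))]), eps_floor)
    }
  }
  structure(list(singular_values = sv,
                 effective_rank = sum(sv > nf),
                 noise_floor = nf, center = center),
            class = "svd_rank")
}

#' @export
print.svd_rank <- function(x, ...) {
  cat("<svd_rank> effective rank", x$effective_rank, "(noise floor",
      signif(x$noise_floor, 3), ")\n")
  cat("singular values:", signif(utils::head(x$singular_values, 8), 4), "\n")
  invisible(x)
}

#' Detect isosbestic points in a curve family
#'
#' Isosbestic points are q values at which all curves of a two-component
#' mixing series cross: the across-curve spread vanishes there while it does
#' not at neighboring q. The relative spread `sd(I) / |mean(I)|` is computed
#' at every q; contiguous runs below `tolerance` flanked by above-tolerance
#' neighbors are reported by the q of their minimal spread. When every q is
#' below tolerance (identical curves) all q values are returned -- a
#' degenerate family has no localized crossings.
#'
#' @param family a `curve_family` with at least 3 curves.
#' @param tolerance relative-spread threshold (default 0.01, i.e. curves
#'   agree to 1 percent at the crossing).
#' @return Numeric vector of q positions (possibly empty).
#' @export
find_isosbestic <- function(family, tolerance = 0.01) {
  stopifnot(inherits(family, "curve_family"))
  if (nrow(family$I) < 3) {
    stop("find_isosbestic: at least 3 curves required", call. = FALSE)
  }
  mu <- colMeans(family$I)
  spread <- apply(family$I, 2, sd) / pmax(abs(mu), .Machine$double.xmin)
  below <- spread < tolerance
  if (all(below)) return(family$q)
  if (!any(below)) return(numeric(0))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- numeric(0)
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    out <- c(out, family$q[idx[which.min(spread[idx])]])
  }
  sort(out)
}
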