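#' O'Sullivan penalized spline basis
#'
#' Builds a cubic B-spline basis with interior knots at quantiles of the
#' data, together with the O'Sullivan penalty — the matrix of integrated
#' products of second derivatives, computed exactly by Simpson's rule on
#' each inter-knot interval (the integrand is piecewise quadratic there).
#' The penalty is positive semi-definite with a two-dimensional null space
#' containing all linear functions, so penalization never shrinks a straight
#' line. The spectral (Demmler-Reinsch) transform of the penalized part
#' yields the mixed-model design used by the Gibbs sampler: a smooth
#' `f(x) = beta0 + beta1 x + Z u` with `u ~ N(0, sigma_u^2 I)`.
#'
#' @param x Covariate values the knots are placed on (needs at least
#'   `n_knots + 2` distinct values).
#' @param n_knots Number of interior knots (default 5).
#' @param boundary Length-2 interval the basis lives on; defaults to
#'   `range(x)`. Set it to the full prediction domain (e.g. `c(0, 100)` for
#'   percent cover) when curves must be evaluated beyond the data.
#' @return An `osullivan_basis` object: `B` (n x (n_knots+4) basis), `Omega`
#'   (penalty), `Z` (n x (n_knots+2) mixed-model design), `transform` (maps
#'   B-spline columns to `Z` columns), `knots`, `interior`, `boundary`.
#' @export
osullivan_basis <- function(x, n_knots = 5, boundary = range(x)) {
  stopifnot(n_knots >= 3, length(boundary) == 2, boundary[1] < boundary[2])
  if (length(unique(x)) < n_knots + 2)
    stop("osullivan_basis: need at least n_knots + 2 distinct x values",
         call. = FALSE)
  if (any(x < boundary[1] | x > boundary[2]))
    stop("osullivan_basis: x outside the boundary interval", call. = FALSE)
  interior <- unname(stats::quantile(unique(x),
                                     probs = seq_len(n_knots) / (n_knots + 1)))
  knots <- c(rep(boundary[1], 4), interior, rep(boundary[2], 4))
  B <- splines::splineDesign(knots, x, ord = 4, outer.ok = FALSE)

  # exact penalty: B'' is piecewise linear between distinct knots, so each
  # entry of the integrand is piecewise quadratic and Simpson is exact
  uk <- unique(knots)
  lower <- uk[-length(uk)]
  upper <- uk[-1]
  pts <- c(lower, (lower + upper) / 2, upper)
  wts <- rep((upper - lower) / 6, 3) * rep(c(1, 4, 1), each = length(lower))
  B2 <- splines::splineDesign(knots, pts, ord = 4, derivs = 2)
  Omega <- crossprod(B2 * sqrt(wts))

  eg <- eigen(Omega, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  # rank is n_knots + 2: everything except the linear null space
  transform <- eg$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[pos]), sum(pos))
  structure(
    list(B = B, Omega = Omega, Z = B %*% transform, transform = transform,
         knots = knots, interior = interior, boundary = boundary,
         n_knots = n_knots),
    class = "osullivan_basis"
  )
}

#' Evaluate the penalized (Z) columns of an O'Sullivan basis at new points
#'
#' @param basis An [osullivan_basis()] object.
#' @param x_new Points within the basis boundary.
#' @return Matrix with `ncol(basis$Z)` columns.
#' @export
osullivan_predict <- function(basis, x_new) {
  stopifnot(inherits(basis, "osullivan_basis"))
  if (any(x_new < basis$boundary[1] | x_new > basis$boundary[2]))
    stop("x_new outside the basis boundary", call. = FALSE)
  splines::splineDesign(basis$knots, x_new, ord = 4) %*% basis$transform
}
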