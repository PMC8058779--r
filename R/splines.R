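#' Knot positions at evenly spaced covariate quantiles
#'
#' Places \code{k} knots at the empirical quantiles of \code{x} with
#' probabilities \eqn{0, 1/(k-1), \dots, (k-2)/(k-1), 1}, so the first and
#' last knots sit at \code{min(x)} and \code{max(x)}.  Quantiles use linear
#' interpolation of order statistics (type 7); any consistent convention
#' yields the same fitted curves.
#'
#' @param x numeric covariate vector.
#' @param k integer >= 2; number of knots.
#' @return sorted numeric vector of \code{k} knots.
#' @seealso [naturalCubicBasis()]
#' @export
#' @examples
#' knotPositions(1:5, 3)  # 1 3 5
knotPositions <- function(x, k) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  k <- as.integer(k)
  if (k < 2L) stop("at least 2 knots are required")
  nd <- length(unique(x))
  if (nd < k) {
    stop("cannot place ", k, " distinct knots: covariate has only ",
         nd, " distinct values")
  }
  kn <- unname(quantile(x, probs = seq(0, 1, length.out = k), type = 7))
  if (anyDuplicated(kn)) {
    stop("duplicate knots for k = ", k, " (", nd,
         " distinct covariate values); reduce the basis dimension")
  }
  kn
}

#' Natural cubic spline basis on given knots
#'
#' Builds the basis of the natural cubic spline space on \code{knots}
#' (cubic polynomial pieces, linear beyond the boundary knots), excluding
#' the intercept: \code{k} knots span a \code{k}-dimensional space
#' including the constant, so the returned matrix has \code{k - 1}
#' columns.  With two (boundary-only) knots the basis is the single linear
#' column.  Values of \code{x} outside the knot range are extrapolated
#' linearly and reported via a message.
#'
#' @param x numeric vector of evaluation points.
#' @param knots sorted numeric vector of at least two distinct knots.
#' @return numeric matrix, \code{length(x)} rows and
#'   \code{length(knots) - 1} columns, with attributes \code{"knots"}.
#' @export
naturalCubicBasis <- function(x, knots) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  knots <- sort(unique(as.numeric(knots)))
  if (length(knots) < 2L) stop("at least 2 distinct knots are required")
  bk <- range(knots)
  if (any(x < bk[1] | x > bk[2])) {
    message("naturalCubicBasis: ", sum(x < bk[1] | x > bk[2]),
            " point(s) outside the knot range; extrapolating linearly")
  }
  if (length(knots) == 2L) {
    S <- matrix(x, ncol = 1L)
  } else {
    S <- unclass(splines::ns(x, knots = knots[-c(1L, length(knots))],
                             Boundary.knots = bk))
    S <- matrix(as.numeric(S), nrow = length(x))
  }
  dimnames(S) <- list(NULL, paste0("s", seq_len(ncol(S))))
  attr(S, "knots") <- knots
  S
}

# Basis of dimension d (the number of beta coefficients, intercept
# excluded): d + 1 knots at evenly spaced quantiles of x.
.basisOfDim <- function(x, d) {
  naturalCubicBasis(x, knotPositions(x, d + 1L))
}
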