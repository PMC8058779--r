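#' Build nested null/alternative models for a study design
#'
#' Constructs the [OdpDesign-class] pair of design matrices realizing one
#' of the three supported sampling designs:
#' \describe{
#'   \item{static}{null = intercept only; alternative = intercept plus
#'     treatment-contrast group indicators (first lexicographic level is
#'     the reference).}
#'   \item{independent}{subjects sampled once along a continuous covariate;
#'     null = intercept only; alternative = intercept plus a
#'     \code{d}-dimensional natural cubic spline basis (tests every basis
#'     coefficient).}
#'   \item{longitudinal}{subjects measured repeatedly; the group-difference
#'     test fits one curve to both classes under the null (intercept +
#'     shared spline) and class-specific curves under the alternative
#'     (intercept + per-class spline columns).}
#' }
#' Spline columns are orthonormalized against the intercept and among
#' themselves; fitted values and all test statistics are invariant to this
#' conditioning choice.
#'
#' @param sampleMeta data.frame (or the \code{colData} of a
#'   SummarizedExperiment) with one row per measurement.  Columns used:
#'   \code{covariate} (numeric; required for non-static designs),
#'   \code{group} (required for static and longitudinal),
#'   \code{individual} (required for longitudinal).
#' @param design one of \code{"static"}, \code{"independent"},
#'   \code{"longitudinal"}.
#' @param d integer spline basis dimension (number of spline coefficients
#'   per curve); ignored for static designs.
#' @param test \code{"group-difference"} (longitudinal default) or
#'   \code{"any-effect"} (a longitudinal design without classes reduces to
#'   the independent-sampling test).
#' @return an [OdpDesign-class] object.
#' @export
#' @examples
#' meta <- data.frame(group = rep(c("a", "b"), c(10, 7)))
#' buildStudy(meta, "static")
buildStudy <- function(sampleMeta,
                       design = c("static", "independent", "longitudinal"),
                       d = NULL,
                       test = c("group-difference", "any-effect")) {
  design <- match.arg(design)
  test <- match.arg(test)
  if (is(sampleMeta, "SummarizedExperiment"))
    sampleMeta <- as.data.frame(colData(sampleMeta))
  sampleMeta <- as.data.frame(sampleMeta)
  N <- nrow(sampleMeta)

  if (design == "static") {
    if (is.null(sampleMeta$group)) stop("static design requires a 'group' column")
    g <- factor(sampleMeta$group)
    if (nlevels(g) < 2L) stop("static design requires a group with >= 2 levels")
    XAlt <- model.matrix(~g)
    colnames(XAlt) <- c("(Intercept)", paste0("group:", levels(g)[-1L]))
    return(new("OdpDesign", kind = "static",
               XNull = matrix(1, N, 1, dimnames = list(NULL, "(Intercept)")),
               XAlt = XAlt, d = 0L, knots = numeric(0),
               roles = c("intercept", rep("group", nlevels(g) - 1L))))
  }

  x <- sampleMeta$covariate
  if (is.null(x) || !is.numeric(x) || any(!is.finite(x)))
    stop(design, " design requires a finite numeric 'covariate' column")
  if (is.null(d)) stop("spline dimension d is required for non-static designs")
  d <- as.integer(d)
  nd <- length(unique(x))
  if (d > nd - 1L)
    stop("spline dimension d = ", d, " exceeds distinct covariate values - 1 (",
         nd - 1L, ")")
  S <- .basisOfDim(x, d)
  # orthonormalize against the intercept (conditioning only)
  Q <- qr.Q(qr(cbind(1, S)))
  S <- Q[, -1L, drop = FALSE]
  colnames(S) <- paste0("s", seq_len(d))

  if (design == "independent" ||
      (design == "longitudinal" && test == "any-effect")) {
    XAlt <- cbind("(Intercept)" = 1, S)
    return(new("OdpDesign", kind = design,
               XNull = matrix(1, N, 1, dimnames = list(NULL, "(Intercept)")),
               XAlt = XAlt, d = d, knots = attr(.basisOfDim(x, d), "knots"),
               roles = c("intercept", rep("basis", d))))
  }

  # longitudinal group-difference test
  if (is.null(sampleMeta$group))
    stop("longitudinal group test requires a 'group' column")
  if (is.null(sampleMeta$individual))
    stop("longitudinal design requires an 'individual' column")
  g <- factor(sampleMeta$group)
  if (nlevels(g) < 2L) stop("group must have >= 2 levels")
  XNull <- cbind("(Intercept)" = 1, S)
  blocks <- lapply(levels(g), function(lev) {
    B <- S * (g == lev)
    colnames(B) <- paste0("s", seq_len(d), ":", lev)
    B
  })
  XAlt <- do.call(cbind, c(list("(Intercept)" = matrix(1, N, 1)), blocks))
  colnames(XAlt)[1L] <- "(Intercept)"
  new("OdpDesign", kind = "longitudinal", XNull = XNull, XAlt = XAlt,
      d = d, knots = attr(.basisOfDim(x, d), "knots"),
      roles = c("intercept", rep(paste0("basis:", levels(g)), each = d)))
}
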