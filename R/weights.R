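#' log2 counts per million
#'
#' \code{log2((count + 0.5) / (libSize + 1) * 1e6)} with the library size
#' taken as the column sum.  The half-count offset avoids taking logs of
#' zero; the +1 on the library size keeps the transform bounded.
#'
#' @param counts nonnegative count matrix (m genes x N samples).
#' @return numeric matrix of logCPM values, same shape.
#' @export
logCPM <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every column must have a positive library size")
  t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
}

#' Filter genes by total count
#'
#' Keeps genes whose total count across all samples is at least
#' \code{minTotal} (default 10, i.e. drop genes with fewer than 10 reads).
#'
#' @param counts count matrix.
#' @param minTotal minimum total count required to keep a gene.
#' @return logical row mask.
#' @export
filterLowCounts <- function(counts, minTotal = 10) {
  rowSums(as.matrix(counts)) >= minTotal
}

#' Estimate inverse-variance precision weights from the mean-variance trend
#'
#' Implements a voom-style procedure: (i) transform counts to logCPM,
#' (ii) fit every gene by OLS under the alternative design and take
#' residual standard deviations, (iii) fit a robust lowess trend of
#' \eqn{\sqrt{sd}} on the mean log2 count, (iv) predict the trend at each
#' observation's fitted log2 count and set the weight to the predicted
#' fourth inverse power (i.e. predicted variance to the -1).  Trend
#' predictions outside the fitted range are clamped at the endpoints.
#'
#' @param counts filtered nonnegative count matrix.
#' @param design an [OdpDesign-class]; residuals are taken under the
#'   alternative model.
#' @param span lowess span for the trend (default 0.5).
#' @return strictly positive m x N weight matrix with attribute
#'   \code{"provenance" = "estimated"}.
#' @export
estimateWeights <- function(counts, design, span = 0.5) {
  counts <- as.matrix(counts)
  m <- nrow(counts)
  if (m < 50L) {
    warning("fewer than 50 genes: refusing to fit a mean-variance trend; ",
            "all weights set to 1")
    W <- matrix(1, m, ncol(counts))
    attr(W, "provenance") <- "unit"
    return(W)
  }
  Y <- logCPM(counts)
  X1 <- design@XAlt
  p1 <- .projector(X1)
  fitted <- .projectRows(Y, p1$Q)
  N <- ncol(Y)
  resSd <- sqrt(rowSums((Y - fitted)^2) / (N - p1$df))
  lib <- colSums(counts)
  # mean log2 count per gene, and fitted log2 counts per observation
  meanLogCount <- rowMeans(Y) + mean(log2(lib + 1)) - log2(1e6)
  lo <- lowess(meanLogCount, sqrt(resSd), f = span)
  fittedLogCount <- sweep(fitted, 2L, log2(lib + 1) - log2(1e6), "+")
  rng <- range(lo$x)
  pred <- approx(lo$x, lo$y, xout = pmin(pmax(fittedLogCount, rng[1]), rng[2]),
                 rule = 2, ties = mean)$y
  pred <- pmax(pred, 1e-6)
  W <- matrix(pred^-4, m, N)
  dimnames(W) <- dimnames(counts)
  attr(W, "provenance") <- "estimated"
  W
}

#' The weight transform reducing weighted to ordinary least squares
#'
#' Given inverse-variance weights \code{w}, the response and design are
#' scaled by \code{sqrt(w)}; ordinary least squares on the transformed
#' pair reproduces the weighted fit exactly (coefficients and weighted
#' RSS).
#'
#' @param y numeric response vector.
#' @param design numeric design matrix.
#' @param w strictly positive weight vector.
#' @return list with elements \code{y} (transformed response) and
#'   \code{design} (transformed design).
#' @export
weightTransform <- function(y, design, w) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  sw <- sqrt(w)
  list(y = y * sw, design = as.matrix(design) * sw)
}
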