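#' Per-gene least-squares fits under both models
#'
#' Fits every gene by ordinary (or precision-weighted) least squares under
#' the null and alternative design matrices and records fitted means,
#' residual sums of squares and maximum-likelihood scale estimates
#' \eqn{\hat\sigma = \sqrt{RSS/N}} (the ML divisor N is used because the
#' ODP statistics are likelihood ratios; the F-type comparators apply the
#' unbiased divisor internally).
#'
#' When \code{weights} are supplied the standard WLS-to-OLS reduction is
#' applied: each row of \code{Y} and the design are multiplied by
#' \code{sqrt(w)} (see [weightTransform()]) and all returned quantities
#' live on that transformed, approximately homoscedastic scale.
#'
#' Genes with numerically zero residual variance under the null model
#' (constant rows) are flagged \code{degenerate}; they carry no evidence,
#' break Normal likelihoods, and are excluded from module clustering.
#'
#' @param Y numeric matrix (m genes x N measurements), a numeric vector
#'   (one gene), or a SummarizedExperiment (first assay used).
#' @param design an [OdpDesign-class] from [buildStudy()].
#' @param weights optional strictly positive m x N matrix of
#'   inverse-variance weights (see [estimateWeights()]).
#' @return a [GeneFitSet-class].
#' @export
fitModels <- function(Y, design, weights = NULL) {
  if (is(Y, "SummarizedExperiment")) Y <- assay(Y)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  Y <- as.matrix(Y)
  ids <- rownames(Y)
  if (is.null(ids)) ids <- paste0("gene_", seq_len(nrow(Y)))
  X0 <- design@XNull
  X1 <- design@XAlt
  N <- ncol(Y)
  if (nrow(X1) != N)
    stop("design has ", nrow(X1), " rows but Y has ", N, " columns")
  if (N <= ncol(X1))
    stop("need more measurements (", N, ") than alternative model columns (",
         ncol(X1), ")")

  if (is.null(weights)) {
    p0 <- .projector(X0); p1 <- .projector(X1)
    mu0 <- .projectRows(Y, p0$Q)
    mu1 <- .projectRows(Y, p1$Q)
    rss0 <- rowSums((Y - mu0)^2)
    rss1 <- rowSums((Y - mu1)^2)
    sw <- matrix(numeric(0), 0, 0)
    weighted <- FALSE
  } else {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == dim(Y)))
      stop("weights must have the same shape as Y")
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be finite and strictly positive")
    sw <- sqrt(weights)
    m <- nrow(Y)
    mu0 <- mu1 <- matrix(0, m, N)
    rss0 <- rss1 <- numeric(m)
    for (i in seq_len(m)) {
      yi <- Y[i, ] * sw[i, ]
      X0i <- X0 * sw[i, ]
      X1i <- X1 * sw[i, ]
      q1 <- qr(X1i)
      if (q1$rank < ncol(X1i))
        stop("gene ", ids[i], ": alternative design rank deficient after ",
             "weighting")
      f0 <- qr.fitted(qr(X0i), yi)
      f1 <- qr.fitted(q1, yi)
      mu0[i, ] <- f0
      mu1[i, ] <- f1
      rss0[i] <- sum((yi - f0)^2)
      rss1[i] <- sum((yi - f1)^2)
    }
    weighted <- TRUE
  }
  # numerical guard: nestedness can be violated only by round-off
  rss0 <- unname(rss0)
  rss1 <- unname(pmin(rss1, rss0))
  dimnames(mu0) <- dimnames(mu1) <- NULL
  scale <- unname(pmax(rowSums(Y^2), 1))
  degenerate <- rss0 <= 1e-12 * scale
  new("GeneFitSet", geneIds = ids, mu0 = mu0, mu1 = mu1,
      rss0 = rss0, rss1 = rss1,
      sigma0 = sqrt(rss0 / N), sigma1 = sqrt(rss1 / N),
      df0 = ncol(X0), df1 = ncol(X1),
      weighted = weighted, weights = sw, degenerate = degenerate)
}

#' Subtract the fitted null model from the data
#'
#' The null-model fit is ancillary to the hypothesis test; removing it
#' recasts the hypotheses as mean-zero (null) versus nonzero mean
#' (alternative).  Every transformed row is orthogonal to the null design.
#' For a weighted [GeneFitSet-class] the input is first moved to the
#' weight-transformed scale using the stored weights.
#'
#' @param Y expression matrix as passed to [fitModels()].
#' @param fits the matching [GeneFitSet-class].
#' @return numeric matrix of the same shape as \code{Y}.
#' @export
nullTransform <- function(Y, fits) {
  if (is(Y, "SummarizedExperiment")) Y <- assay(Y)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  Y <- as.matrix(Y)
  if (fits@weighted) Y <- Y * fits@weights
  Yp <- Y - fits@mu0
  attr(Yp, "nullTransformed") <- TRUE
  Yp
}

#' Eigen-genes: top right-singular vectors of the expression matrix
#'
#' Rows of \code{Y} are centered (gene-level means are nuisance) and the
#' first \code{E} right-singular vectors are returned; these data-driven
#' summary curves represent directions of maximal variation and are used
#' to choose the spline dimension.
#'
#' @param Y numeric matrix m x N (or SummarizedExperiment).
#' @param E number of eigen-genes (default 4).
#' @return E x N matrix, rows ordered by singular value; the singular
#'   values are attached as attribute \code{"singularValues"}.
#' @export
eigenGenes <- function(Y, E = 4L) {
  if (is(Y, "SummarizedExperiment")) Y <- assay(Y)
  Y <- as.matrix(Y)
  E <- as.integer(E)
  if (E > min(dim(Y))) stop("E exceeds min(m, N)")
  Yc <- Y - rowMeans(Y)
  sv <- svd(Yc, nu = 0, nv = E)
  out <- t(sv$v)
  attr(out, "singularValues") <- sv$d[seq_len(E)]
  out
}

#' Leave-one-out cross-validation error via the hat-matrix shortcut
#'
#' For a least-squares fit of \code{v} on \code{design}, the LOOCV error
#' is \eqn{\mathrm{mean}\left[((v_j - \hat v_j)/(1 - h_{jj}))^2\right]}
#' with \eqn{h_{jj}} the leverages — identical to refitting with each
#' point left out.  A leverage of (numerically) one makes the criterion
#' infinite, so such a dimension is never selected.
#'
#' @param v numeric response vector.
#' @param design full-rank numeric design matrix (including any
#'   intercept).
#' @return nonnegative scalar (possibly \code{Inf}).
#' @export
loocvError <- function(v, design) {
  .loocv(v, design)[["mean"]]
}

# mean LOOCV error plus its Monte-Carlo standard error (over observations)
.loocv <- function(v, design) {
  design <- as.matrix(design)
  qx <- qr(design)
  if (qx$rank < ncol(design)) stop("design must have full column rank")
  Q <- qr.Q(qx)
  h <- rowSums(Q^2)
  if (any(h >= 1 - 1e-12)) return(c(mean = Inf, se = Inf))
  e2 <- ((v - qr.fitted(qx, v)) / (1 - h))^2
  c(mean = mean(e2), se = sd(e2) / sqrt(length(e2)))
}

#' Choose the spline dimension by eigen-gene cross-validation
#'
#' For each eigen-gene and each candidate dimension \code{d = 1..D}, an
#' intercept + d-dimensional natural cubic basis is fitted and the LOOCV
#' error computed; each eigen-gene votes for the smallest \code{d} whose
#' error is within one standard error of the minimum (the one-SE
#' parsimony rule: a bare arg-min over-selects because nested
#' least-squares CV curves are nearly flat beyond the true dimension)
#' and the maximum vote across eigen-genes is returned.  When
#' \code{splits} is given (e.g. the two
#' treatment arms of a longitudinal study) the procedure is run on each
#' split's columns separately and all eigen-genes from every split vote.
#'
#' @param Y expression matrix (m x N) or SummarizedExperiment.
#' @param x numeric covariate vector of length N.
#' @param D maximum dimension searched (truncated, with a warning, at the
#'   number of distinct covariate values minus one).
#' @param E eigen-genes per (split) dataset, default 4.
#' @param splits optional factor/vector of length N partitioning columns.
#' @return the selected integer dimension, with the per-eigen-gene CV
#'   error matrix attached as attribute \code{"cvErrors"} (one matrix per
#'   split).
#' @export
selectDimension <- function(Y, x, D = 4L, E = 4L, splits = NULL) {
  if (is(Y, "SummarizedExperiment")) Y <- assay(Y)
  Y <- as.matrix(Y)
  if (length(x) != ncol(Y)) stop("x must have one value per column of Y")
  pieces <- if (is.null(splits)) list(seq_len(ncol(Y))) else
    split(seq_len(ncol(Y)), splits)
  best <- integer(0)
  cvList <- list()
  for (pi in seq_along(pieces)) {
    idx <- pieces[[pi]]
    xs <- x[idx]
    Dmax <- length(unique(xs)) - 1L
    Ds <- as.integer(D)
    if (Ds > Dmax) {
      warning("D truncated from ", Ds, " to ", Dmax,
              " (distinct covariate values - 1)")
      Ds <- Dmax
    }
    eg <- eigenGenes(Y[, idx, drop = FALSE], E = min(E, length(idx)))
    cv <- se <- matrix(NA_real_, nrow(eg), Ds)
    for (d in seq_len(Ds)) {
      Xd <- cbind(1, .basisOfDim(xs, d))
      for (e in seq_len(nrow(eg))) {
        parts <- .loocv(eg[e, ], Xd)
        cv[e, d] <- parts[["mean"]]
        se[e, d] <- parts[["se"]]
      }
    }
    votes <- vapply(seq_len(nrow(cv)), function(e) {
      mn <- which.min(cv[e, ])
      min(which(cv[e, ] <= cv[e, mn] + se[e, mn]))
    }, integer(1))
    best <- c(best, votes)
    cvList[[pi]] <- cv
  }
  out <- max(best)
  attr(out, "cvErrors") <- cvList
  out
}
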