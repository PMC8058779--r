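#' Symmetric Kullback-Leibler distance between two Normal gene models
#'
#' For two N-observation Normal models with mean vectors \code{muA},
#' \code{muB} and common per-model scales \code{sigmaA}, \code{sigmaB},
#' the symmetric KL distance (KL(P||Q) + KL(Q||P), summed over
#' observations) is
#' \deqn{\delta = \sum_j \frac{\sigma_a^2 + (\mu_{aj}-\mu_{bj})^2}
#'   {2\sigma_b^2} + \frac{\sigma_b^2 + (\mu_{aj}-\mu_{bj})^2}
#'   {2\sigma_a^2} - 1.}
#' This is the clustering metric for gene-to-module assignment.
#'
#' @param muA,muB numeric mean vectors of equal length.
#' @param sigmaA,sigmaB positive scales.
#' @return nonnegative scalar.
#' @export
symmetricKL <- function(muA, sigmaA, muB, sigmaB) {
  stopifnot(length(muA) == length(muB), sigmaA > 0, sigmaB > 0)
  d2 <- (muA - muB)^2
  sum((sigmaA^2 + d2) / (2 * sigmaB^2) +
      (sigmaB^2 + d2) / (2 * sigmaA^2) - 1)
}

# delta matrix between genes (mu m x N, sigma length m) and modules
# (centers K x N, upsilon length K), using alternative parameters only.
.klMatrix <- function(mu, sigma, centers, upsilon) {
  N <- ncol(mu)
  D2 <- .sqDistMatrix(mu, centers)
  s2 <- sigma^2
  u2 <- upsilon^2
  A <- outer(s2, 1 / (2 * u2)) * N          # N * sigma^2/(2 u^2)
  B <- outer(1 / (2 * s2), u2) * N          # N * u^2/(2 sigma^2)
  C <- sweep(D2 / 2, 2L, 1 / u2, "*") + sweep(D2 / 2, 1L, 1 / s2, "*")
  A + B + C - N
}

#' Cluster genes into modules by symmetric KL distance
#'
#' Alternating-minimization clustering of per-gene alternative model
#' parameters \eqn{(\hat\mu'_{i1}, \hat\sigma_{i1})} fitted on
#' null-transformed data.  Modules are initialized from K distinct genes
#' drawn with a seeded generator; genes are assigned to the module with
#' the smallest symmetric KL distance (only alternative parameters drive
#' assignment); module parameters are then updated as member averages
#' (center = mean fitted curve, \eqn{\upsilon_{k1}^2} = mean
#' \eqn{\hat\sigma_{i1}^2}, \eqn{\upsilon_{k0}^2} = mean
#' \eqn{\hat\sigma_{i0}^2}) and the steps repeat until the assignment is
#' unchanged or \code{maxIter} is reached.  Emptied modules are reseeded
#' with the gene farthest from its current module.
#'
#' Degenerate genes (zero residual variance) are excluded and keep an
#' \code{NA} assignment.
#'
#' @param fits a [GeneFitSet-class] from the original data; the
#'   alternative-model parameters on the null-transformed scale are
#'   derived internally (\eqn{\hat\mu'_{i1} = \hat\mu_{i1} -
#'   \hat\mu_{i0}}, identical to refitting the alternative model on the
#'   transformed data).
#' @param K number of modules (default 800; at least 200 is recommended
#'   for complex studies, and results are robust for K >= 50).
#' @param seed integer seed for the module initialization.
#' @param maxIter maximum number of assignment passes (default 100).
#' @return a [ModuleSet-class].
#' @export
klClust <- function(fits, K = 800L, seed = 1L, maxIter = 100L) {
  keep <- which(!fits@degenerate & fits@sigma1 > 0)
  mu <- fits@mu1[keep, , drop = FALSE] - fits@mu0[keep, , drop = FALSE]
  s1 <- fits@sigma1[keep]
  s0 <- fits@sigma0[keep]
  mC <- length(keep)
  K <- as.integer(K)
  if (K > mC) stop("K = ", K, " exceeds the ", mC, " clusterable genes")
  N <- ncol(mu)

  set.seed(seed)
  init <- sample.int(mC, K)
  centers <- mu[init, , drop = FALSE]
  u1 <- s1[init]
  u0 <- s0[init]

  assign <- integer(mC)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    delta <- .klMatrix(mu, s1, centers, u1)
    newAssign <- max.col(-delta, ties.method = "first")
    best <- delta[cbind(seq_len(mC), newAssign)]
    # reseed empty modules with the worst-fitting genes
    empty <- setdiff(seq_len(K), unique(newAssign))
    if (length(empty)) {
      worst <- order(best, decreasing = TRUE)
      take <- worst[seq_along(empty)]
      newAssign[take] <- empty
      centers[empty, ] <- mu[take, , drop = FALSE]
      u1[empty] <- s1[take]
      u0[empty] <- s0[take]
      best[take] <- 0
    }
    objective <- c(objective, sum(best))
    if (identical(newAssign, assign)) { converged <- TRUE; break }
    assign <- newAssign
    sizes <- tabulate(assign, nbins = K)
    cs <- rowsum(mu, assign)
    present <- as.integer(rownames(cs))
    centers[present, ] <- cs / sizes[present]
    u1[present] <- sqrt(as.numeric(rowsum(s1^2, assign)) / sizes[present])
    u0[present] <- sqrt(as.numeric(rowsum(s0^2, assign)) / sizes[present])
  }
  if (!converged)
    warning("klClust did not converge in ", maxIter, " iterations")
  sizes <- tabulate(assign, nbins = K)
  full <- rep(NA_integer_, length(fits@geneIds))
  full[keep] <- assign
  new("ModuleSet", K = K, assignment = full, centers = centers,
      upsilon1 = u1, upsilon0 = u0, sizes = sizes,
      iterations = iter, converged = converged, objective = objective)
}

#' The mODP statistic
#'
#' Evaluates, for every row of the null-transformed data, the modular ODP
#' statistic
#' \deqn{S(y') = \frac{\sum_k g_k(y'; c_{k1}, \upsilon_{k1}) |R_k|}
#'                    {\sum_k f_k(y'; 0, \upsilon_{k0}) |R_k|}}
#' with Normal likelihoods, computed in log space via log-sum-exp so it is
#' overflow-free.  The \emph{log} of the ratio is returned; the statistic
#' is used only through its ranks.  Exactly 2Km log-likelihood terms are
#' evaluated (attribute \code{"evaluations"}).
#'
#' @param Yp null-transformed matrix (m x N) or a single vector.
#' @param modules a [ModuleSet-class].
#' @return numeric vector of log mODP statistics.
#' @export
modpStat <- function(Yp, modules) {
  if (is.null(dim(Yp))) Yp <- matrix(Yp, nrow = 1L)
  Yp <- as.matrix(Yp)
  N <- ncol(Yp)
  if (ncol(modules@centers) != N)
    stop("module centers and data have different lengths")
  lw <- log(modules@sizes)
  u1sq <- modules@upsilon1^2
  u0sq <- modules@upsilon0^2
  D2 <- .sqDistMatrix(Yp, modules@centers)
  logNum <- sweep(sweep(D2, 2L, -2 * u1sq, "/"), 2L,
                  lw - (N / 2) * log(2 * pi * u1sq), "+")
  rss <- rowSums(Yp^2)
  logDen <- outer(rss, -2 * u0sq, "/")
  logDen <- sweep(logDen, 2L, lw - (N / 2) * log(2 * pi * u0sq), "+")
  out <- unname(.rowLogSumExp(logNum) - .rowLogSumExp(logDen))
  attr(out, "evaluations") <- 2L * modules@K * nrow(Yp)
  out
}

#' Full estimated-ODP statistic (quadratic-cost reference)
#'
#' Exact evaluation of the estimated ODP statistic on null-transformed
#' data: the sum over \emph{all} genes of alternative Normal likelihoods
#' divided by the sum of null likelihoods,
#' \deqn{S(y'_i) = \frac{\sum_k g_k(y'_i; \hat\mu'_{k1},
#'   \hat\sigma_{k1})}{\sum_k f_k(y'_i; 0, \hat\sigma_{k0})}.}
#' Cost is O(m) per gene and O(m^2) overall, so this serves as the exact
#' reference that [modpStat()] approximates (with singleton modules the
#' two agree identically).  Returned on the log scale.
#'
#' @param Yp null-transformed matrix m x N.
#' @param fits the matching [GeneFitSet-class]; degenerate genes are
#'   excluded from the sums.
#' @return numeric vector of log statistics, one per row of \code{Yp}.
#' @export
odpStatFull <- function(Yp, fits) {
  if (is.null(dim(Yp))) Yp <- matrix(Yp, nrow = 1L)
  Yp <- as.matrix(Yp)
  N <- ncol(Yp)
  keep <- which(!fits@degenerate & fits@sigma1 > 0)
  mu <- fits@mu1[keep, , drop = FALSE] - fits@mu0[keep, , drop = FALSE]
  s1sq <- fits@sigma1[keep]^2
  s0sq <- fits@sigma0[keep]^2
  D2 <- .sqDistMatrix(Yp, mu)
  logNum <- sweep(sweep(D2, 2L, -2 * s1sq, "/"), 2L,
                  -(N / 2) * log(2 * pi * s1sq), "+")
  rss <- rowSums(Yp^2)
  logDen <- outer(rss, -2 * s0sq, "/")
  logDen <- sweep(logDen, 2L, -(N / 2) * log(2 * pi * s0sq), "+")
  unname(.rowLogSumExp(logNum) - .rowLogSumExp(logDen))
}
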