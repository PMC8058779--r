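#' Bootstrap empirical null distribution of mODP statistics
#'
#' The theoretical null distribution of ODP-type statistics is unknown, so
#' an empirical null is generated by a residual bootstrap.  For each
#' iteration, every gene's alternative-fit residuals are resampled over
#' measurement indices with replacement (independent indices per gene);
#' because alternative-fit residuals are deflated by the extra fitted
#' degrees of freedom relative to the null-transformed data, they are
#' first rescaled by \code{sqrt((N - df0) / (N - df1))}.  The resampled
#' data are then treated exactly like observed data: per-gene models are
#' refitted and the module parameters are re-estimated by the same
#' clustering update used in [klClust()], warm-started from the observed
#' modules (assignment + parameter passes to a fixpoint, capped at
#' \code{passes}).  This symmetric treatment is what calibrates the null:
#' observed genes are scored against modules fitted around them, so
#' bootstrap genes must be too.  All m statistics from all B iterations
#' are pooled on a common scale.
#'
#' @param Yp null-transformed data matrix (m x N).
#' @param design the [OdpDesign-class] used for the fits.
#' @param fits the matching [GeneFitSet-class] (provides residuals and
#'   model dimensions).
#' @param modules the observed [ModuleSet-class].
#' @param B number of bootstrap iterations (default 500).
#' @param seed integer seed; the same seed reproduces the pool exactly.
#' @param passes cap on warm-started re-clustering passes per iteration
#'   (default 3; assignments typically stabilize in 1-2).
#' @return numeric vector of pooled null statistics, length
#'   (clusterable m) x B.
#' @export
bootstrapNull <- function(Yp, design, fits, modules, B = 500L, seed = 1L,
                          passes = 3L) {
  Yp <- as.matrix(Yp)
  N <- ncol(Yp)
  if (N < 4L) stop("N = ", N, " is too small to resample (need N >= 4)")
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  keep <- which(!fits@degenerate & fits@sigma1 > 0)
  R <- Yp[keep, , drop = FALSE] -
    (fits@mu1[keep, , drop = FALSE] - fits@mu0[keep, , drop = FALSE])
  R <- R * sqrt((N - fits@df0) / (N - fits@df1))

  if (fits@weighted) {
    # per-gene weighted designs: no common subspace, use the full-rank path
    set.seed(seed)
    return(.bootPoolWeighted(R, design, fits@weights[keep, , drop = FALSE],
                             modules, B, passes))
  }

  K <- modules@K
  # orthonormal bases: null space and the alternative-only complement.
  # Module centers lie in the alternative-only space, so all distance
  # computations reduce to r = df1 - df0 coordinates.
  qa <- qr(cbind(design@XNull, design@XAlt))
  Qfull <- qr.Q(qa)[, seq_len(fits@df1), drop = FALSE]
  Q0 <- Qfull[, seq_len(fits@df0), drop = FALSE]
  Qr <- Qfull[, -seq_len(fits@df0), drop = FALSE]
  cenObs <- modules@centers %*% Qr        # K x r coordinates

  set.seed(seed)
  as.numeric(.bootPoolCpp(R, Q0, Qr, cenObs, modules@upsilon1^2,
                          modules@upsilon0^2, as.integer(modules@sizes),
                          B, as.integer(passes)))
}

# Bootstrap pool for precision-weighted fits.  Each gene has its own
# weighted design, so fitted values are computed from per-gene
# orthonormal bases (precomputed once) and all distances live in the
# full N-dimensional space.
.bootPoolWeighted <- function(R, design, sw, modules, B, passes) {
  m <- nrow(R); N <- ncol(R); K <- modules@K
  p0 <- ncol(design@XNull); p1 <- ncol(design@XAlt)
  Q0a <- array(0, c(m, N, p0))
  Q1a <- array(0, c(m, N, p1))
  for (i in seq_len(m)) {
    Q0a[i, , ] <- qr.Q(qr(design@XNull * sw[i, ]))
    Q1a[i, , ] <- qr.Q(qr(design@XAlt * sw[i, ]))
  }
  projRows <- function(Z, Qa, p) {
    F <- matrix(0, m, N)
    for (cc in seq_len(p)) {
      coef <- rowSums(Qa[, , cc] * Z)
      F <- F + Qa[, , cc] * coef
    }
    F
  }
  rowidx <- rep(seq_len(m), times = N)
  pool <- vector("list", B)
  for (b in seq_len(B)) {
    colidx <- sample.int(N, m * N, replace = TRUE)
    Z <- matrix(R[cbind(rowidx, colidx)], m, N)
    mu0b <- projRows(Z, Q0a, p0)
    mu1b <- projRows(Z, Q1a, p1)
    Zp <- Z - mu0b
    muA <- mu1b - mu0b
    s1sq <- pmax(rowSums((Z - mu1b)^2), 1e-300) / N
    s0sq <- pmax(rowSums(Zp^2), 1e-300) / N
    cen <- modules@centers
    u1sq <- modules@upsilon1^2
    u0sq <- modules@upsilon0^2
    sizes <- modules@sizes
    aold <- integer(0)
    for (it in seq_len(passes)) {
      delta <- .klMatrix(muA, sqrt(s1sq), cen, sqrt(u1sq))
      a <- max.col(-delta, ties.method = "first")
      if (identical(a, aold)) break
      aold <- a
      sizes <- tabulate(a, nbins = K)
      cs <- rowsum(muA, a)
      present <- as.integer(rownames(cs))
      cen[present, ] <- cs / sizes[present]
      u1sq[present] <- as.numeric(rowsum(s1sq, a)) / sizes[present]
      u0sq[present] <- as.numeric(rowsum(s0sq, a)) / sizes[present]
    }
    ok <- sizes > 0L
    lw <- log(sizes[ok])
    D2 <- .sqDistMatrix(Zp, cen[ok, , drop = FALSE])
    logNum <- sweep(sweep(D2, 2L, -2 * u1sq[ok], "/"), 2L,
                    lw - (N / 2) * log(2 * pi * u1sq[ok]), "+")
    logDen <- outer(rowSums(Zp^2), -2 * u0sq[ok], "/")
    logDen <- sweep(logDen, 2L,
                    lw - (N / 2) * log(2 * pi * u0sq[ok]), "+")
    pool[[b]] <- unname(.rowLogSumExp(logNum) - .rowLogSumExp(logDen))
  }
  unlist(pool)
}

#' Empirical p-values from a pooled null
#'
#' \eqn{p_i = (1 + \#\{pool \ge s_i\}) / (|pool| + 1)}; ties count as
#' greater-or-equal and the add-one correction keeps p-values strictly
#' positive (required by the pi0/q-value machinery).
#'
#' @param observed numeric vector of observed statistics.
#' @param pool numeric vector of pooled null statistics.
#' @return numeric vector of p-values in (0, 1].
#' @export
empiricalPvalues <- function(observed, pool) {
  if (!length(pool)) stop("null pool is empty")
  sp <- sort(pool)
  nGE <- length(sp) - findInterval(observed, sp, left.open = TRUE)
  (1 + nGE) / (length(sp) + 1)
}

#' Estimate the proportion of true null hypotheses
#'
#' Computes \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))}
#' over a grid of \eqn{\lambda}, smooths the sequence with a natural cubic
#' spline (3 df) and evaluates the smoother at the largest \eqn{\lambda};
#' the estimate is clamped to (0, 1].  With fewer than 100 p-values the
#' single fixed \eqn{\lambda = 0.5} estimate is used instead (with a
#' warning), since the smoother is unstable on small sets.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param lambda grid of tuning values (default 0.05 to 0.95 by 0.05).
#' @return scalar \eqn{\hat\pi_0} in (0, 1].
#' @export
estimatePi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(p > 0), all(p <= 1))
  m <- length(p)
  if (m < 100L) {
    warning("fewer than 100 p-values; using the fixed lambda = 0.5 estimate")
    pi0 <- sum(p > 0.5) / (m * 0.5)
    return(min(max(pi0, 1 / m), 1))
  }
  lambda <- sort(lambda)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- lm(pi0l ~ splines::ns(lambda, df = 3))
  pi0 <- predict(fit, newdata = data.frame(lambda = max(lambda)))[[1]]
  min(max(pi0, 1 / m), 1)
}

#' q-values by the pi0-adjusted step-up rule
#'
#' \eqn{q_i = \min_{t \ge p_i} \hat\pi_0 m t / \#\{p \le t\}}, enforced
#' monotone non-decreasing in p and capped at 1.  With \eqn{\hat\pi_0 = 1}
#' this reduces to Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param pi0 proportion of true nulls (default 1).
#' @return numeric vector of q-values, aligned with \code{p}.
#' @export
qValues <- function(p, pi0 = 1) {
  stopifnot(all(p > 0), all(p <= 1), pi0 > 0, pi0 <= 1)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  r <- rank(p, ties.method = "max")
  q <- pi0 * m * p / r
  q[o] <- cummin(q[o])
  pmin(q, 1)
}

# Grenander estimator: slopes of the least concave majorant of the
# empirical CDF of p-values, a monotone-decreasing density estimate.
.grenander <- function(p) {
  x <- sort(unique(p))
  cnt <- tabulate(match(p, x), nbins = length(x))
  w <- diff(c(0, x))                       # gap widths
  slope <- (cnt / length(p)) / w
  # weighted PAVA for a non-increasing sequence
  n <- length(slope)
  val <- slope; wt <- w; len <- rep(1L, n); k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- slope[i]; wt[k] <- w[i]; len[k] <- 1L
    while (k > 1L && val[k - 1L] < val[k]) {
      tot <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) / tot
      wt[k - 1L] <- tot
      len[k - 1L] <- len[k - 1L] + len[k]
      k <- k - 1L
    }
  }
  f <- rep(val[seq_len(k)], len[seq_len(k)])
  list(x = x, f = f)
}

#' Local false discovery rate from the p-value density
#'
#' Estimates the p-value density with the Grenander estimator (slopes of
#' the least concave majorant of the empirical CDF, a nonparametric
#' monotone-decreasing density) and returns
#' \eqn{\mathrm{lfdr}(p) = \min(1, \hat\pi_0 / \hat f(p))}.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param pi0 proportion of true nulls.
#' @return numeric vector of local FDRs in [0, 1].
#' @export
localFdr <- function(p, pi0 = 1) {
  stopifnot(all(p > 0), all(p <= 1))
  g <- .grenander(p)
  f <- g$f[match(p, g$x)]
  pmin(pmax(pi0 / pmax(f, 1e-12), 0), 1)
}
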