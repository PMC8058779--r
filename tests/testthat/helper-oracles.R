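# Independent oracle implementations used to check the package's fast
# paths.  These deliberately use brute force / textbook constructions.

# Natural cubic spline basis on knots k1..kk via the truncated power
# construction with explicit natural constraints (spans {1, x, d_j - d_{K-1}}
# with d_j(x) = [(x - k_j)_+^3 - (x - k_K)_+^3] / (k_K - k_j)).
truncPowerNaturalBasis <- function(x, knots) {
  k <- length(knots)
  dd <- function(j) {
    (pmax(x - knots[j], 0)^3 - pmax(x - knots[k], 0)^3) / (knots[k] - knots[j])
  }
  cols <- list(x)
  if (k > 2) {
    for (j in seq_len(k - 2)) cols[[j + 1]] <- dd(j) - dd(k - 1)
  }
  do.call(cbind, cols)
}

# Brute-force leave-one-out CV by refitting n times.
bruteLoocv <- function(v, X) {
  n <- length(v)
  errs <- vapply(seq_len(n), function(j) {
    fit <- lm.fit(X[-j, , drop = FALSE], v[-j])
    (v[j] - sum(X[j, ] * fit$coefficients))^2
  }, numeric(1))
  mean(errs)
}

# WLS through the normal equations.
wlsNormalEq <- function(y, X, w) {
  A <- crossprod(X, X * w)
  solve(A, crossprod(X, w * y))
}

# Symmetric KL between per-coordinate Normals by numerical integration.
numericSymKL <- function(muA, sigmaA, muB, sigmaB) {
  kl1 <- function(m1, s1, m2, s2) {
    integrate(function(z) {
      p <- dnorm(z, m1, s1)
      p * (dnorm(z, m1, s1, log = TRUE) - dnorm(z, m2, s2, log = TRUE))
    }, m1 - 10 * s1, m1 + 10 * s1, rel.tol = 1e-10)$value
  }
  sum(vapply(seq_along(muA), function(j) {
    kl1(muA[j], sigmaA, muB[j], sigmaB) + kl1(muB[j], sigmaB, muA[j], sigmaA)
  }, numeric(1)))
}

# Small independent-design study for reuse across tests.
makeIndependentStudy <- function(m = 100, N = 16, d = 2, seed = 1,
                                 pi0 = 0.5, snr = 2) {
  simulateStudy("independent", m = m, N = N, pi0 = pi0, U = max(1, m %/% 20),
                snr = snr, seed = seed)
}

quietStudy <- function(exprs, meta) suppressMessages(odpStudy(exprs, meta))
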