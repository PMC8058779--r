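# Shared small fixture: fits on null-transformed data ready for clustering
localFits <- function(m = 60, N = 12, seed = 2, snr = 2, pi0 = 0.5) {
  sim <- simulateStudy("independent", m = m, N = N, pi0 = pi0,
                       U = max(1, m %/% 20), snr = snr, seed = seed)
  meta <- as.data.frame(SummarizedExperiment::colData(sim$study))
  des <- buildStudy(meta, "independent", d = 2)
  Y <- SummarizedExperiment::assay(sim$study)
  fits <- fitModels(Y, des)
  list(fits = fits, Yp = nullTransform(Y, fits), des = des, sim = sim)
}

test_that("symmetric KL matches numerical integration and its axioms", {
  expect_equal(symmetricKL(c(1, 2), 1.5, c(1, 2), 1.5), 0)
  expect_equal(symmetricKL(c(1, 0), 1, c(0, 0), 1), 1)
  # oracle: numerically integrated KL(P||Q) + KL(Q||P) per coordinate
  set.seed(9)
  for (rep in 1:5) {
    muA <- rnorm(3); muB <- rnorm(3)
    sA <- rexp(1) + 0.5; sB <- rexp(1) + 0.5
    expect_equal(symmetricKL(muA, sA, muB, sB),
                 numericSymKL(muA, sA, muB, sB), tolerance = 1e-6)
    expect_equal(symmetricKL(muA, sA, muB, sB),
                 symmetricKL(muB, sB, muA, sA))
  }
})

test_that("singleton clustering reproduces per-gene parameters exactly", {
  L <- localFits(m = 25)
  keep <- !L$fits@degenerate
  mods <- klClust(L$fits, K = sum(keep), seed = 1)
  expect_true(all(table(moduleAssignments(mods)) == 1))
  perm <- moduleAssignments(mods)[keep]
  muA <- (L$fits@mu1 - L$fits@mu0)[keep, ]
  expect_lt(max(abs(mods@centers[perm, ] - muA)), 1e-12)
  expect_lt(max(abs(mods@upsilon1[perm] - L$fits@sigma1[keep])), 1e-12)
  expect_lt(max(abs(mods@upsilon0[perm] - L$fits@sigma0[keep])), 1e-12)
})

test_that("well-separated groups are recovered from any initialization", {
  N <- 10
  set.seed(77)
  p1 <- rnorm(N); p2 <- rnorm(N)
  p1 <- 10 * p1 / sqrt(sum(p1^2)); p2 <- 10 * p2 / sqrt(sum(p2^2))
  mu <- rbind(matrix(rep(p1, 50), 50, byrow = TRUE) + rnorm(50 * N, sd = .1),
              matrix(rep(p2, 50), 50, byrow = TRUE) + rnorm(50 * N, sd = .1))
  fits <- new("GeneFitSet", geneIds = paste0("g", 1:100),
              mu0 = matrix(0, 100, N), mu1 = mu,
              rss0 = rep(101, 100), rss1 = rep(N, 100),
              sigma0 = rep(3, 100), sigma1 = rep(1, 100),
              df0 = 1L, df1 = 3L, weighted = FALSE,
              weights = matrix(numeric(0), 0, 0),
              degenerate = rep(FALSE, 100))
  truthPart <- rep(1:2, each = 50)
  for (s in 1:20) {
    mods <- klClust(fits, K = 2, seed = s)
    a <- moduleAssignments(mods)
    agree <- max(mean(a == truthPart), mean(a == 3 - truthPart))
    expect_identical(agree, 1)
  }
})

test_that("clustering objective never ends above its starting value", {
  L <- localFits(m = 150, N = 14, seed = 4)
  mods <- klClust(L$fits, K = 12, seed = 9)
  obj <- mods@objective
  expect_true(mods@converged)
  expect_lte(obj[length(obj)], obj[1] + 1e-9)
})

test_that("K = 1 module gives the closed-form Normal log-ratio", {
  L <- localFits(m = 40)
  mods <- klClust(L$fits, K = 1, seed = 3)
  s <- modpStat(L$Yp, mods)
  cen <- mods@centers[1, ]
  u1 <- mods@upsilon1[1]; u0 <- mods@upsilon0[1]
  N <- ncol(L$Yp)
  manual <- (N * log(u0 / u1)) +
    rowSums(L$Yp^2) / (2 * u0^2) -
    rowSums(sweep(L$Yp, 2, cen)^2) / (2 * u1^2)
  expect_equal(as.numeric(s), unname(manual), tolerance = 1e-10)
})

test_that("module-size rescaling and relabeling leave the statistic unchanged", {
  L <- localFits(m = 50)
  mods <- klClust(L$fits, K = 5, seed = 2)
  s0 <- modpStat(L$Yp, mods)
  m7 <- mods; m7@sizes <- mods@sizes * 7L
  expect_equal(as.numeric(modpStat(L$Yp, m7)), as.numeric(s0),
               tolerance = 1e-12)
  perm <- sample(5)
  mp <- mods
  mp@centers <- mods@centers[perm, ]
  mp@upsilon1 <- mods@upsilon1[perm]
  mp@upsilon0 <- mods@upsilon0[perm]
  mp@sizes <- mods@sizes[perm]
  mp@assignment <- order(perm)[mods@assignment]
  expect_equal(as.numeric(modpStat(L$Yp, mp)), as.numeric(s0),
               tolerance = 1e-12)
})

test_that("singleton modules reproduce the full estimated-ODP statistic", {
  L <- localFits(m = 200, N = 16, seed = 6)
  keep <- !L$fits@degenerate
  mods <- klClust(L$fits, K = sum(keep), seed = 1)
  sModp <- modpStat(L$Yp, mods)
  sFull <- odpStatFull(L$Yp, L$fits)
  expect_lt(max(abs(as.numeric(sModp) - sFull)), 1e-10)
})

test_that("statistic evaluation touches exactly 2Km likelihood terms", {
  L <- localFits(m = 80)
  mods <- klClust(L$fits, K = 10, seed = 1)
  s <- modpStat(L$Yp, mods)
  expect_identical(attr(s, "evaluations"), 2L * 10L * 80L)
})

test_that("identical genes receive identical statistics", {
  L <- localFits(m = 30)
  Yp <- L$Yp[rep(1, 5), ]
  s <- modpStat(Yp, klClust(L$fits, K = 4, seed = 2))
  expect_identical(max(s) - min(s), 0)
})

test_that("full ODP statistic is permutation invariant and reduces to the likelihood ratio", {
  L <- localFits(m = 40, seed = 8)
  s1 <- odpStatFull(L$Yp, L$fits)
  # permuting gene order permutes outputs identically
  perm <- sample(40)
  fitsP <- L$fits
  fitsP@geneIds <- L$fits@geneIds[perm]
  fitsP@mu0 <- L$fits@mu0[perm, ]; fitsP@mu1 <- L$fits@mu1[perm, ]
  fitsP@rss0 <- L$fits@rss0[perm]; fitsP@rss1 <- L$fits@rss1[perm]
  fitsP@sigma0 <- L$fits@sigma0[perm]; fitsP@sigma1 <- L$fits@sigma1[perm]
  fitsP@degenerate <- L$fits@degenerate[perm]
  s2 <- odpStatFull(L$Yp, fitsP)
  expect_equal(s2, s1, tolerance = 1e-12)
  # m = 1: Neyman-Pearson single-test likelihood ratio
  one <- fitModels(L$Yp[3, , drop = FALSE], L$des)
  sOne <- odpStatFull(L$Yp[3, , drop = FALSE], one)
  y <- L$Yp[3, ]
  N <- length(y)
  lr <- sum(dnorm(y, (one@mu1 - one@mu0)[1, ], one@sigma1[1], log = TRUE)) -
    sum(dnorm(y, 0, one@sigma0[1], log = TRUE))
  expect_equal(sOne, lr, tolerance = 1e-10)
})

test_that("mODP ranks agree with the full estimated ODP at moderate K", {
  L <- localFits(m = 200, N = 16, seed = 12, snr = 2)
  mods <- klClust(L$fits, K = 50, seed = 3)
  sM <- as.numeric(modpStat(L$Yp, mods))
  sF <- odpStatFull(L$Yp, L$fits)
  keep <- !L$fits@degenerate
  expect_gt(cor(sM[keep], sF[keep], method = "spearman"), 0.95)
})
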