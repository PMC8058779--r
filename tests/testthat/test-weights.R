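test_that("logCPM matches direct arithmetic and is library-size invariant", {
  counts <- matrix(c(0, 500000, 500000), 3, 1)   # library size 1e6
  lc <- logCPM(counts)
  expect_equal(lc[1, 1], log2(0.5 * 1e6 / (1e6 + 1)), tolerance = 1e-12)
  expect_equal(lc[1, 1], -1.0000014, tolerance = 1e-6)
  # a count at half the library size lands at ~ log2(5e5 cpm)
  expect_equal(lc[2, 1], log2(5e5), tolerance = 1e-5)

  # doubling all counts in a large library barely shifts logCPM
  big <- matrix(rpois(200, 500) + 1, 100, 2)
  big[1, ] <- 1e6
  shift <- logCPM(big * 2) - logCPM(big)
  expect_lt(max(abs(shift)), 1e-3)
  expect_error(logCPM(matrix(-1, 2, 2)), "nonnegative")
})

test_that("low-count filter keeps genes at the >= 10 reads boundary", {
  counts <- rbind(a = c(4, 5), b = c(5, 5), c = c(6, 5))  # totals 9, 10, 11
  expect_identical(unname(filterLowCounts(counts, 10)),
                   c(FALSE, TRUE, TRUE))
  expect_true(all(filterLowCounts(counts, 0)))
  expect_false(any(filterLowCounts(matrix(0, 3, 4), 1)))
})

test_that("weights are near-constant under homoscedastic truth", {
  set.seed(8)
  N <- 16
  des <- buildStudy(data.frame(group = rep(c("a", "b"), each = N / 2)),
                    "static")
  # log-Normal counts: constant variance on the log scale regardless of
  # abundance, so the mean-variance trend is flat
  mu <- rnorm(3000, 9, 1.5)
  counts <- matrix(round(2^(mu + rnorm(3000 * N, sd = 0.4))), 3000, N)
  W <- estimateWeights(counts, des)
  expect_true(all(W > 0))
  expect_lt(sd(W) / mean(W), 0.1)
})

test_that("estimated weights track true inverse variances for overdispersed counts", {
  sim <- simulateCounts(m = 2000, N = 16, pi0 = 1, U = 1, phi = 0.2,
                        seed = 42)
  des <- buildStudy(sim$sampleMeta, "static")
  keep <- filterLowCounts(sim$counts, 10)
  counts <- sim$counts[keep, ]
  W <- estimateWeights(counts, des)
  # delta method: var(log2 cpm) ~ (1/mu + phi) / log(2)^2, mu = count mean
  mu <- rowMeans(counts)
  trueVar <- (1 / mu + 0.2) / log(2)^2
  rho <- cor(rowMeans(W), 1 / trueVar, method = "spearman")
  expect_gt(rho, 0.6)
})

test_that("small gene sets fall back to unit weights with a warning", {
  des <- buildStudy(data.frame(group = rep(c("a", "b"), each = 3)), "static")
  counts <- matrix(rpois(10 * 6, 50), 10, 6)
  expect_warning(W <- estimateWeights(counts, des), "fewer than 50")
  expect_true(all(W == 1))
})

test_that("the sqrt-weight transform reduces WLS to OLS exactly", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 12
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rnorm(n)
    w <- rexp(n) + 0.1
    tr <- weightTransform(y, X, w)
    bOls <- qr.coef(qr(tr$design), tr$y)
    bWls <- wlsNormalEq(y, X, w)
    expect_lt(max(abs(bOls - as.numeric(bWls))), 1e-10)
  }
  # unit weights are the identity transform
  tr <- weightTransform(1:4, cbind(1, 1:4), rep(1, 4))
  expect_identical(tr$y, as.numeric(1:4))
  # constant weights leave coefficients unchanged and scale the RSS
  y <- rnorm(8); X <- cbind(1, 1:8)
  tr <- weightTransform(y, X, rep(4, 8))
  f1 <- lm.fit(X, y); f2 <- lm.fit(tr$design, tr$y)
  expect_lt(max(abs(f1$coefficients - f2$coefficients)), 1e-10)
  expect_equal(sum(f2$residuals^2), 4 * sum(f1$residuals^2))
})

test_that("weighted mODP controls the FDR when the precision weights are known", {
  # heteroscedastic Gaussian truth; the true inverse variances are
  # supplied, isolating the weighted machinery from weight estimation
  fdp <- vapply(1:25, function(s) {
    set.seed(5000 + s)
    m <- 800; N <- 16
    grp <- rep(c("ctrl", "trt"), each = 8)
    sdMat <- outer(sqrt(4 / rchisq(m, 4)), runif(N, 0.5, 2))
    m1 <- 80
    delta <- rnorm(10)[sample.int(10, m1, TRUE)] * 2
    mu <- matrix(0, m, N); mu[1:m1, grp == "trt"] <- delta
    Y <- mu + matrix(rnorm(m * N), m, N) * sdMat
    rownames(Y) <- sprintf("g%04d", 1:m)
    study <- quietStudy(Y, data.frame(sample_id = paste0("s", 1:N),
                                      group = grp))
    res <- odp(study, config = odpConfig("static", K = 50, B = 40,
                                         seed = 5000 + s,
                                         weights = sdMat^-2))
    truth <- data.frame(gene_id = rownames(Y),
                        status = rep(c("alternative", "null"),
                                     c(m1, m - m1)))
    evaluateCalls(res, truth, cutoffs = 0.1)$fdp
  }, numeric(1))
  expect_lte(mean(fdp), 0.12)
})

test_that("estimated-weight pipeline is calibrated on global-null counts", {
  sim <- simulateCounts(m = 1000, N = 16, pi0 = 1, U = 1, phi = 0.2,
                        seed = 4001)
  study <- quietStudy(sim$counts, sim$sampleMeta)
  res <- odp(study, config = odpConfig("static", K = 50, B = 50,
                                       seed = 4001, weights = "estimate"))
  ks <- suppressWarnings(
    ks.test(resultsTable(res)$p_value, "punif")$statistic)
  expect_lt(ks, 0.06)
})

test_that("mODP statistics are invariant to rescaling all weights", {
  sim <- simulateCounts(m = 300, N = 12, pi0 = 0.8, U = 3, phi = 0.1,
                        seed = 3)
  des <- buildStudy(sim$sampleMeta, "static")
  Y <- logCPM(sim$counts)
  W <- estimateWeights(sim$counts, des)
  statsFor <- function(W) {
    fits <- fitModels(Y, des, weights = W)
    Yp <- nullTransform(Y, fits)
    mods <- klClust(fits, K = 20, seed = 5)
    s <- modpStat(Yp, mods)
    attributes(s) <- NULL
    s
  }
  expect_equal(statsFor(W), statsFor(5 * W), tolerance = 1e-8)
})
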