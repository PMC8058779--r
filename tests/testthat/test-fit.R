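test_that("per-gene fits reproduce the hand-computed two-group ANOVA", {
  des <- buildStudy(data.frame(group = c("a", "a", "b", "b")), "static")
  fits <- fitModels(c(1, 2, 3, 4), des)
  expect_equal(fits@rss0, 5)
  expect_equal(fits@rss1, 1)
  expect_equal(fits@sigma0^2, 1.25)
  expect_equal(fits@sigma1^2, 0.25)
  expect_equal(as.numeric(fits@mu1), c(1.5, 1.5, 3.5, 3.5))
})

test_that("constant genes are flagged degenerate with zero residuals", {
  des <- buildStudy(data.frame(group = c("a", "a", "b", "b")), "static")
  fits <- fitModels(rbind(g1 = rep(2, 4), g2 = c(1, 2, 3, 4)), des)
  expect_identical(fits@degenerate, c(TRUE, FALSE))
  expect_equal(fits@rss0[1], 0)
  expect_equal(fits@rss1[1], 0)
})

test_that("constant weights reproduce the unweighted fit", {
  sim <- makeIndependentStudy(m = 30, N = 12)
  meta <- as.data.frame(SummarizedExperiment::colData(sim$study))
  des <- buildStudy(meta, "independent", d = 2)
  Y <- SummarizedExperiment::assay(sim$study)
  f0 <- fitModels(Y, des)
  fw <- fitModels(Y, des, weights = matrix(3, nrow(Y), ncol(Y)))
  # fitted means scale by sqrt(w); on the common scale they agree
  expect_lt(max(abs(fw@mu1 / sqrt(3) - f0@mu1)), 1e-10)
  expect_lt(max(abs(fw@rss1 / 3 - f0@rss1)), 1e-8)
})

test_that("nestedness of RSS holds on random data with equality iff orthogonal", {
  set.seed(11)
  des <- buildStudy(data.frame(covariate = seq(0, 1, length.out = 15)),
                    "independent", d = 3)
  Y <- matrix(rnorm(50 * 15), 50, 15)
  fits <- fitModels(Y, des)
  expect_true(all(fits@rss1 <= fits@rss0 + 1e-9))
  # a row orthogonal to the alternative-only space has rss0 == rss1
  X1 <- altMatrix(des)
  y <- rnorm(15)
  yOrth <- y - qr.fitted(qr(X1), y)  # in the orthogonal complement
  fo <- fitModels(yOrth + mean(y), des)
  expect_lt(abs(fo@rss0 - fo@rss1), 1e-9)
})

test_that("eigen-genes recover rank-1 structure and Gram-matrix singular values", {
  set.seed(5)
  v <- rnorm(10)
  Y <- outer(rnorm(40, mean = 2), v)
  eg <- eigenGenes(Y, E = 2)
  vc <- v - mean(v)
  cosang <- abs(sum(eg[1, ] * vc)) / sqrt(sum(eg[1, ]^2) * sum(vc^2))
  expect_gt(cosang, 1 - 1e-8)
  # singular values match eigenvalues of the Gram matrix
  Y2 <- matrix(rnorm(200), 20, 10)
  eg2 <- eigenGenes(Y2, E = 4)
  Yc <- Y2 - rowMeans(Y2)
  lam <- sort(eigen(crossprod(Yc), symmetric = TRUE)$values,
              decreasing = TRUE)
  expect_lt(max(abs(attr(eg2, "singularValues") - sqrt(lam[1:4]))), 1e-8)
})

test_that("LOOCV shortcut equals brute-force refits and hand cases", {
  set.seed(21)
  for (rep in 1:5) {
    x <- sort(runif(20))
    X <- cbind(1, x)
    v <- 2 * x + rnorm(20)
    expect_lt(abs(loocvError(v, X) - bruteLoocv(v, X)), 1e-10)
  }
  # intercept-only hand case: residuals (-1,-1,2), leverages 1/3
  expect_equal(loocvError(c(0, 0, 3), matrix(1, 3, 1)), 4.5)
  # exact fit gives zero error
  x <- 1:6
  expect_equal(loocvError(2 + 3 * x, cbind(1, x)), 0)
  # saturated leverage reports infinite error
  expect_identical(loocvError(c(1, 2), diag(2)), Inf)
})

test_that("spline dimension selection favors the truth and breaks ties to smaller d", {
  x <- seq(0, 1, length.out = 25)
  # exactly linear eigen-structure selects d = 1
  Ylin <- outer(rnorm(30), x) + rnorm(30)
  expect_identical(as.integer(selectDimension(Ylin, x, D = 4)), 1L)
  # d = 2 truth with noise sigma = 0.1 is recovered in >= 90% of
  # replicates; E matches the rank of the generating basis (a 2-dim truth
  # yields exactly 2 structured eigen-genes)
  # curve coefficients are bounded away from zero so the generating
  # dimension is unambiguous
  S2 <- naturalCubicBasis(x, knotPositions(x, 3))
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    coefs <- matrix(sample(c(-1, 1), 24, TRUE) * runif(24, 0.5, 1.5), 12)
    curves <- coefs %*% t(S2)
    Y <- curves[rep(1:12, each = 3), ] +
      matrix(rnorm(36 * 25, sd = 0.1), 36)
    if (as.integer(selectDimension(Y, x, D = 4, E = 2)) == 2L)
      hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("dimension search is truncated and split-aware", {
  x <- rep(1:4, 5)
  Y <- matrix(rnorm(10 * 20), 10, 20)
  expect_warning(selectDimension(Y, x, D = 10), "truncated")
  splits <- rep(c("a", "b"), each = 10)
  x2 <- rep(seq(0, 1, length.out = 10), 2)
  d <- selectDimension(matrix(rnorm(200), 10, 20), x2, D = 2,
                       splits = splits)
  expect_length(attr(d, "cvErrors"), 2L)
})

test_that("null transform removes the null signal and preserves the F statistic", {
  set.seed(31)
  des <- buildStudy(data.frame(covariate = seq(0, 1, length.out = 12)),
                    "independent", d = 2)
  Y <- matrix(rnorm(20 * 12, mean = 5), 20, 12)
  fits <- fitModels(Y, des)
  Yp <- nullTransform(Y, fits)
  # intercept-only null: rows are centered
  expect_lt(max(abs(rowMeans(Yp))), 1e-12)
  # null-orthogonal data pass through unchanged
  expect_lt(max(abs(nullTransform(Yp, fitModels(Yp, des)) - Yp)), 1e-10)
  # F computed from transformed data equals F from the original data
  fits2 <- fitModels(Yp, des)
  f1 <- fStatistic(fits)$stat
  f2 <- fStatistic(fits2)$stat
  expect_lt(max(abs(f1 - f2)), 1e-10)
  # refitting the alternative on transformed data equals mu1 - mu0
  expect_lt(max(abs(fits2@mu1 - (fits@mu1 - fits@mu0))), 1e-10)
  expect_lt(max(abs(fits2@sigma1 - fits@sigma1)), 1e-12)
})

test_that("dimension selection is invariant to gene order and positive scaling", {
  set.seed(61)
  x <- seq(0, 1, length.out = 20)
  S2 <- naturalCubicBasis(x, knotPositions(x, 3))
  Y <- matrix(rnorm(15 * 2), 15) %*% t(S2) + matrix(rnorm(300, sd = .2), 15)
  d1 <- as.integer(selectDimension(Y, x, D = 4))
  d2 <- as.integer(selectDimension(Y[sample(15), ], x, D = 4))
  d3 <- as.integer(selectDimension(7 * Y, x, D = 4))
  expect_identical(d1, d2)
  expect_identical(d1, d3)
})
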