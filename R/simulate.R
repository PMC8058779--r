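#' Simulate a gene expression study with known truth
#'
#' Generates log-scale expression data with the structure used throughout
#' the package's validation: a fixed proportion \code{pi0} of true-null
#' genes, \code{U} unique alternative mean profiles shared among the
#' alternative genes (co-expression), per-gene noise scales drawn from a
#' scaled inverse-chi-square distribution, and iid Normal noise at a
#' controlled signal-to-noise ratio.  Each alternative gene's profile is
#' scaled so that \eqn{\|signal\| / (\sigma_i \sqrt N) = snr}, i.e.
#' \code{snr} is the per-observation RMS signal-to-noise ratio.
#'
#' Designs: \code{independent} places N subjects on an even covariate
#' grid and draws profiles as random coefficients on a 3-dimensional
#' natural cubic basis; \code{static} uses two equal groups with
#' profile-specific mean differences (the profile draw scales the common
#' snr, so \code{snr} is the average scale); \code{longitudinal} measures
#' \code{N / nTime} individuals at \code{nTime} time points in two
#' classes, alternative profiles being class-difference curves, with
#' per-individual random intercepts of scale \code{gammaSd} times
#' \eqn{\sigma_i}.
#'
#' @param design study design kind.
#' @param m number of genes; \code{N} number of measurements.
#' @param pi0 proportion of true nulls; \code{U} number of unique
#'   alternative profiles (requires \code{U <= m (1 - pi0)}).
#' @param snr signal-to-noise ratio (> 0).
#' @param seed integer seed; the same seed reproduces the study exactly.
#' @param sigmaDf,sigmaScale parameters of the scaled inverse-chi-square
#'   draw of per-gene variances (defaults 4 and 1).
#' @param gammaSd longitudinal individual-effect scale relative to
#'   \eqn{\sigma_i}.
#' @param nTime time points per individual (longitudinal only; must
#'   divide N).
#' @return list with elements \code{study} (a SummarizedExperiment with
#'   assay \code{exprs} and the sample metadata as colData) and
#'   \code{truth} (data.frame: gene_id, status, profile, sigma; the true
#'   mean matrix as attribute \code{"means"}).
#' @export
simulateStudy <- function(design = c("independent", "static", "longitudinal"),
                          m = 2000L, N = 20L, pi0 = 0.8, U = 10L, snr = 1,
                          seed = 1L, sigmaDf = 4, sigmaScale = 1,
                          gammaSd = 0.5, nTime = 5L) {
  design <- match.arg(design)
  stopifnot(snr > 0, pi0 >= 0, pi0 <= 1)
  m <- as.integer(m); N <- as.integer(N); U <- as.integer(U)
  m1 <- m - round(m * pi0)
  if (U > max(m1, 1L) && m1 > 0L)
    stop("U = ", U, " exceeds the ", m1, " alternative genes")
  set.seed(seed)

  meta <- switch(design,
    independent = data.frame(sample_id = sprintf("s%02d", seq_len(N)),
                             covariate = seq(0, 1, length.out = N)),
    static = data.frame(sample_id = sprintf("s%02d", seq_len(N)),
                        group = rep(c("ctrl", "trt"), c(ceiling(N / 2),
                                                        floor(N / 2)))),
    longitudinal = {
      if (N %% nTime != 0L) stop("N must be a multiple of nTime")
      nInd <- N %/% nTime
      if (nInd < 2L) stop("need at least 2 individuals")
      data.frame(sample_id = sprintf("s%02d", seq_len(N)),
                 covariate = rep(seq(0, 1, length.out = nTime), nInd),
                 individual = rep(sprintf("i%02d", seq_len(nInd)),
                                  each = nTime),
                 group = rep(rep(c("ctrl", "trt"), length.out = nInd),
                             each = nTime))
    })

  # unit-norm profile curves in the alternative-only space
  profiles <- matrix(0, max(U, 1L), N)
  if (design == "independent" || design == "longitudinal") {
    x <- meta$covariate
    S <- .basisOfDim(x, 3L)
    if (design == "longitudinal") {
      pairL <- buildStudy(meta, "longitudinal", d = 3L)
      Qa <- .projector(pairL@XAlt)$Q
      Q0 <- .projector(pairL@XNull)$Q
    }
    for (u in seq_len(U)) {
      repeat {
        cu <- as.numeric(S %*% rnorm(ncol(S)))
        if (design == "independent") cu <- cu - mean(cu)
        if (design == "longitudinal") {
          # class-difference curve: alternative-only component of a
          # treated-class-specific curve
          cu <- cu * (meta$group == "trt")
          cu <- as.numeric(cu %*% Qa %*% t(Qa)) -
            as.numeric(cu %*% Q0 %*% t(Q0))
        }
        if (sqrt(sum(cu^2)) > 1e-8) break
      }
      profiles[u, ] <- cu / sqrt(sum(cu^2))
    }
  } else {
    g <- as.numeric(meta$group == "trt")
    v <- g - mean(g)
    v <- v / sqrt(sum(v^2))
    amp <- rnorm(U)
    for (u in seq_len(U)) profiles[u, ] <- amp[u] * v
  }

  sigma <- sqrt(sigmaDf * sigmaScale / rchisq(m, sigmaDf))
  status <- rep(c("null", "alternative"), c(m - m1, m1))
  profIdx <- rep(NA_integer_, m)
  if (m1 > 0L) profIdx[status == "alternative"] <- sample.int(U, m1,
                                                              replace = TRUE)
  baseline <- rnorm(m, 0, 1)
  means <- matrix(rep(baseline, N), m, N)
  alt <- which(status == "alternative")
  if (length(alt)) {
    means[alt, ] <- means[alt, , drop = FALSE] +
      profiles[profIdx[alt], , drop = FALSE] * (snr * sigma[alt] * sqrt(N))
  }
  Y <- means + matrix(rnorm(m * N), m, N) * sigma
  if (design == "longitudinal" && gammaSd > 0) {
    ind <- factor(meta$individual)
    G <- matrix(rnorm(m * nlevels(ind)), m) * (gammaSd * sigma)
    Y <- Y + G[, as.integer(ind)]
  }
  ids <- sprintf("gene_%05d", seq_len(m))
  rownames(Y) <- ids
  colnames(Y) <- meta$sample_id
  truth <- data.frame(gene_id = ids, status = status, profile = profIdx,
                      sigma = sigma, stringsAsFactors = FALSE)
  attr(truth, "means") <- means
  attr(truth, "params") <- list(design = design, m = m, N = N, pi0 = pi0,
                                U = U, snr = snr, seed = seed)
  list(study = SummarizedExperiment(assays = list(exprs = Y),
                                    colData = DataFrame(meta)),
       truth = truth)
}

#' Simulate over-dispersed RNA-seq counts with known truth
#'
#' Static two-group negative-binomial counts with variance
#' \eqn{\mu + \phi \mu^2} (Poisson when \code{phi = 0}).  Baseline
#' abundances are drawn from a gamma distribution, alternative genes get
#' profile-specific log2 fold changes between the groups.  This exercises
#' the precision-weight path end to end.
#'
#' @param m,N genes and samples; \code{pi0}, \code{U} as in
#'   [simulateStudy()].
#' @param phi over-dispersion (>= 0).
#' @param seed integer seed.
#' @param libSize expected library size per sample.
#' @param lfcSd standard deviation of the per-profile log2 fold change.
#' @return list with \code{counts} (integer matrix), \code{sampleMeta}
#'   and \code{truth} as in [simulateStudy()].
#' @export
simulateCounts <- function(m = 2000L, N = 16L, pi0 = 0.9, U = 10L,
                           phi = 0.2, seed = 1L, libSize = 1e6,
                           lfcSd = 1) {
  stopifnot(phi >= 0)
  m <- as.integer(m); N <- as.integer(N)
  set.seed(seed)
  m1 <- m - round(m * pi0)
  grp <- rep(c("ctrl", "trt"), c(ceiling(N / 2), floor(N / 2)))
  abund <- rgamma(m, shape = 0.7, rate = 1)
  abund <- abund / sum(abund)
  lfc <- rnorm(U, 0, lfcSd)
  status <- rep(c("null", "alternative"), c(m - m1, m1))
  profIdx <- rep(NA_integer_, m)
  if (m1 > 0L) profIdx[status == "alternative"] <- sample.int(U, m1,
                                                              replace = TRUE)
  foldRow <- rep(1, m)
  foldRow[status == "alternative"] <- 2^lfc[profIdx[status == "alternative"]]
  mu <- outer(abund, rep(libSize, N))
  mu[, grp == "trt"] <- mu[, grp == "trt"] * foldRow
  counts <- if (phi == 0) {
    matrix(rpois(m * N, lambda = mu), m, N)
  } else {
    matrix(rnbinom(m * N, mu = mu, size = 1 / phi), m, N)
  }
  ids <- sprintf("gene_%05d", seq_len(m))
  rownames(counts) <- ids
  colnames(counts) <- sprintf("s%02d", seq_len(N))
  truth <- data.frame(gene_id = ids, status = status, profile = profIdx,
                      stringsAsFactors = FALSE)
  attr(truth, "params") <- list(m = m, N = N, pi0 = pi0, U = U, phi = phi,
                                seed = seed)
  list(counts = counts,
       sampleMeta = data.frame(sample_id = colnames(counts), group = grp),
       truth = truth)
}

#' Realized false discovery proportion and power at q-value cutoffs
#'
#' Compares significance calls against simulation truth: at each cutoff
#' \code{c}, discoveries are genes with \eqn{q \le c}; FDP is the
#' fraction of discoveries that are truly null (0 when there are none)
#' and power is the fraction of alternative genes discovered.
#'
#' @param q named numeric vector of q-values, or an [OdpResults-class].
#' @param truth truth data.frame from [simulateStudy()].
#' @param cutoffs q-value thresholds (default spans 0.0001 to 0.1).
#' @return data.frame with columns \code{cutoff}, \code{discoveries},
#'   \code{fdp}, \code{power}.
#' @export
evaluateCalls <- function(q, truth,
                          cutoffs = c(1e-4, 1e-3, 0.01, 0.05, 0.1)) {
  if (is(q, "OdpResults")) {
    tab <- resultsTable(q)
    q <- setNames(tab$q_value, tab$gene_id)
  }
  if (is.null(names(q))) names(q) <- truth$gene_id
  q <- q[truth$gene_id]
  isNull <- truth$status == "null"
  m1 <- sum(!isNull)
  rows <- lapply(cutoffs, function(cc) {
    disc <- q <= cc
    nd <- sum(disc)
    data.frame(cutoff = cc, discoveries = nd,
               fdp = if (nd) sum(disc & isNull) / nd else 0,
               power = if (m1) sum(disc & !isNull) / m1 else 0)
  })
  do.call(rbind, rows)
}
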