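#' Tuning parameters for the mODP pipeline
#'
#' Bundles the pipeline defaults: K = 800 modules, B = 500 bootstrap
#' iterations, E = 4 eigen-genes, dimension search depth D = 4, minimum
#' total count 10 for the RNA-seq filter.  A single seed fans out to
#' stage-specific sub-streams (clustering initialization, bootstrap) so
#' stages are independently reproducible.
#'
#' @param design study design kind (see [buildStudy()]).
#' @param d spline dimension, or \code{"auto"} to select it by eigen-gene
#'   cross-validation.
#' @param K number of modules; \code{B} bootstrap iterations; \code{E}
#'   eigen-genes; \code{D} maximum dimension searched.
#' @param seed integer master seed.
#' @param weights \code{"none"}, \code{"estimate"} (treat the assay as raw
#'   counts and estimate precision weights), or a numeric weight matrix.
#' @param minCount total-count filter threshold used with
#'   \code{weights = "estimate"}.
#' @param maxIter clustering iteration cap.
#' @param test hypothesis for longitudinal designs (see [buildStudy()]).
#' @return a named list of class \code{"odpConfig"}.
#' @export
odpConfig <- function(design = c("static", "independent", "longitudinal"),
                      d = "auto", K = 800L, B = 500L, E = 4L, D = 4L,
                      seed = 1L, weights = "none", minCount = 10L,
                      maxIter = 100L, test = "group-difference") {
  structure(list(design = match.arg(design), d = d, K = as.integer(K),
                 B = as.integer(B), E = as.integer(E), D = as.integer(D),
                 seed = as.integer(seed), weights = weights,
                 minCount = as.integer(minCount),
                 maxIter = as.integer(maxIter), test = test),
            class = "odpConfig")
}

# resolve inputs shared by odp() and runComparison(); returns the working
# matrix (logCPM + filter applied when counts), metadata, design and
# weight matrix
.prepareStudy <- function(study, config, design = NULL) {
  if (is(study, "SummarizedExperiment")) {
    Y <- assay(study)
    meta <- as.data.frame(colData(study))
  } else if (is.list(study) && !is.null(study$study)) {
    Y <- assay(study$study)
    meta <- as.data.frame(colData(study$study))
  } else {
    stop("study must be a SummarizedExperiment (see odpStudy())")
  }
  W <- NULL
  counts <- NULL
  wmode <- "none"
  if (is.matrix(config$weights)) {
    W <- config$weights
    wmode <- "file"
  } else if (identical(config$weights, "estimate")) {
    counts <- Y
    keepGenes <- filterLowCounts(counts, config$minCount)
    counts <- counts[keepGenes, , drop = FALSE]
    Y <- logCPM(counts)
    wmode <- "estimate"
  }

  dHat <- NA_integer_
  if (is.null(design)) {
    if (config$design == "static") {
      dHat <- 0L
      design <- buildStudy(meta, "static")
    } else {
      dHat <- if (identical(config$d, "auto")) {
        splits <- if (config$design == "longitudinal" &&
                      config$test == "group-difference") meta$group else NULL
        as.integer(selectDimension(Y, meta$covariate, D = config$D,
                                   E = config$E, splits = splits))
      } else as.integer(config$d)
      design <- buildStudy(meta, config$design, d = dHat, test = config$test)
    }
  } else {
    dHat <- design@d
  }
  if (wmode == "estimate") W <- estimateWeights(counts, design)
  list(Y = Y, meta = meta, design = design, W = W, dHat = dHat,
       wmode = wmode)
}

#' Run the full mODP significance analysis
#'
#' Orchestrates the pipeline end to end: (optional) count filtering,
#' logCPM and precision-weight estimation; eigen-gene cross-validated
#' choice of the spline dimension; per-gene least-squares fits under the
#' nested models; subtraction of the fitted null model; KL module
#' clustering; the mODP statistic for every gene; a bootstrap empirical
#' null with pooled p-values; and pi0, q-value and local-FDR estimation.
#' Degenerate (constant) genes are reported with statistic \code{-Inf}
#' (log scale, i.e. a zero likelihood ratio) and p-value 1.
#'
#' @param study a SummarizedExperiment (see [odpStudy()] /
#'   [readExpression()]) or the list returned by [simulateStudy()].
#' @param config an [odpConfig()]; individual \code{...} arguments
#'   override its entries.
#' @param design optionally a pre-built [OdpDesign-class] (skips
#'   dimension selection).
#' @param ... passed to [odpConfig()] when \code{config} is missing.
#' @return an [OdpResults-class].
#' @export
#' @examples
#' sim <- simulateStudy("independent", m = 300, N = 16, pi0 = 0.8,
#'                      U = 5, snr = 1, seed = 7)
#' res <- odp(sim$study, config = odpConfig("independent", K = 40, B = 20,
#'                                          seed = 7))
#' res
odp <- function(study, config = NULL, design = NULL, ...) {
  if (is.null(config)) config <- odpConfig(...)
  prep <- .prepareStudy(study, config, design)
  Y <- prep$Y
  seeds <- .spawnSeeds(config$seed, 2L)

  fits <- fitModels(Y, prep$design, weights = prep$W)
  Yp <- nullTransform(Y, fits)
  K <- min(config$K, sum(!fits@degenerate & fits@sigma1 > 0))
  mods <- klClust(fits, K = K, seed = seeds[1], maxIter = config$maxIter)
  stat <- modpStat(Yp, mods)
  attributes(stat) <- NULL
  pool <- bootstrapNull(Yp, prep$design, fits, mods, B = config$B,
                        seed = seeds[2])

  ok <- !fits@degenerate
  p <- rep(1, length(stat))
  p[ok] <- empiricalPvalues(stat[ok], pool)
  stat[!ok] <- -Inf
  pi0 <- estimatePi0(p[ok])
  q <- qValues(p, pi0)
  lf <- localFdr(p, pi0)

  tab <- data.frame(gene_id = fits@geneIds, stat = stat, p_value = p,
                    q_value = q, lfdr = lf, stringsAsFactors = FALSE)
  cfg <- unclass(config)
  cfg$K <- K
  cfg$weights <- prep$wmode
  cfg$clusterSeed <- seeds[1]
  cfg$bootSeed <- seeds[2]
  new("OdpResults", table = tab, pi0 = pi0, dHat = prep$dHat,
      modules = mods, config = cfg, poolSize = length(pool))
}

#' Benchmark mODP against F-type tests on one dataset
#'
#' Runs five testing procedures on identical inputs with shared seeds:
#' the mODP pipeline, the parametric F-test and moderated F-test, and
#' their bootstrap empirical-null variants.  Each method's p-values are
#' converted to q-values with its own pi0 estimate.
#'
#' @inheritParams odp
#' @return data.frame with columns \code{gene_id}, \code{method}
#'   (\code{"modp"}, \code{"f"}, \code{"modf"}, \code{"boot_f"},
#'   \code{"boot_modf"}), \code{stat}, \code{p_value}, \code{q_value}.
#' @export
runComparison <- function(study, config = NULL, design = NULL, ...) {
  if (is.null(config)) config <- odpConfig(...)
  prep <- .prepareStudy(study, config, design)
  res <- odp(study, config = config, design = prep$design)

  fits <- fitModels(prep$Y, prep$design, weights = prep$W)
  seeds <- .spawnSeeds(config$seed, 2L)
  pieces <- list()
  addMethod <- function(name, tab) {
    pi0 <- estimatePi0(tab$p_value)
    data.frame(gene_id = tab$gene_id, method = name, stat = tab$stat,
               p_value = tab$p_value, q_value = qValues(tab$p_value, pi0),
               stringsAsFactors = FALSE)
  }
  mt <- resultsTable(res)
  pieces$modp <- data.frame(gene_id = mt$gene_id, method = "modp",
                            stat = mt$stat, p_value = mt$p_value,
                            q_value = mt$q_value, stringsAsFactors = FALSE)
  pieces$f <- addMethod("f", fStatistic(fits))
  pieces$modf <- addMethod("modf", moderatedF(fits))
  pieces$boot_f <- addMethod("boot_f",
    bootstrapComparator(prep$Y, prep$design, "f", B = config$B,
                        seed = seeds[2], weights = prep$W))
  pieces$boot_modf <- addMethod("boot_modf",
    bootstrapComparator(prep$Y, prep$design, "modf", B = config$B,
                        seed = seeds[2], weights = prep$W))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
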