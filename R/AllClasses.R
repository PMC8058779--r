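#' Nested null/alternative design matrices for one study design
#'
#' An \code{OdpDesign} holds the pair of nested design matrices realizing a
#' static, independent-sampling or longitudinal study: the null model (no
#' differential signal) and the alternative model (intercept plus spline
#' basis columns, possibly class-specific).  Objects are created with
#' [buildStudy()].
#'
#' @slot kind character; one of \code{"static"}, \code{"independent"},
#'   \code{"longitudinal"}.
#' @slot XNull numeric matrix, N x p0.
#' @slot XAlt numeric matrix, N x p1 (p1 > p0, full column rank).
#' @slot d integer; spline basis dimension (0 for static two-group).
#' @slot knots numeric; sorted knot positions (empty for static).
#' @slot roles character; one label per column of \code{XAlt}.
#'
#' @details The column space of \code{XNull} must be a subspace of the
#'   column space of \code{XAlt}; validity checks this by projection.
#' @export
setClass("OdpDesign",
  representation(kind = "character", XNull = "matrix", XAlt = "matrix",
                 d = "integer", knots = "numeric", roles = "character"))

setValidity("OdpDesign", function(object) {
  msg <- NULL
  if (!object@kind %in% c("static", "independent", "longitudinal"))
    msg <- c(msg, "kind must be static, independent or longitudinal")
  if (nrow(object@XNull) != nrow(object@XAlt))
    msg <- c(msg, "XNull and XAlt must have the same number of rows")
  if (ncol(object@XAlt) <= ncol(object@XNull))
    msg <- c(msg, "alternative model must have more columns than the null")
  qa <- qr(object@XAlt)
  if (qa$rank < ncol(object@XAlt))
    msg <- c(msg, "XAlt is rank deficient")
  res <- qr.resid(qa, object@XNull)
  if (max(abs(res)) > 1e-8 * (1 + max(abs(object@XNull))))
    msg <- c(msg, "null column space is not nested in the alternative")
  if (length(object@roles) != ncol(object@XAlt))
    msg <- c(msg, "roles must label every XAlt column")
  if (is.null(msg)) TRUE else msg
})

#' Per-gene least-squares fits under the null and alternative models
#'
#' Container returned by [fitModels()]: fitted mean vectors, residual sums
#' of squares and maximum-likelihood scale estimates (divisor N) for every
#' gene under both models of an [OdpDesign-class].
#'
#' @slot geneIds character vector, length m.
#' @slot mu0,mu1 numeric matrices (m x N) of fitted means.
#' @slot rss0,rss1 numeric; residual sums of squares.
#' @slot sigma0,sigma1 numeric; ML scale estimates sqrt(RSS/N).
#' @slot df0,df1 integer; model column counts.
#' @slot weighted logical; TRUE when precision weights were applied (all
#'   quantities then live on the weight-transformed scale).
#' @slot weights numeric matrix (m x N of sqrt-weight multipliers, or 0 x 0).
#' @slot degenerate logical vector; genes with (numerically) zero residual
#'   variance, excluded from module clustering downstream.
#' @export
setClass("GeneFitSet",
  representation(geneIds = "character", mu0 = "matrix", mu1 = "matrix",
                 rss0 = "numeric", rss1 = "numeric",
                 sigma0 = "numeric", sigma1 = "numeric",
                 df0 = "integer", df1 = "integer",
                 weighted = "logical", weights = "matrix",
                 degenerate = "logical"))

setValidity("GeneFitSet", function(object) {
  m <- length(object@geneIds)
  msg <- NULL
  if (nrow(object@mu0) != m || nrow(object@mu1) != m)
    msg <- c(msg, "fitted mean matrices must have one row per gene")
  if (any(object@rss1 > object@rss0 + 1e-9 * (1 + object@rss0)))
    msg <- c(msg, "rss1 exceeds rss0: models are not nested")
  if (any(!is.finite(object@mu1)))
    msg <- c(msg, "non-finite fitted values")
  if (is.null(msg)) TRUE else msg
})

#' Gene modules from symmetric Kullback-Leibler clustering
#'
#' Result of [klClust()]: module assignments together with module-level
#' alternative centers \eqn{c_{k1}}, alternative scales \eqn{\upsilon_{k1}}
#' and null scales \eqn{\upsilon_{k0}} (the null center is identically zero
#' on null-transformed data).
#'
#' @slot K integer; number of modules.
#' @slot assignment integer vector over genes (NA for genes excluded as
#'   degenerate).
#' @slot centers numeric matrix K x N of module mean curves.
#' @slot upsilon1,upsilon0 numeric; module scales under the alternative and
#'   null models.
#' @slot sizes integer; module memberships |R_k|.
#' @slot iterations integer; iterations run.
#' @slot converged logical; assignment fixpoint reached before maxIter.
#' @slot objective numeric; trace of the total within-module symmetric KL
#'   distance, one value per assignment pass.
#' @export
setClass("ModuleSet",
  representation(K = "integer", assignment = "integer", centers = "matrix",
                 upsilon1 = "numeric", upsilon0 = "numeric",
                 sizes = "integer", iterations = "integer",
                 converged = "logical", objective = "numeric"))

setValidity("ModuleSet", function(object) {
  msg <- NULL
  if (sum(object@sizes) != sum(!is.na(object@assignment)))
    msg <- c(msg, "module sizes must sum to the number of clustered genes")
  if (any(object@upsilon1 <= 0) || any(object@upsilon0 <= 0))
    msg <- c(msg, "module scales must be positive")
  a <- object@assignment[!is.na(object@assignment)]
  if (length(a) && (min(a) < 1L || max(a) > object@K))
    msg <- c(msg, "assignment indices must lie in 1..K")
  if (is.null(msg)) TRUE else msg
})

#' Significance results from the mODP pipeline
#'
#' Returned by [odp()].  The per-gene table holds the (log-scale) mODP
#' statistic, its pooled bootstrap p-value, the q-value and the local FDR;
#' global quantities are the estimated proportion of true nulls and the
#' bootstrap pool size.
#'
#' @slot table data.frame with columns gene_id, stat, p_value, q_value,
#'   lfdr.
#' @slot pi0 numeric; estimated proportion of true nulls.
#' @slot dHat integer; spline dimension used (0 for static).
#' @slot modules the [ModuleSet-class] used for the statistic.
#' @slot config list echoing all tuning parameters and seeds.
#' @slot poolSize integer; number of pooled bootstrap null statistics.
#' @export
setClass("OdpResults",
  representation(table = "data.frame", pi0 = "numeric", dHat = "integer",
                 modules = "ModuleSet", config = "list",
                 poolSize = "integer"))

setValidity("OdpResults", function(object) {
  msg <- NULL
  need <- c("gene_id", "stat", "p_value", "q_value", "lfdr")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "results table is missing required columns")
  p <- object@table$p_value; q <- object@table$q_value
  if (any(p <= 0 | p > 1)) msg <- c(msg, "p-values must lie in (0,1]")
  o <- order(p)
  if (is.unsorted(q[o])) msg <- c(msg, "q-values must be monotone in p")
  if (object@pi0 <= 0 || object@pi0 > 1) msg <- c(msg, "pi0 must be in (0,1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "OdpDesign", function(object) {
  cat("OdpDesign (", object@kind, " sampling)\n", sep = "")
  cat("  null model:        ", nrow(object@XNull), "x", ncol(object@XNull), "\n")
  cat("  alternative model: ", nrow(object@XAlt), "x", ncol(object@XAlt), "\n")
  if (object@d > 0L) {
    cat("  spline dimension:  ", object@d, "\n")
    cat("  knots:             ", paste(signif(object@knots, 4), collapse = ", "),
        "\n")
  }
  invisible(object)
})

setMethod("show", "GeneFitSet", function(object) {
  cat("GeneFitSet:", length(object@geneIds), "genes x",
      ncol(object@mu1), "measurements\n")
  cat("  model df (null/alt):", object@df0, "/", object@df1, "\n")
  cat("  weighted fits:      ", object@weighted, "\n")
  cat("  degenerate genes:   ", sum(object@degenerate), "\n")
  invisible(object)
})

setMethod("show", "ModuleSet", function(object) {
  cat("ModuleSet:", object@K, "modules over",
      sum(!is.na(object@assignment)), "genes\n")
  cat("  iterations:", object@iterations,
      if (object@converged) "(converged)" else "(max iterations reached)", "\n")
  cat("  module sizes: min", min(object@sizes), "median",
      median(object@sizes), "max", max(object@sizes), "\n")
  invisible(object)
})

setMethod("show", "OdpResults", function(object) {
  cat("OdpResults over", nrow(object@table), "genes\n")
  cat("  pi0 estimate:  ", signif(object@pi0, 4), "\n")
  cat("  spline dim:    ", object@dHat, "\n")
  cat("  bootstrap pool:", object@poolSize, "null statistics\n")
  cat("  q <= 0.05:", sum(object@table$q_value <= 0.05),
      " q <= 0.10:", sum(object@table$q_value <= 0.10), "\n")
  invisible(object)
})
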