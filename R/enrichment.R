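#' Score gene sets by their proportion of true positives
#'
#' For each gene set S the score is \eqn{ptp(S) = 1 - \hat\pi_0(p_S)},
#' the estimated proportion of truly alternative genes among the set's
#' p-values; the dataset-wide reference \code{ptpOverall} is
#' \eqn{1 - \hat\pi_0} over all p-values.  Sets smaller than 100 matched
#' genes use the fixed \eqn{\lambda = 0.5} estimator (the smoother needs
#' more points); sets with fewer than 5 matched genes are flagged
#' unreliable.  Unmatched gene IDs are dropped with a message; sets empty
#' after matching are removed.
#'
#' @param p named numeric vector of per-gene p-values (names = gene IDs),
#'   or unnamed with \code{geneIds} supplied.
#' @param sets named list of gene-ID vectors (e.g. from
#'   [readGeneSets()]).
#' @param geneIds optional character vector naming \code{p}.
#' @return data.frame with columns \code{set}, \code{size}, \code{ptp},
#'   \code{unreliable}; overall ptp as attribute \code{"ptpOverall"}.
#' @export
setPTP <- function(p, sets, geneIds = names(p)) {
  if (is.null(geneIds)) stop("p must be named or geneIds supplied")
  names(p) <- geneIds
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  fixedPi0 <- function(ps) {
    pi0 <- sum(ps > 0.5) / (length(ps) * 0.5)
    min(max(pi0, 0), 1)
  }
  rows <- lapply(names(sets), function(nm) {
    ids <- unique(sets[[nm]])
    hit <- intersect(ids, geneIds)
    dropped <- length(ids) - length(hit)
    if (dropped > 0)
      message("setPTP: '", nm, "': ", dropped, " unmatched gene ID(s) dropped")
    if (!length(hit)) {
      message("setPTP: '", nm, "' empty after matching; dropped")
      return(NULL)
    }
    ps <- p[hit]
    pi0 <- if (length(ps) >= 100L) estimatePi0(ps) else fixedPi0(ps)
    data.frame(set = nm, size = length(hit), ptp = 1 - pi0,
               unreliable = length(hit) < 5L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  overallPi0 <- if (length(p) >= 100L) estimatePi0(p) else fixedPi0(p)
  attr(out, "ptpOverall") <- 1 - overallPi0
  out
}
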