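#' Assemble and validate an expression study container
#'
#' Builds a SummarizedExperiment with assay \code{exprs} and the sample
#' metadata as colData, enforcing the study invariants: unique gene IDs,
#' one metadata row per measurement column, no missing expression values
#' (rejected, never imputed — downstream likelihood sums assume complete
#' vectors), and a finite covariate wherever one is present.
#'
#' @param exprs numeric matrix, genes x measurements, with rownames.
#' @param sampleMeta data.frame with one row per measurement column;
#'   recognized columns: \code{sample_id}, \code{covariate},
#'   \code{group}, \code{individual} (plus free extras).
#' @return a SummarizedExperiment.
#' @export
odpStudy <- function(exprs, sampleMeta) {
  exprs <- as.matrix(exprs)
  sampleMeta <- as.data.frame(sampleMeta)
  if (is.null(rownames(exprs))) stop("exprs must carry gene IDs as rownames")
  if (anyDuplicated(rownames(exprs))) {
    dup <- unique(rownames(exprs)[duplicated(rownames(exprs))])
    stop("duplicate gene IDs: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (nrow(sampleMeta) != ncol(exprs)) {
    stop("metadata has ", nrow(sampleMeta), " rows but the expression ",
         "matrix has ", ncol(exprs), " measurement columns")
  }
  bad <- which(!is.finite(exprs), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("missing/non-finite expression value at gene '",
         rownames(exprs)[bad[1, 1]], "', column ", bad[1, 2],
         " (missing values are rejected, not imputed)")
  }
  if (!is.null(sampleMeta$covariate) &&
      any(!is.finite(sampleMeta$covariate)))
    stop("covariate values must be finite")
  message("study: ", nrow(exprs), " genes x ", ncol(exprs), " measurements")
  SummarizedExperiment(assays = list(exprs = exprs),
                       colData = DataFrame(sampleMeta))
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects gene IDs in the first column (header \code{gene_id}) and one
#' column per measurement.  All cells must be numeric; the offending cell
#' is named otherwise.
#'
#' @param path file path.
#' @param sampleMeta optional data.frame (or path to a TSV readable by
#'   [readSampleMeta()]); when given, row count must match the
#'   measurement columns.
#' @param format \code{"tsv"} or \code{"csv"}; guessed from the extension
#'   by default.
#' @return a SummarizedExperiment (via [odpStudy()]); without metadata, a
#'   minimal colData with \code{sample_id} is created.
#' @export
readExpression <- function(path, sampleMeta = NULL,
                           format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  raw <- if (format == "csv") {
    read.csv(path, check.names = FALSE, colClasses = "character")
  } else {
    read.delim(path, check.names = FALSE, colClasses = "character")
  }
  if (!ncol(raw) >= 2L) stop("expected a gene_id column plus measurements")
  ids <- raw[[1L]]
  vals <- raw[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(vals))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  nas <- which(is.na(as.matrix(vals)) | as.matrix(vals) == "NA",
               arr.ind = TRUE)
  if (nrow(bad) || nrow(nas)) {
    cell <- if (nrow(bad)) bad[1, ] else nas[1, ]
    stop("non-numeric cell at gene '", ids[cell[1]], "', column '",
         colnames(vals)[cell[2]], "'")
  }
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  if (is.character(sampleMeta)) sampleMeta <- readSampleMeta(sampleMeta)
  if (is.null(sampleMeta))
    sampleMeta <- data.frame(sample_id = colnames(vals))
  odpStudy(num, sampleMeta)
}

#' Read a sample metadata table
#'
#' TSV with required column \code{sample_id}; recognized optional columns
#' are \code{covariate} (numeric), \code{group} and \code{individual}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readSampleMeta <- function(path) {
  meta <- read.delim(path, check.names = FALSE)
  if (is.null(meta$sample_id)) stop("metadata requires a sample_id column")
  meta
}

#' Write an expression study back to canonical TSV
#'
#' Inverse of [readExpression()]: first column \code{gene_id}, one column
#' per measurement.  Writing then re-reading then writing again is a
#' fixpoint of the canonical dialect.
#'
#' @param study SummarizedExperiment or matrix with rownames.
#' @param path output path.
#' @export
writeExpression <- function(study, path) {
  Y <- if (is(study, "SummarizedExperiment")) assay(study) else as.matrix(study)
  df <- data.frame(gene_id = rownames(Y), Y, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene IDs.
#'
#' @param path GMT file path.
#' @return named list of gene-ID character vectors.
#' @export
readGeneSets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  sets
}

#' Write the significance table as annotated TSV
#'
#' Columns gene_id, stat, p_value, q_value, lfdr; header comment lines
#' record the seed, K, B, the selected spline dimension and pi0 so runs
#' are self-describing.
#'
#' @param results an [OdpResults-class].
#' @param path output path.
#' @export
writeSignificance <- function(results, path) {
  cfg <- results@config
  hdr <- sprintf("# seed=%s K=%s B=%s d=%s pi0=%.6g",
                 cfg$seed, cfg$K, cfg$B, results@dHat, results@pi0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(results@table, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
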