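#' @describeIn OdpDesign-class null model design matrix
#' @param object an object of the documented class
#' @export
setGeneric("nullMatrix", function(object) standardGeneric("nullMatrix"))
setMethod("nullMatrix", "OdpDesign", function(object) object@XNull)

#' @describeIn OdpDesign-class alternative model design matrix
#' @export
setGeneric("altMatrix", function(object) standardGeneric("altMatrix"))
setMethod("altMatrix", "OdpDesign", function(object) object@XAlt)

#' @describeIn OdpDesign-class sampling design kind
#' @export
setGeneric("designKind", function(object) standardGeneric("designKind"))
setMethod("designKind", "OdpDesign", function(object) object@kind)

#' @describeIn OdpDesign-class spline basis dimension
#' @export
setGeneric("splineDim", function(object) standardGeneric("splineDim"))
setMethod("splineDim", "OdpDesign", function(object) object@d)

#' @describeIn GeneFitSet-class per-gene fit summary as a data.frame
#'   (gene_id, rss0, rss1, sigma0, sigma1, df0, df1, degenerate); write it
#'   with [utils::write.table()] for a TSV export
#' @export
setGeneric("fitTable", function(object) standardGeneric("fitTable"))
setMethod("fitTable", "GeneFitSet", function(object) {
  data.frame(gene_id = object@geneIds,
             rss0 = object@rss0, rss1 = object@rss1,
             sigma0 = object@sigma0, sigma1 = object@sigma1,
             df0 = object@df0, df1 = object@df1,
             degenerate = object@degenerate,
             stringsAsFactors = FALSE)
})

#' @describeIn ModuleSet-class gene-to-module assignment vector
#' @export
setGeneric("moduleAssignments",
           function(object) standardGeneric("moduleAssignments"))
setMethod("moduleAssignments", "ModuleSet", function(object) object@assignment)

#' @describeIn ModuleSet-class per-module parameter table (size, upsilon1,
#'   upsilon0)
#' @export
setGeneric("moduleParameters",
           function(object) standardGeneric("moduleParameters"))
setMethod("moduleParameters", "ModuleSet", function(object) {
  data.frame(module = seq_len(object@K), size = object@sizes,
             upsilon1 = object@upsilon1, upsilon0 = object@upsilon0)
})

#' @describeIn OdpResults-class per-gene significance table
#' @export
setGeneric("resultsTable", function(object) standardGeneric("resultsTable"))
setMethod("resultsTable", "OdpResults", function(object) object@table)

#' @describeIn OdpResults-class estimated proportion of true nulls
#' @export
setGeneric("pi0Est", function(object) standardGeneric("pi0Est"))
setMethod("pi0Est", "OdpResults", function(object) object@pi0)

#' @describeIn OdpResults-class modules used for the mODP statistic
#' @export
setGeneric("modules", function(object) standardGeneric("modules"))
setMethod("modules", "OdpResults", function(object) object@modules)
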