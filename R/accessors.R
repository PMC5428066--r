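#' @include AllClasses.R
NULL

# ---------------------------------------------------------------- generics --

#' Accessors for lendex classes
#'
#' @param x,object a lendex object.
#' @param ... ignored.
#' @name lendex-accessors
NULL

#' @rdname lendex-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname lendex-accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname lendex-accessors
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname lendex-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname lendex-accessors
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname lendex-accessors
#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))

#' @rdname lendex-accessors
#' @export
setGeneric("bioTypes", function(x) standardGeneric("bioTypes"))

#' @rdname lendex-accessors
#' @export
setGeneric("curveWindows", function(x) standardGeneric("curveWindows"))

#' @rdname lendex-accessors
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))

#' @rdname lendex-accessors
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))

# ------------------------------------------------------- ExpressionMatrix --

#' @rdname lendex-accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) {
  assay(x, "exprs")
})

#' @rdname lendex-accessors
#' @export
setMethod("exprScale", "ExpressionMatrix", function(x) x@scale)

#' @rdname lendex-accessors
#' @export
setMethod("sampleConditions", "ExpressionMatrix", function(x) {
  cd <- colData(x)
  if (!"condition" %in% names(cd)) {
    return(setNames(rep(NA_character_, ncol(x)), colnames(x)))
  }
  setNames(as.character(cd$condition), colnames(x))
})

#' @rdname lendex-accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
              nrow(object), ncol(object), object@scale))
  cond <- sampleConditions(object)
  if (!all(is.na(cond))) {
    tab <- table(cond, useNA = "no")
    cat(sprintf("conditions: %s\n",
                paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  }
})

# --------------------------------------------------------- GeneAnnotation --

#' @rdname lendex-accessors
#' @export
setMethod("geneIds", "GeneAnnotation", function(x) x@data$gene_id)

#' @rdname lendex-accessors
#' @export
setMethod("geneLengths", "GeneAnnotation", function(x) {
  setNames(x@data$gene_length, x@data$gene_id)
})

#' @rdname lendex-accessors
#' @export
setMethod("exonLengths", "GeneAnnotation", function(x) {
  setNames(x@data$exon_length, x@data$gene_id)
})

#' @rdname lendex-accessors
#' @export
setMethod("bioTypes", "GeneAnnotation", function(x) {
  setNames(x@data$biotype, x@data$gene_id)
})

#' @export
setMethod("length", "GeneAnnotation", function(x) nrow(x@data))

#' @export
setMethod("as.data.frame", "GeneAnnotation", function(x, ...) x@data)

setMethod("show", "GeneAnnotation", function(object) {
  d <- object@data
  cat(sprintf("GeneAnnotation: %d genes (%d protein_coding)\n",
              nrow(d), sum(d$biotype == "protein_coding")))
  cat(sprintf("gene_length: %g - %g bp; exon_length known for %d genes\n",
              min(d$gene_length), max(d$gene_length), sum(!is.na(d$exon_length))))
})

# ------------------------------------------------------ FoldChangeProfile --

#' @rdname lendex-accessors
#' @export
setMethod("geneIds", "FoldChangeProfile", function(x) x@gene_id)

#' @rdname lendex-accessors
#' @export
setMethod("geneLengths", "FoldChangeProfile", function(x) {
  setNames(x@length, x@gene_id)
})

#' @export
setMethod("length", "FoldChangeProfile", function(x) length(x@gene_id))

#' @export
setMethod("as.data.frame", "FoldChangeProfile", function(x, ...) {
  data.frame(gene_id = x@gene_id, logfc = x@logfc, variance = x@variance,
             length = x@length, stringsAsFactors = FALSE)
})

setMethod("show", "FoldChangeProfile", function(object) {
  cat(sprintf("FoldChangeProfile: %d genes\n", length(object@gene_id)))
  cat(sprintf("logfc: median %.3g [%.3g, %.3g]; length: %g - %g bp\n",
              median(object@logfc), min(object@logfc), max(object@logfc),
              min(object@length), max(object@length)))
})

# ------------------------------------------------------------ BinnedCurve --

#' @rdname lendex-accessors
#' @export
setMethod("curveWindows", "BinnedCurve", function(x) x@windows)

#' @export
setMethod("length", "BinnedCurve", function(x) nrow(x@windows))

#' @export
setMethod("as.data.frame", "BinnedCurve", function(x, ...) x@windows)

setMethod("show", "BinnedCurve", function(object) {
  cat(sprintf("BinnedCurve (%s): %d windows of %d genes, step %d\n",
              object@statistic, nrow(object@windows), object@window,
              object@step))
})

# ------------------------------------------------------ BootstrapEnvelope --

#' @rdname lendex-accessors
#' @export
setMethod("curveWindows", "BootstrapEnvelope", function(x) x@windows)

#' @export
setMethod("length", "BootstrapEnvelope", function(x) nrow(x@windows))

#' @export
setMethod("as.data.frame", "BootstrapEnvelope", function(x, ...) x@windows)

setMethod("show", "BootstrapEnvelope", function(object) {
  cat(sprintf(
    "BootstrapEnvelope: %d windows, %d iterations, %.0f%% CI, seed %d (%s)\n",
    nrow(object@windows), object@n_iterations, 100 * object@ci, object@seed,
    if (object@replace) "resampled with replacement" else "permutation"))
})

# --------------------------------------------------------------- DEResult --

#' @rdname lendex-accessors
#' @export
setMethod("upGenes", "DEResult", function(x) {
  x@table$gene_id[x@table$direction == "up"]
})

#' @rdname lendex-accessors
#' @export
setMethod("downGenes", "DEResult", function(x) {
  x@table$gene_id[x@table$direction == "down"]
})

#' @rdname lendex-accessors
#' @export
setMethod("geneIds", "DEResult", function(x) x@table$gene_id)

#' @export
setMethod("as.data.frame", "DEResult", function(x, ...) x@table)

setMethod("show", "DEResult", function(object) {
  d <- object@table
  cat(sprintf(
    "DEResult (%s t-test, alpha %.3g): %d genes, %d up, %d down\n",
    object@method, object@de_alpha, nrow(d),
    sum(d$direction == "up"), sum(d$direction == "down")))
})
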