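#' @include lendex-package.R
NULL

.EXPR_SCALES <- c("counts", "linear", "log2", "log10")

# ---------------------------------------------------------------- classes --

#' ExpressionMatrix: genes-by-samples expression with a declared scale
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass carrying a
#' single `exprs` assay, optional per-sample condition labels in
#' `colData(x)$condition`, and a `scale` tag declaring the units of the
#' values (`"counts"`, `"linear"`, `"log2"` or `"log10"`). Validity requires
#' unique gene and sample identifiers, finite values, and non-negative
#' values on the counts and linear scales.
#'
#' @slot scale character(1), one of `counts`, `linear`, `log2`, `log10`.
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(scale = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@scale) != 1L || !(object@scale %in% .EXPR_SCALES)) {
    msg <- c(msg, sprintf("scale must be one of: %s",
                          paste(.EXPR_SCALES, collapse = ", ")))
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  }
  v <- assay(object, withDimnames = FALSE)
  if (!is.numeric(v) || !all(is.finite(v))) {
    msg <- c(msg, "expression values must be finite numbers")
  } else if (length(object@scale) == 1L &&
             object@scale %in% c("counts", "linear") && any(v < 0)) {
    msg <- c(msg, sprintf("negative values not allowed on scale '%s'",
                          object@scale))
  }
  if (length(msg)) msg else TRUE
})

#' GeneAnnotation: per-gene length and biotype table
#'
#' Holds one row per gene with its total genomic span (`gene_length`, bp),
#' optionally the length of the union of its exons (`exon_length`, bp) and
#' a `biotype` label (e.g. `protein_coding`).
#'
#' @slot data data.frame with columns `gene_id`, `gene_length`,
#'   `exon_length`, `biotype`.
#' @aliases GeneAnnotation-class
#' @exportClass GeneAnnotation
setClass("GeneAnnotation", slots = c(data = "data.frame"))

setValidity("GeneAnnotation", function(object) {
  d <- object@data
  req <- c("gene_id", "gene_length", "exon_length", "biotype")
  if (!all(req %in% names(d))) {
    return(sprintf("annotation must have columns: %s",
                   paste(req, collapse = ", ")))
  }
  msg <- character()
  if (anyDuplicated(d$gene_id)) msg <- c(msg, "gene_id must be unique")
  if (any(!is.finite(d$gene_length)) || any(d$gene_length < 1)) {
    msg <- c(msg, "gene_length must be finite and >= 1")
  }
  ex <- d$exon_length
  bad <- !is.na(ex) & (ex < 1 | ex > d$gene_length)
  if (any(bad)) {
    msg <- c(msg, "exon_length must satisfy 1 <= exon_length <= gene_length")
  }
  if (length(msg)) msg else TRUE
})

#' FoldChangeProfile: per-gene log2 fold change, variance and length
#'
#' One entry per gene for a single case/control contrast: `logfc` is the
#' difference of per-condition mean log2 expression (case minus control),
#' `variance` is the sum of the per-condition sample variances, and
#' `length` is the gene's annotated genomic length in base pairs.
#'
#' @aliases FoldChangeProfile-class
#' @exportClass FoldChangeProfile
setClass("FoldChangeProfile",
  slots = c(gene_id = "character", logfc = "numeric",
            variance = "numeric", length = "numeric")
)

setValidity("FoldChangeProfile", function(object) {
  n <- length(object@gene_id)
  msg <- character()
  if (length(object@logfc) != n || length(object@variance) != n ||
      length(object@length) != n) {
    msg <- c(msg, "gene_id, logfc, variance and length must have equal length")
  }
  if (anyDuplicated(object@gene_id)) msg <- c(msg, "gene_id must be unique")
  if (any(!is.finite(object@logfc))) msg <- c(msg, "logfc must be finite")
  if (any(object@variance < 0)) msg <- c(msg, "variance must be >= 0")
  if (any(object@length < 1)) msg <- c(msg, "length must be >= 1 bp")
  if (length(msg)) msg else TRUE
})

#' BinnedCurve: sliding-window summary of a per-gene statistic
#'
#' Genes are sorted by length (ties broken by gene id) and grouped into
#' windows of `window` consecutive genes advanced by `step`; each emitted
#' row holds the window's 0-based start offset into the sorted order, the
#' mean member length (bp), the mean of the windowed statistic, the
#' standard error of the mean of the statistic within the window, and the
#' window size. Trailing genes that do not fill a complete window are not
#' emitted.
#'
#' @aliases BinnedCurve-class
#' @exportClass BinnedCurve
setClass("BinnedCurve",
  slots = c(windows = "data.frame", window = "integer", step = "integer",
            statistic = "character")
)

setValidity("BinnedCurve", function(object) {
  w <- object@windows
  req <- c("start", "mean_length", "mean_stat", "sem", "n_genes")
  if (!all(req %in% names(w))) {
    return(sprintf("windows must have columns: %s", paste(req, collapse = ", ")))
  }
  msg <- character()
  if (is.unsorted(w$start, strictly = TRUE) && nrow(w) > 1L) {
    msg <- c(msg, "window starts must be strictly increasing")
  }
  if (nrow(w) > 1L && is.unsorted(w$mean_length)) {
    msg <- c(msg, "mean_length must be non-decreasing across windows")
  }
  if (any(w$n_genes != object@window)) {
    msg <- c(msg, "every emitted window must contain exactly `window` genes")
  }
  if (length(msg)) msg else TRUE
})

#' BootstrapEnvelope: pointwise null quantile band for a binned curve
#'
#' Per window, the lower and upper empirical quantiles of the window mean
#' statistic across shuffle replicates in which the pairing of per-gene
#' statistics with gene lengths is randomized. Records the iteration
#' count, confidence level, seed and whether shuffling sampled with
#' replacement.
#'
#' @aliases BootstrapEnvelope-class
#' @exportClass BootstrapEnvelope
setClass("BootstrapEnvelope",
  slots = c(windows = "data.frame", n_iterations = "integer", ci = "numeric",
            seed = "integer", window = "integer", step = "integer",
            replace = "logical")
)

setValidity("BootstrapEnvelope", function(object) {
  w <- object@windows
  req <- c("start", "mean_length", "lower", "upper")
  if (!all(req %in% names(w))) {
    return(sprintf("windows must have columns: %s", paste(req, collapse = ", ")))
  }
  msg <- character()
  if (any(w$lower > w$upper)) msg <- c(msg, "lower must be <= upper")
  if (length(object@ci) != 1L || object@ci <= 0 || object@ci >= 1) {
    msg <- c(msg, "ci must lie in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' DEResult: per-gene differential-expression calls
#'
#' Per-gene two-sample t-test results for a contrast: `logfc`, `p_value`
#' and `direction` (`up`/`down` when `p_value < de_alpha`, split by the
#' sign of the fold change, otherwise `none`).
#'
#' @aliases DEResult-class
#' @exportClass DEResult
setClass("DEResult",
  slots = c(table = "data.frame", de_alpha = "numeric", method = "character")
)

setValidity("DEResult", function(object) {
  d <- object@table
  req <- c("gene_id", "logfc", "p_value", "direction")
  if (!all(req %in% names(d))) {
    return(sprintf("table must have columns: %s", paste(req, collapse = ", ")))
  }
  msg <- character()
  if (!all(d$direction %in% c("up", "down", "none"))) {
    msg <- c(msg, "direction must be one of up, down, none")
  }
  called <- d$direction != "none"
  if (any(d$p_value[called] >= object@de_alpha)) {
    msg <- c(msg, "directional calls require p_value < de_alpha")
  }
  if (any(d$direction == "up" & d$logfc <= 0) ||
      any(d$direction == "down" & d$logfc >= 0)) {
    msg <- c(msg, "direction must match the sign of logfc")
  }
  if (length(msg)) msg else TRUE
})

# ----------------------------------------------------------- constructors --

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param scale units of `values`: `"counts"`, `"linear"`, `"log2"` or
#'   `"log10"`.
#' @param condition optional condition labels: either a vector named by
#'   sample id or an unnamed vector in column order.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("G", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, scale = "counts", condition = c("case", "control"))
#' @export
ExpressionMatrix <- function(values, scale, condition = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment(assays = list(exprs = values))
  if (!is.null(condition)) {
    condition <- as.character(if (!is.null(names(condition))) {
      unname(condition[colnames(values)])
    } else condition)
    if (length(condition) != ncol(values)) {
      stop("condition must provide one label per sample", call. = FALSE)
    }
    colData(se)$condition <- condition
  }
  new("ExpressionMatrix", se, scale = scale)
}

#' Construct a GeneAnnotation
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param gene_length total genomic span per gene, base pairs.
#' @param exon_length optional length of the exon union per gene, bp;
#'   `NA` when unknown.
#' @param biotype gene biotype labels; recycled if length 1.
#' @return a [GeneAnnotation-class] object.
#' @export
GeneAnnotation <- function(gene_id, gene_length,
                           exon_length = NA_real_,
                           biotype = "protein_coding") {
  d <- data.frame(
    gene_id = as.character(gene_id),
    gene_length = as.numeric(gene_length),
    exon_length = as.numeric(rep_len(exon_length, length(gene_id))),
    biotype = as.character(rep_len(biotype, length(gene_id))),
    stringsAsFactors = FALSE
  )
  new("GeneAnnotation", data = d)
}

#' Construct a FoldChangeProfile
#'
#' @param gene_id,logfc,variance,length parallel per-gene vectors; see
#'   [FoldChangeProfile-class].
#' @return a [FoldChangeProfile-class] object.
#' @export
FoldChangeProfile <- function(gene_id, logfc, variance, length) {
  new("FoldChangeProfile",
      gene_id = as.character(gene_id), logfc = as.numeric(logfc),
      variance = as.numeric(variance), length = as.numeric(length))
}
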