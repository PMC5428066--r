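#' @include AllClasses.R
NULL

#' Collapse probe-level rows to gene-level rows
#'
#' Probes mapping to more than one gene are discarded entirely (only
#' unambiguous probes are informative at the gene level); each retained
#' gene's row is the arithmetic mean of its probes' log2 rows. The input
#' must already be on the log2 scale so that the average is an average of
#' log intensities.
#'
#' @param x an [ExpressionMatrix-class] keyed by probe id, scale `log2`.
#' @param probe_map named list `probe_id -> character vector of gene ids`
#'   (see [readProbeMap()]).
#' @return an [ExpressionMatrix-class] keyed by gene id (rows in sorted
#'   gene-id order), scale `log2`, sample conditions preserved.
#' @export
collapseProbes <- function(x, probe_map) {
  stopifnot(is(x, "ExpressionMatrix"), is.list(probe_map))
  if (exprScale(x) != "log2") {
    stop("collapseProbes requires log2-scale input; log-transform first",
         call. = FALSE)
  }
  probes <- intersect(rownames(x), names(probe_map))
  if (!length(probes)) stop("no probes of the matrix appear in the probe map")
  unambiguous <- probes[lengths(probe_map[probes]) == 1L]
  if (!length(unambiguous)) {
    stop("every matrix probe maps to multiple genes; nothing to collapse")
  }
  gene_of <- vapply(probe_map[unambiguous], `[[`, character(1), 1L)
  v <- exprValues(x)[unambiguous, , drop = FALSE]
  sums <- rowsum(v, group = gene_of)       # sorted by gene id
  n_probes <- as.vector(table(gene_of)[rownames(sums)])
  collapsed <- sums / n_probes
  cond <- sampleConditions(x)
  ExpressionMatrix(collapsed, scale = "log2",
                   condition = if (all(is.na(cond))) NULL else cond)
}

#' Normalize read counts by exon length (exon density)
#'
#' Divides each gene's counts by the total length of the union of its
#' exons, giving average reads per exonic base — a length-normalized
#' expression measure for RNA-seq.
#'
#' @param counts an [ExpressionMatrix-class] with scale `counts`.
#' @param annot a [GeneAnnotation-class] providing `exon_length` for every
#'   matrix gene.
#' @param pseudocount value added to every count before division
#'   (default 0); a pseudocount of 1 guarantees strictly positive
#'   densities ahead of a log transform.
#' @return an [ExpressionMatrix-class] with scale `linear`.
#' @export
exonDensityNormalize <- function(counts, annot, pseudocount = 0) {
  stopifnot(is(counts, "ExpressionMatrix"), is(annot, "GeneAnnotation"),
            pseudocount >= 0)
  if (exprScale(counts) != "counts") {
    stop("exonDensityNormalize expects scale 'counts'", call. = FALSE)
  }
  ex <- exonLengths(annot)
  lens <- ex[rownames(counts)]
  missing <- rownames(counts)[is.na(lens)]
  if (length(missing)) {
    stopListing("genes without exon_length in the annotation", missing)
  }
  if (any(lens <= 0)) stop("exon_length must be positive")
  v <- (exprValues(counts) + pseudocount) / lens
  cond <- sampleConditions(counts)
  ExpressionMatrix(v, scale = "linear",
                   condition = if (all(is.na(cond))) NULL else cond)
}

#' Quantile-normalize samples of an expression matrix
#'
#' Forces every sample (column) to share the identical empirical value
#' distribution — the across-sample mean of order statistics — while
#' preserving within-sample ranks. Ties within a column receive the mean
#' of the reference values over their tied rank span (the "ties =
#' average" convention), so tied inputs stay tied; on tie-free data the
#' transformation is exactly idempotent.
#'
#' @param x an [ExpressionMatrix-class] with at least two samples.
#' @return an [ExpressionMatrix-class] on the same scale.
#' @export
quantileNormalize <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (ncol(x) < 2L) {
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  }
  v <- exprValues(x)
  ref <- rowMeans(apply(v, 2L, sort))
  out <- apply(v, 2L, function(col) {
    mapped <- ref[rank(col, ties.method = "first")]
    # mean of the reference values across each tied rank span
    stats::ave(mapped, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  cond <- sampleConditions(x)
  ExpressionMatrix(out, scale = exprScale(x),
                   condition = if (all(is.na(cond))) NULL else cond)
}

#' Log-transform an expression matrix
#'
#' @param x an [ExpressionMatrix-class] with scale `counts` or `linear`.
#' @param base logarithm base, 2 or 10.
#' @param pseudocount non-negative value added before taking logs.
#'   Defaults to 1 for counts (so zeros map to zero) and 0 for linear
#'   intensity data, which is assumed strictly positive.
#' @return an [ExpressionMatrix-class] with scale `log2` or `log10`.
#' @export
logTransform <- function(x, base = 2, pseudocount = NULL) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (!exprScale(x) %in% c("counts", "linear")) {
    stop("logTransform expects scale 'counts' or 'linear'", call. = FALSE)
  }
  if (!base %in% c(2, 10)) stop("base must be 2 or 10")
  if (is.null(pseudocount)) {
    pseudocount <- if (exprScale(x) == "counts") 1 else 0
  }
  stopifnot(pseudocount >= 0)
  v <- exprValues(x)
  if (any(v < 0)) stop("negative values cannot be log-transformed")
  if (any(v + pseudocount <= 0)) {
    stop("zero values require a positive pseudocount", call. = FALSE)
  }
  v <- log(v + pseudocount, base = base)
  cond <- sampleConditions(x)
  ExpressionMatrix(v, scale = if (base == 2) "log2" else "log10",
                   condition = if (all(is.na(cond))) NULL else cond)
}
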