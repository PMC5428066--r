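#' @include AllClasses.R
NULL

# Resolve `case`/`control` to disjoint, non-empty sample-id sets. Each may
# be a condition label (matched against colData(x)$condition) or an
# explicit vector of sample ids.
resolveContrast <- function(x, case, control) {
  cond <- sampleConditions(x)
  resolve <- function(sel, what) {
    if (all(sel %in% colnames(x))) return(unique(sel))
    if (length(sel) == 1L && sel %in% cond) {
      return(colnames(x)[!is.na(cond) & cond == sel])
    }
    bad <- setdiff(sel, colnames(x))
    if (length(bad)) {
      stopListing(sprintf("%s samples absent from the matrix", what), bad)
    }
    stop(sprintf("cannot resolve %s specification", what))
  }
  case_s <- resolve(case, "case")
  control_s <- resolve(control, "control")
  if (!length(case_s) || !length(control_s)) {
    stop("case and control sample sets must be non-empty")
  }
  if (length(intersect(case_s, control_s))) {
    stop("case and control sample sets must be disjoint")
  }
  list(case = case_s, control = control_s)
}

#' Per-gene log2 fold change with summed per-condition variances
#'
#' For each gene, expression is averaged per condition and the log2 fold
#' change is the difference of those means (case minus control). The
#' per-gene variance is the sum of the two per-condition sample variances
#' (denominator n-1; 0 when a condition has a single sample).
#'
#' @param x an [ExpressionMatrix-class], scale `log2`.
#' @param case,control condition labels (matched against the matrix's
#'   condition annotation) or explicit sample-id vectors; must be
#'   disjoint and non-empty.
#' @param annot a [GeneAnnotation-class] supplying gene lengths; matrix
#'   genes absent from the annotation are dropped with a message.
#' @return a [FoldChangeProfile-class].
#' @export
computeFoldChange <- function(x, case, control, annot) {
  stopifnot(is(x, "ExpressionMatrix"), is(annot, "GeneAnnotation"))
  if (exprScale(x) != "log2") {
    stop("computeFoldChange expects log2-scale expression", call. = FALSE)
  }
  ctr <- resolveContrast(x, case, control)
  lens <- geneLengths(annot)[rownames(x)]
  keep <- !is.na(lens)
  if (!any(keep)) stop("no matrix gene has a length annotation")
  if (any(!keep)) {
    message(sprintf("computeFoldChange: dropped %d unannotated gene(s)",
                    sum(!keep)))
  }
  v <- exprValues(x)[keep, , drop = FALSE]
  vc <- v[, ctr$case, drop = FALSE]
  vk <- v[, ctr$control, drop = FALSE]
  FoldChangeProfile(
    gene_id = rownames(v),
    logfc = rowMeans(vc) - rowMeans(vk),
    variance = rowVarsMat(vc) + rowVarsMat(vk),
    length = unname(lens[keep])
  )
}

#' Start offsets of length-ordered sliding windows
#'
#' Windows of `window` consecutive genes are advanced by `step`; a window
#' is emitted only if it fits completely, so trailing genes beyond the
#' last full window are not covered.
#'
#' @param n_genes total number of genes.
#' @param window window size in genes (default 200).
#' @param step step between window starts in genes (default 40).
#' @return integer vector of 0-based start offsets into the sorted order:
#'   `0, step, 2*step, ...` while `start + window <= n_genes`.
#' @export
windowStarts <- function(n_genes, window = 200L, step = 40L) {
  n_genes <- as.integer(n_genes)
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < 2L) stop("window must be >= 2")
  if (step < 1L || step > window) stop("step must satisfy 0 < step <= window")
  if (n_genes < window) {
    stop(sprintf("need at least %d genes for a %d-gene window (got %d)",
                 window, window, n_genes), call. = FALSE)
  }
  seq.int(0L, n_genes - window, by = step)
}

# Order genes ascending by length with ties broken by gene id (stable,
# reproducible). Returns the permutation.
lengthOrder <- function(length, gene_id) {
  order(length, gene_id, method = "radix")
}

# Fast window means of an already-sorted statistic vector via cumulative
# sums; used per shuffle iteration where only means are needed.
windowMeans <- function(stat_sorted, starts, window) {
  cs <- c(0, cumsum(stat_sorted))
  (cs[starts + window + 1L] - cs[starts + 1L]) / window
}

#' Bin a fold-change profile into a length-ordered sliding-window curve
#'
#' Genes are sorted ascending by length (ties broken by gene id), grouped
#' into overlapping windows of `window` consecutive genes advanced by
#' `step`, and the per-gene log fold change is averaged within each
#' window. The window SEM is the standard deviation (n-1 denominator) of
#' the member statistics divided by `sqrt(window)`.
#'
#' @param profile a [FoldChangeProfile-class].
#' @param window,step window size and step, in genes.
#' @param statistic label describing the windowed statistic (metadata
#'   only).
#' @return a [BinnedCurve-class] whose `mean_length` column is the mean
#'   member length of each window.
#' @export
binCurve <- function(profile, window = 200L, step = 40L,
                     statistic = "log2_fold_change") {
  stopifnot(is(profile, "FoldChangeProfile"))
  n <- length(profile@gene_id)
  starts <- windowStarts(n, window, step)
  ord <- lengthOrder(profile@length, profile@gene_id)
  s <- profile@logfc[ord]
  L <- profile@length[ord]
  window <- as.integer(window)
  stats_per_window <- vapply(starts, function(st) {
    idx <- (st + 1L):(st + window)
    si <- s[idx]
    mu <- mean(si)
    c(mean(L[idx]), mu, sd(si) / sqrt(window))
  }, numeric(3))
  new("BinnedCurve",
      windows = data.frame(
        start = as.integer(starts),
        mean_length = stats_per_window[1L, ],
        mean_stat = stats_per_window[2L, ],
        sem = stats_per_window[3L, ],
        n_genes = window
      ),
      window = window, step = as.integer(step), statistic = statistic)
}

#' Per-group mean-expression-versus-length curves
#'
#' For each sample group, computes each gene's mean expression across the
#' group's samples and bins it along the shared length-sorted gene order,
#' yielding one curve per group (e.g. one per cell type). No contrast is
#' involved; the windowed statistic is the group mean expression itself.
#'
#' @param x an [ExpressionMatrix-class] on a log scale (`log10` as
#'   conventionally displayed, or `log2`).
#' @param groups named character vector mapping every sample id of the
#'   matrix to a group label.
#' @param annot a [GeneAnnotation-class] supplying gene lengths.
#' @param window,step as in [binCurve()].
#' @return named list of [BinnedCurve-class], one per group label.
#' @export
meanExpressionCurve <- function(x, groups, annot, window = 200L, step = 40L) {
  stopifnot(is(x, "ExpressionMatrix"), is(annot, "GeneAnnotation"))
  if (!exprScale(x) %in% c("log2", "log10")) {
    stop("meanExpressionCurve expects log-scale expression", call. = FALSE)
  }
  if (is.null(names(groups))) stop("groups must be named by sample id")
  unknown <- setdiff(colnames(x), names(groups))
  if (length(unknown)) {
    stopListing("samples without a group label", unknown)
  }
  lens <- geneLengths(annot)[rownames(x)]
  keep <- !is.na(lens)
  if (!any(keep)) stop("no matrix gene has a length annotation")
  v <- exprValues(x)[keep, , drop = FALSE]
  lens <- lens[keep]
  labels <- unique(unname(groups[colnames(x)]))
  curves <- lapply(labels, function(lab) {
    samp <- colnames(x)[groups[colnames(x)] == lab]
    prof <- FoldChangeProfile(
      gene_id = rownames(v),
      logfc = rowMeans(v[, samp, drop = FALSE]),
      variance = rowVarsMat(v[, samp, drop = FALSE]),
      length = unname(lens)
    )
    binCurve(prof, window = window, step = step,
             statistic = sprintf("mean_%s_expression", exprScale(x)))
  })
  setNames(curves, labels)
}

#' Write a binned curve as TSV
#'
#' Columns `window_start`, `mean_length_bp`, `mean_stat`, `sem`,
#' `n_genes`, preceded by `#` metadata lines recording window, step and
#' the windowed statistic. The x-axis value is the mean (not median)
#' member length, as stated in the header.
#'
#' @param curve a [BinnedCurve-class].
#' @param path output path.
#' @param extra_meta named list of additional metadata lines.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path, extra_meta = list()) {
  stopifnot(is(curve, "BinnedCurve"))
  w <- curve@windows
  df <- data.frame(window_start = w$start, mean_length_bp = w$mean_length,
                   mean_stat = w$mean_stat, sem = w$sem, n_genes = w$n_genes)
  meta <- c(list(statistic = curve@statistic, window = curve@window,
                 step = curve@step, length_summary = "mean"), extra_meta)
  writeTsvWithHeader(df, path, meta)
}
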