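#' @include foldchange.R
NULL

# Vectorized two-sample t-test over the rows of two matrices.
# Welch by default; pooled-variance when var_equal = TRUE. Degenerate rows
# (zero variance in both groups): p = 1 when the means are equal, p = 0
# when they differ (the separation is infinitely many standard errors).
rowTTest <- function(a, b, var_equal = FALSE) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowVarsMat(a); v2 <- rowVarsMat(b)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(diff))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- diff / sqrt(se2)
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(diff[degen] == 0, 1, 0)
    t_stat[degen] <- ifelse(diff[degen] == 0, 0, sign(diff[degen]) * Inf)
    df[degen] <- NA_real_
  }
  list(statistic = t_stat, p_value = p, df = df, diff = diff)
}

#' Per-gene differential expression by two-sample t-test
#'
#' Tests each gene for a case-versus-control difference in mean log2
#' expression with a two-sided two-sample t-test (Welch by default).
#' Genes with `p < de_alpha` are split by the sign of the mean difference
#' into up- and down-regulated sets; no multiple-testing correction is
#' applied at this stage — the threshold deliberately defines the gene
#' sets for the downstream length-shift test.
#'
#' @param x an [ExpressionMatrix-class], scale `log2`.
#' @param case,control condition labels or sample-id vectors; each
#'   resolved condition needs at least two samples.
#' @param de_alpha per-gene significance threshold (default 0.01).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return a [DEResult-class].
#' @export
perGeneTTest <- function(x, case, control, de_alpha = 0.01,
                         var_equal = FALSE) {
  stopifnot(is(x, "ExpressionMatrix"), de_alpha > 0, de_alpha < 1)
  if (exprScale(x) != "log2") {
    stop("perGeneTTest expects log2-scale expression", call. = FALSE)
  }
  ctr <- resolveContrast(x, case, control)
  if (length(ctr$case) < 2L || length(ctr$control) < 2L) {
    stop("each condition needs >= 2 samples for a t-test", call. = FALSE)
  }
  v <- exprValues(x)
  tt <- rowTTest(v[, ctr$case, drop = FALSE],
                 v[, ctr$control, drop = FALSE], var_equal = var_equal)
  direction <- rep("none", nrow(v))
  sig <- tt$p_value < de_alpha
  direction[sig & tt$diff > 0] <- "up"
  direction[sig & tt$diff < 0] <- "down"
  new("DEResult",
      table = data.frame(
        gene_id = rownames(v),
        logfc = tt$diff,
        t = tt$statistic,
        p_value = tt$p_value,
        direction = direction,
        stringsAsFactors = FALSE
      ),
      de_alpha = de_alpha,
      method = if (var_equal) "pooled" else "welch")
}

#' Test whether DE gene sets are length-shifted
#'
#' For each direction (up/down), compares the gene lengths of the set
#' with the lengths of all analyzed genes by a two-sided two-sample
#' t-test (Welch by default), then applies a Bonferroni correction by
#' `family_size`. The reference includes the set itself (`"all"`); the
#' disjoint alternative is available via `reference = "complement"`.
#'
#' @param de a [DEResult-class].
#' @param annot a [GeneAnnotation-class]; analyzed genes are the DE
#'   table's genes that carry a length.
#' @param family_size number of tests in the Bonferroni family, e.g.
#'   2 directions x 3 contrasts = 6 in a three-region study.
#' @param reference `"all"` (default) or `"complement"`.
#' @param log_length test `log10` lengths instead of raw base pairs
#'   (lengths are heavy-tailed; raw bp is the default convention).
#' @param var_equal use the pooled-variance t-test.
#' @return data.frame with one row per direction: `direction`, `n_set`,
#'   `mean_length_set`, `mean_length_all`, `t`, `p_raw`, `p_bonferroni`,
#'   `n_tests_in_family`, `testable`. Sets with fewer than 2 genes are
#'   flagged untestable and emit no p-value.
#' @export
lengthShiftTest <- function(de, annot, family_size = 2L,
                            reference = c("all", "complement"),
                            log_length = FALSE, var_equal = FALSE) {
  stopifnot(is(de, "DEResult"), is(annot, "GeneAnnotation"),
            family_size >= 1)
  reference <- match.arg(reference)
  lens <- geneLengths(annot)
  ids <- intersect(de@table$gene_id, names(lens))
  if (!length(ids)) stop("no DE-table gene has a length annotation")
  all_len <- unname(lens[ids])
  if (log_length) all_len <- log10(all_len)
  rows <- lapply(c("up", "down"), function(dir) {
    set_ids <- intersect(
      de@table$gene_id[de@table$direction == dir], ids)
    set_len <- unname(lens[set_ids])
    if (log_length) set_len <- log10(set_len)
    ref_len <- if (reference == "all") all_len else {
      all_len[!(ids %in% set_ids)]
    }
    out <- data.frame(
      direction = dir,
      n_set = length(set_ids),
      mean_length_set = if (length(set_len)) mean(set_len) else NA_real_,
      mean_length_all = mean(ref_len),
      t = NA_real_, p_raw = NA_real_, p_bonferroni = NA_real_,
      n_tests_in_family = as.integer(family_size),
      testable = length(set_ids) >= 2L,
      stringsAsFactors = FALSE
    )
    if (out$testable) {
      ht <- t.test(set_len, ref_len, var.equal = var_equal)
      out$t <- unname(ht$statistic)
      out$p_raw <- ht$p.value
      out$p_bonferroni <- min(1, ht$p.value * family_size)
    }
    out
  })
  do.call(rbind, rows)
}

#' Boxplot summary statistics for sets of gene lengths
#'
#' Median, first and third quartiles (linear-interpolation "type 7"
#' convention), whiskers at the most extreme values within 1.5 x IQR of
#' the box, and the notch half-width `1.58 * IQR / sqrt(n)` — the
#' numbers needed to redraw a notched length boxplot per gene set.
#'
#' @param sets named list of numeric length vectors (bp).
#' @return data.frame with one row per set; empty sets yield `n = 0` and
#'   `NA` statistics.
#' @export
boxplotSummary <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  rows <- lapply(names(sets), function(nm) {
    v <- sets[[nm]]
    n <- length(v)
    if (n == 0L) {
      return(data.frame(set = nm, n = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, whisker_low = NA_real_,
                        whisker_high = NA_real_, notch_half_width = NA_real_,
                        stringsAsFactors = FALSE))
    }
    q <- quantile(v, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(
      set = nm, n = n, median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(v[v >= q[1] - 1.5 * iqr]),
      whisker_high = max(v[v <= q[3] + 1.5 * iqr]),
      notch_half_width = 1.58 * iqr / sqrt(n),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "quartile_type") <- 7L
  out
}

#' Full threshold-based length-shift analysis
#'
#' Runs [perGeneTTest()], tests the up- and down-regulated sets for a
#' length shift against all analyzed genes with [lengthShiftTest()], and
#' tabulates boxplot summary statistics of gene lengths for the `up`,
#' `down` and `all` sets.
#'
#' @inheritParams perGeneTTest
#' @inheritParams lengthShiftTest
#' @param annot a [GeneAnnotation-class].
#' @return list with components `de` ([DEResult-class]), `shift`
#'   (data.frame from [lengthShiftTest()]) and `boxplot` (data.frame from
#'   [boxplotSummary()]).
#' @export
deLengthPipeline <- function(x, case, control, annot, de_alpha = 0.01,
                             family_size = 2L, reference = "all",
                             log_length = FALSE, var_equal = FALSE) {
  de <- perGeneTTest(x, case, control, de_alpha = de_alpha,
                     var_equal = var_equal)
  shift <- lengthShiftTest(de, annot, family_size = family_size,
                           reference = reference, log_length = log_length,
                           var_equal = var_equal)
  lens <- geneLengths(annot)
  ids <- intersect(de@table$gene_id, names(lens))
  sets <- list(
    up = unname(lens[intersect(upGenes(de), ids)]),
    down = unname(lens[intersect(downGenes(de), ids)]),
    all = unname(lens[ids])
  )
  list(de = de, shift = shift, boxplot = boxplotSummary(sets))
}
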