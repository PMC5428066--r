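# Fixtures built in code; nothing is stored on disk.

# Small labelled expression matrix.
toyMatrix <- function(values, genes = NULL, samples = NULL,
                      scale = "log2", condition = NULL) {
  m <- matrix(values, nrow = if (is.null(genes)) 3 else length(genes))
  rownames(m) <- genes %||% paste0("G", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  ExpressionMatrix(m, scale = scale, condition = condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random null fold-change profile: logfc independent of length.
nullProfile <- function(n, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    FoldChangeProfile(
      gene_id = sprintf("G%05d", seq_len(n)),
      logfc = rnorm(n, 0, sd),
      variance = runif(n, 0, 1),
      length = round(10^runif(n, 3, 6))
    )
  })
}

# Independent oracle: enumerate window starts with an explicit loop.
bruteStarts <- function(n, window, step) {
  window <- as.integer(window)
  step <- as.integer(step)
  starts <- integer(0)
  st <- 0L
  while (st + window <= n) {
    starts <- c(starts, st)
    st <- st + step
  }
  starts
}

# Independent oracle: re-sort and average with explicit loops.
bruteBinCurve <- function(gene_id, logfc, length, window, step) {
  ord <- order(length, gene_id)
  s <- logfc[ord]
  L <- length[ord]
  starts <- bruteStarts(base::length(s), window, step)
  t(vapply(starts, function(st) {
    idx <- (st + 1):(st + window)
    c(start = st, mean_length = mean(L[idx]), mean_stat = mean(s[idx]),
      sem = stats::sd(s[idx]) / sqrt(window))
  }, numeric(4)))
}

# Minimal Ensembl-dialect GTF writer. `features` is a data.frame with
# columns type, start, end, gene_id and optionally biotype.
writeToyGTF <- function(features, path = tempfile(fileext = ".gtf")) {
  lines <- vapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    bt <- if (!is.null(f$biotype) && !is.na(f$biotype)) {
      sprintf(' gene_biotype "%s";', f$biotype)
    } else ""
    sprintf('chr1\ttest\t%s\t%d\t%d\t.\t+\t.\tgene_id "%s";%s',
            f$type, f$start, f$end, f$gene_id, bt)
  }, character(1))
  writeLines(lines, path)
  path
}

# Write matrix / annotation / conditions to a temp dir, returning paths.
writeToyBundle <- function(x, annot, dir = tempfile()) {
  dir.create(dir)
  paths <- list(
    matrix = file.path(dir, "matrix.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    conditions = file.path(dir, "conditions.tsv")
  )
  writeExpressionMatrix(x, paths$matrix)
  writeGeneAnnotation(annot, paths$annotation)
  cond <- sampleConditions(x)
  write.table(data.frame(sample_id = names(cond), condition = unname(cond)),
              paths$conditions, sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
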