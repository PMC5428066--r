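annot4 <- GeneAnnotation(gene_id = paste0("G", 1:4),
                         gene_length = c(1000, 2000, 4000, 8000))

test_that("fold change is the difference of per-condition means with
           summed variances", {
  x <- toyMatrix(c(4, 2, 1, 0, 4, 2, 3, 0, 2, 1, 0, 0, 2, 1, 0, 0),
                 genes = paste0("G", 1:4),
                 samples = c("c1", "c2", "k1", "k2"),
                 scale = "log2",
                 condition = c("case", "case", "control", "control"))
  prof <- computeFoldChange(x, "case", "control", annot4)
  df <- as.data.frame(prof)
  # G1: case {4,4}, control {2,2} -> logfc 2, variance 0
  expect_equal(df$logfc[df$gene_id == "G1"], 2)
  expect_equal(df$variance[df$gene_id == "G1"], 0)
  # G3: case {1,3}, control {0,0} -> logfc 2, variance 2 + 0
  expect_equal(df$logfc[df$gene_id == "G3"], 2)
  expect_equal(df$variance[df$gene_id == "G3"], 2)
  # G4: case equals control -> logfc 0
  expect_equal(df$logfc[df$gene_id == "G4"], 0)
  expect_equal(unname(geneLengths(prof)), c(1000, 2000, 4000, 8000))
})

test_that("contrasts validate their sample sets", {
  x <- toyMatrix(rnorm(8), genes = paste0("G", 1:4),
                 samples = c("a", "b"), scale = "log2")
  expect_error(computeFoldChange(x, c("a", "zz"), "b", annot4),
               "absent from the matrix.*zz")
  expect_error(computeFoldChange(x, "a", "a", annot4), "disjoint")
})

test_that("window starts match brute-force enumeration", {
  cases <- list(c(200, 200, 40), c(240, 200, 40), c(1000, 200, 40),
                c(205, 200, 5), c(57, 10, 3), c(500, 100, 100))
  for (cs in cases) {
    expect_identical(windowStarts(cs[1], cs[2], cs[3]),
                     bruteStarts(cs[1], cs[2], cs[3]))
  }
  expect_identical(windowStarts(200, 200, 40), 0L)
  expect_identical(windowStarts(240, 200, 40), c(0L, 40L))
  expect_error(windowStarts(199, 200, 40), "at least 200")
  expect_error(windowStarts(300, 200, 300), "step")
})

test_that("emitted window count follows floor((n - window)/step) + 1", {
  withr::with_seed(3, {
    for (n in sort(sample(200:2000, 30))) {
      expect_identical(length(windowStarts(n, 200, 40)),
                       length(bruteStarts(n, 200, 40)))
      expect_identical(length(windowStarts(n, 200, 40)),
                       as.integer((n - 200) %/% 40 + 1))
    }
  })
})

test_that("binned curves agree with a brute-force recomputation", {
  prof <- nullProfile(950, seed = 5)
  curve <- binCurve(prof, window = 200, step = 40)
  oracle <- bruteBinCurve(geneIds(prof), as.data.frame(prof)$logfc,
                          as.data.frame(prof)$length, 200, 40)
  w <- curveWindows(curve)
  expect_equal(w$start, unname(oracle[, "start"]))
  expect_equal(w$mean_length, unname(oracle[, "mean_length"]))
  expect_equal(w$mean_stat, unname(oracle[, "mean_stat"]))
  expect_equal(w$sem, unname(oracle[, "sem"]))
  expect_true(all(w$n_genes == 200))
  expect_false(is.unsorted(w$mean_length))
})

test_that("constant profiles give flat curves with zero sem", {
  prof <- FoldChangeProfile(sprintf("G%03d", 1:300), rep(0.7, 300),
                            rep(0, 300), seq(1000, 300000, length.out = 300))
  w <- curveWindows(binCurve(prof, 100, 50))
  expect_equal(w$mean_stat, rep(0.7, nrow(w)))
  expect_equal(w$sem, rep(0, nrow(w)))
})

test_that("a planted step in the longest genes lands in the last window", {
  n <- 400
  lens <- seq(1000, 400000, length.out = n)
  lfc <- c(rep(0, 200), rep(1, 200))  # +1 for the 200 longest genes
  prof <- FoldChangeProfile(sprintf("G%03d", 1:n), lfc, rep(0, n), lens)
  w <- curveWindows(binCurve(prof, window = 200, step = 200))
  expect_equal(w$mean_stat, c(0, 1))
})

test_that("binning is invariant to input row order and equivariant under
           constant shifts", {
  prof <- nullProfile(600, seed = 11)
  w1 <- curveWindows(binCurve(prof, 150, 30))
  perm <- withr::with_seed(2, sample.int(600))
  df <- as.data.frame(prof)[perm, ]
  prof2 <- FoldChangeProfile(df$gene_id, df$logfc, df$variance, df$length)
  expect_equal(curveWindows(binCurve(prof2, 150, 30)), w1)

  prof3 <- FoldChangeProfile(geneIds(prof), as.data.frame(prof)$logfc + 1.5,
                             as.data.frame(prof)$variance,
                             as.data.frame(prof)$length)
  w3 <- curveWindows(binCurve(prof3, 150, 30))
  expect_equal(w3$mean_stat, w1$mean_stat + 1.5)
  expect_equal(w3$sem, w1$sem)
})

test_that("window=step reduces to disjoint block means", {
  prof <- nullProfile(500, seed = 13)
  w <- curveWindows(binCurve(prof, window = 100, step = 100))
  df <- as.data.frame(prof)
  ord <- order(df$length, df$gene_id)
  s <- df$logfc[ord]
  blocks <- colMeans(matrix(s, nrow = 100))
  expect_equal(w$mean_stat, blocks)
})

test_that("mean-expression curves are per-group and shift-equivariant", {
  n <- 300
  lens <- round(10^seq(3, 5.5, length.out = n))
  annot <- GeneAnnotation(gene_id = sprintf("G%03d", 1:n),
                          gene_length = lens)
  base_expr <- withr::with_seed(5, matrix(rnorm(n * 4, 2, 0.5), n, 4))
  m <- cbind(base_expr, base_expr + 1)
  rownames(m) <- sprintf("G%03d", 1:n)
  colnames(m) <- paste0("S", 1:8)
  x <- ExpressionMatrix(m, scale = "log10")
  groups <- setNames(rep(c("A", "B"), each = 4), colnames(m))
  curves <- meanExpressionCurve(x, groups, annot, window = 100, step = 20)
  expect_named(curves, c("A", "B"))
  # group B = group A + 1 everywhere, pointwise
  expect_equal(curveWindows(curves$B)$mean_stat,
               curveWindows(curves$A)$mean_stat + 1)

  # constant expression gives a flat curve at the constant
  xc <- ExpressionMatrix(matrix(3, n, 2,
                                dimnames = list(sprintf("G%03d", 1:n),
                                                c("S1", "S2"))),
                         scale = "log10")
  flat <- meanExpressionCurve(xc, c(S1 = "A", S2 = "A"), annot, 100, 20)
  expect_equal(curveWindows(flat$A)$mean_stat, rep(3, 11))

  expect_error(meanExpressionCurve(x, groups[-1], annot, 100, 20),
               "without a group")
})

test_that("a planted positive expression slope yields a monotone curve", {
  cfg <- syntheticConfig(n_genes = 2000, beta = 0, noise_sd = 0.3, seed = 21)
  annot <- simulateLengths(cfg)
  lens <- geneLengths(annot)
  # neuron-style group: expression increases with log length
  withr::with_seed(22, {
    expr <- 1 + 0.5 * (log10(lens) - mean(log10(lens))) +
      matrix(rnorm(2000 * 4, 0, 0.3), 2000, 4)
  })
  dimnames(expr) <- list(names(lens), paste0("S", 1:4))
  x <- ExpressionMatrix(expr, scale = "log10")
  curves <- meanExpressionCurve(x, setNames(rep("neuron", 4), colnames(expr)),
                                annot, 200, 40)
  w <- curveWindows(curves$neuron)
  expect_gt(cor(w$mean_length, w$mean_stat, method = "spearman"), 0.9)
})

test_that("curve TSVs carry the window metadata", {
  prof <- nullProfile(400, seed = 1)
  curve <- binCurve(prof, 200, 40)
  path <- tempfile(fileext = ".tsv")
  writeCurve(curve, path)
  header <- grep("^#", readLines(path), value = TRUE)
  expect_true(any(grepl("window: 200", header)))
  expect_true(any(grepl("length_summary: mean", header)))
  back <- read.delim(path, comment.char = "#")
  expect_equal(back$mean_stat, curveWindows(curve)$mean_stat)
})
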