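test_that("per-gene t-test matches stats::t.test on random genes", {
  withr::with_seed(17, {
    n <- 100
    m <- matrix(rnorm(n * 9, 5, 1), n, 9)
    dimnames(m) <- list(sprintf("G%03d", 1:n), paste0("S", 1:9))
    x <- ExpressionMatrix(m, scale = "log2",
                          condition = rep(c("case", "control"), c(4, 5)))
    for (ve in c(FALSE, TRUE)) {
      de <- perGeneTTest(x, "case", "control", var_equal = ve)
      df <- as.data.frame(de)
      oracle <- vapply(seq_len(n), function(i) {
        t.test(m[i, 1:4], m[i, 5:9], var.equal = ve)$p.value
      }, numeric(1))
      expect_equal(df$p_value, oracle, tolerance = 1e-10)
    }
  })
})

test_that("degenerate genes are handled deliberately", {
  m <- rbind(
    G1 = c(3, 3, 3, 3, 3, 3),    # identical everywhere: p = 1, none
    G2 = c(5, 5, 5, 1, 1, 1),    # zero variance, separated means
    G3 = c(5.01, 5.02, 4.99, 1.01, 1.0, 0.98)  # tiny jitter
  )
  colnames(m) <- paste0("S", 1:6)
  x <- ExpressionMatrix(m, scale = "log2",
                        condition = rep(c("case", "control"), each = 3))
  df <- as.data.frame(perGeneTTest(x, "case", "control"))
  expect_equal(df$p_value[df$gene_id == "G1"], 1)
  expect_identical(df$direction[df$gene_id == "G1"], "none")
  expect_equal(df$p_value[df$gene_id == "G2"], 0)
  expect_identical(df$direction[df$gene_id == "G2"], "up")
  expect_identical(df$direction[df$gene_id == "G3"], "up")
})

test_that("swapping case and control flips directions, not p-values", {
  withr::with_seed(19, {
    m <- matrix(rnorm(50 * 8), 50, 8,
                dimnames = list(sprintf("G%02d", 1:50), paste0("S", 1:8)))
  })
  x <- ExpressionMatrix(m, scale = "log2",
                        condition = rep(c("case", "control"), each = 4))
  a <- as.data.frame(perGeneTTest(x, "case", "control", de_alpha = 0.2))
  b <- as.data.frame(perGeneTTest(x, "control", "case", de_alpha = 0.2))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$logfc, -b$logfc)
  flip <- c(up = "down", down = "up", none = "none")
  expect_identical(unname(flip[a$direction]), b$direction)
})

test_that("t-tests require two samples per condition", {
  x <- toyMatrix(rnorm(9), genes = paste0("G", 1:3),
                 samples = paste0("S", 1:3), scale = "log2",
                 condition = c("case", "control", "control"))
  expect_error(perGeneTTest(x, "case", "control"), ">= 2 samples")
})

test_that("length-shift test detects a planted shift and applies
           Bonferroni", {
  withr::with_seed(23, {
    n <- 10000
    lens <- round(10^runif(n, 3, 6))
  })
  ids <- sprintf("G%05d", 1:n)
  annot <- GeneAnnotation(gene_id = ids, gene_length = lens)
  # up set = the 500 longest genes
  up_ids <- ids[order(lens, decreasing = TRUE)][1:500]
  tab <- data.frame(gene_id = ids, logfc = ifelse(ids %in% up_ids, 1, 0),
                    p_value = ifelse(ids %in% up_ids, 1e-6, 0.5),
                    direction = ifelse(ids %in% up_ids, "up", "none"),
                    stringsAsFactors = FALSE)
  de <- new("DEResult", table = tab, de_alpha = 0.01, method = "welch")
  res <- lengthShiftTest(de, annot, family_size = 6)
  up <- res[res$direction == "up", ]
  expect_gt(up$mean_length_set, up$mean_length_all)
  expect_lt(up$p_bonferroni, 0.001)
  expect_equal(up$p_bonferroni, min(1, up$p_raw * 6))
  # empty down set is untestable, not an error
  down <- res[res$direction == "down", ]
  expect_false(down$testable)
  expect_true(is.na(down$p_raw))
})

test_that("Bonferroni arithmetic caps at 1", {
  # p_raw 0.04 with a family of 6 gives 0.24; a family of 50 caps at 1
  expect_equal(min(1, 0.04 * 6), 0.24)
  withr::with_seed(29, {
    n <- 400
    annot <- GeneAnnotation(gene_id = sprintf("G%03d", 1:n),
                            gene_length = round(10^runif(n, 3, 5)))
    ids <- geneIds(annot)
    set <- sample(ids, 50)
    tab <- data.frame(gene_id = ids, logfc = as.numeric(ids %in% set),
                      p_value = ifelse(ids %in% set, 1e-4, 0.9),
                      direction = ifelse(ids %in% set, "up", "none"))
    de <- new("DEResult", table = tab, de_alpha = 0.01, method = "welch")
    r6 <- lengthShiftTest(de, annot, family_size = 6)
    r1 <- lengthShiftTest(de, annot, family_size = 1)
    up6 <- r6[r6$direction == "up", ]; up1 <- r1[r1$direction == "up", ]
    expect_equal(up6$p_raw, up1$p_raw)
    expect_equal(up6$p_bonferroni, min(1, up6$p_raw * 6))
    expect_gte(up6$p_bonferroni, up6$p_raw)
    expect_lte(up6$p_bonferroni, 1)
  })
})

test_that("set-vs-complement and log-length options move the reference", {
  withr::with_seed(31, {
    n <- 2000
    annot <- GeneAnnotation(gene_id = sprintf("G%04d", 1:n),
                            gene_length = round(10^runif(n, 3, 6)))
    ids <- geneIds(annot)
    set <- sample(ids, 200)
    tab <- data.frame(gene_id = ids, logfc = as.numeric(ids %in% set),
                      p_value = ifelse(ids %in% set, 1e-4, 0.9),
                      direction = ifelse(ids %in% set, "up", "none"))
    de <- new("DEResult", table = tab, de_alpha = 0.01, method = "welch")
    r_all <- lengthShiftTest(de, annot)
    r_comp <- lengthShiftTest(de, annot, reference = "complement")
    # the complement excludes the set, so the reference mean differs
    expect_false(isTRUE(all.equal(
      r_all$mean_length_all[1], r_comp$mean_length_all[1])))
    r_log <- lengthShiftTest(de, annot, log_length = TRUE)
    expect_lt(r_log$mean_length_all[1], 7)  # log10 bp, not bp
  })
})

test_that("boxplot summaries follow the type-7 quartile convention", {
  s <- boxplotSummary(list(set = 1:9))
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$whisker_high, 9)
  expect_equal(s$notch_half_width, 1.58 * 4 / 3)

  # whiskers reach only the most extreme points within 1.5 IQR
  v <- c(1:9, 100)
  s2 <- boxplotSummary(list(set = v))
  expect_lt(s2$whisker_high, 100)

  # empty set: a row with n = 0 and no statistics
  s3 <- boxplotSummary(list(up = numeric(0), all = 1:5))
  expect_equal(s3$n[s3$set == "up"], 0L)
  expect_true(is.na(s3$median[s3$set == "up"]))
})

test_that("the threshold analysis ties DE calls to length summaries", {
  cfg <- syntheticConfig(n_genes = 1200, beta = 0.6, noise_sd = 0.3,
                         n_case = 6, n_control = 6, seed = 41)
  sim <- simulateExpression(cfg)
  res <- deLengthPipeline(sim$matrix, "case", "control", sim$annotation,
                          de_alpha = 0.01, family_size = 2)
  expect_s4_class(res$de, "DEResult")
  expect_setequal(res$boxplot$set, c("up", "down", "all"))
  # positive beta: up-called genes are longer, down-called shorter
  shift <- res$shift
  expect_gt(shift$mean_length_set[shift$direction == "up"],
            shift$mean_length_all[shift$direction == "up"])
  expect_lt(shift$mean_length_set[shift$direction == "down"],
            shift$mean_length_all[shift$direction == "down"])
})

test_that("a tissue mixture with neuronal loss length-shifts the
           down-regulated genes", {
  mix <- mixtureConfig(
    cell_types = data.frame(name = c("neuron", "glia"),
                            baseline = c(0, 0), slope = c(1, 0)),
    fraction_case = c(neuron = 0.3, glia = 0.7),
    fraction_control = c(neuron = 0.5, glia = 0.5)
  )
  cfg <- syntheticConfig(n_genes = 1500, noise_sd = 0.4, n_case = 8,
                         n_control = 8, seed = 43)
  sim <- simulateCellMixture(mix, cfg)
  res <- deLengthPipeline(sim$tissue, "case", "control", sim$annotation,
                          de_alpha = 0.01, family_size = 2)
  shift <- res$shift
  down <- shift[shift$direction == "down", ]
  expect_true(down$testable)
  # genes lost with the neurons are the long ones
  expect_gt(down$mean_length_set, down$mean_length_all)
})
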