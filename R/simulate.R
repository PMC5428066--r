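#' @include AllClasses.R
NULL

# Seed offsets keep the random streams of the generator stages disjoint:
# reusing one stream for both length and baseline draws would correlate
# the two quantities (both are inverse-CDF transforms of the same
# uniforms) and plant a spurious length-expression association.
.SEED_LENGTHS <- 0L
.SEED_EXPRESSION <- 1L
.SEED_MIXTURE <- 2L

#' Configuration for the synthetic expression generator
#'
#' Describes a two-condition study with an optional planted length
#' effect: gene lengths are drawn from a truncated log-normal spanning
#' roughly 1 kb to 1 Mb, per-gene baseline log2 expression is Gaussian,
#' and case samples receive an extra `beta * (log10 length - center)`
#' log2 fold change so that `beta` is the planted slope in log2-fold-
#' change units per log10 base pair. Per-sample noise is Gaussian on the
#' log2 scale (intensity platform) or Poisson after exponentiation
#' (counts platform).
#'
#' @param n_genes number of genes.
#' @param length_log10_mean,length_log10_sd mean and sd of log10 gene
#'   length before truncation.
#' @param length_bounds truncation bounds in bp, `c(lower, upper)`.
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression
#'   distribution.
#' @param beta planted length-effect slope, log2-fold-change units per
#'   log10 bp (0 = null).
#' @param noise_sd per-sample Gaussian noise sd on the log2 scale.
#' @param n_case,n_control sample counts per condition.
#' @param platform `"intensity"` (log2 values with Gaussian noise) or
#'   `"counts"` (integer counts at the given depth).
#' @param count_depth expected total reads per sample for counts mode.
#' @param noncoding_fraction fraction of genes labelled with a
#'   non-coding biotype, to exercise the protein-coding filter.
#' @param seed integer seed recorded in all outputs.
#' @return a validated config list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(n_genes = 5000L,
                            length_log10_mean = 4.2,
                            length_log10_sd = 0.5,
                            length_bounds = c(1e3, 1e6),
                            baseline_mean = 6,
                            baseline_sd = 1,
                            beta = 0,
                            noise_sd = 0.5,
                            n_case = 10L,
                            n_control = 10L,
                            platform = c("intensity", "counts"),
                            count_depth = 5e6,
                            noncoding_fraction = 0,
                            seed = 1L) {
  platform <- match.arg(platform)
  cfg <- list(
    n_genes = as.integer(n_genes),
    length_log10_mean = length_log10_mean,
    length_log10_sd = length_log10_sd,
    length_bounds = as.numeric(length_bounds),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    beta = beta, noise_sd = noise_sd,
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    platform = platform, count_depth = count_depth,
    noncoding_fraction = noncoding_fraction,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_genes >= 1L, cfg$noise_sd >= 0,
            length(cfg$length_bounds) == 2L,
            cfg$length_bounds[1] >= 1,
            cfg$length_bounds[1] <= cfg$length_bounds[2],
            cfg$n_case >= 1L, cfg$n_control >= 1L,
            cfg$noncoding_fraction >= 0, cfg$noncoding_fraction < 1,
            cfg$count_depth > 0)
  structure(cfg, class = "SyntheticConfig")
}

#' Configuration for tissue-as-cell-type-mixture simulation
#'
#' Each cell type has a baseline log2 expression offset, a
#' length-effect slope (e.g. neurons expressing long genes more
#' strongly: slope > 0; glia flat: slope 0), and optionally an extra
#' case-only slope modelling a within-cell length-dependent response
#' (e.g. hyperactive tangle-bearing neurons up-regulating long genes).
#' Tissue samples are proportion-weighted sums of the cell-type linear
#' profiles; shifting the proportions between conditions emulates
#' neuronal loss.
#'
#' @param cell_types data.frame with columns `name`, `baseline`
#'   (log2 offset), `slope` (log2 per log10 bp) and optionally
#'   `case_shift_slope` (extra case-only slope, default 0).
#' @param fraction_case,fraction_control named proportions per cell
#'   type; each must sum to 1.
#' @param seed integer seed.
#' @return a validated config list of class `MixtureConfig`.
#' @export
mixtureConfig <- function(cell_types, fraction_case, fraction_control,
                          seed = 1L) {
  stopifnot(is.data.frame(cell_types),
            all(c("name", "baseline", "slope") %in% names(cell_types)))
  if (!"case_shift_slope" %in% names(cell_types)) {
    cell_types$case_shift_slope <- 0
  }
  nm <- as.character(cell_types$name)
  stopifnot(!anyDuplicated(nm),
            setequal(names(fraction_case), nm),
            setequal(names(fraction_control), nm))
  for (fr in list(fraction_case, fraction_control)) {
    if (any(fr < 0) || any(fr > 1)) stop("proportions must lie in [0, 1]")
    if (abs(sum(fr) - 1) > 1e-8) {
      stop("cell-type proportions must sum to 1 in each condition")
    }
  }
  structure(list(cell_types = cell_types,
                 fraction_case = fraction_case[nm],
                 fraction_control = fraction_control[nm],
                 seed = as.integer(seed)),
            class = "MixtureConfig")
}

# Truncated log-normal sampler on the log10 scale via inverse CDF.
rTruncLog10 <- function(n, mean, sd, bounds) {
  lo <- log10(bounds[1]); hi <- log10(bounds[2])
  if (lo == hi) return(rep(bounds[1], n))
  if (sd == 0) {
    if (mean < lo || mean > hi) {
      stop("truncation bounds exclude all mass of the length distribution")
    }
    return(rep(10^mean, n))
  }
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  if (phi - plo < 1e-12) {
    stop("truncation bounds exclude all mass of the length distribution")
  }
  u <- runif(n, plo, phi)
  10^(mean + sd * qnorm(u))
}

#' Simulate per-gene length annotation
#'
#' Gene lengths are drawn from the configured truncated log-normal and
#' rounded to whole base pairs; exon lengths are a uniform random
#' fraction (0.2-1) of the gene length. All genes are `protein_coding`
#' except an optional non-coding spike-in fraction (biotype `lincRNA`)
#' used to exercise the coding filter.
#'
#' @param config a [syntheticConfig()].
#' @return a [GeneAnnotation-class] with `n_genes` genes.
#' @export
simulateLengths <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(config$seed + .SEED_LENGTHS, {
    n <- config$n_genes
    len <- round(rTruncLog10(n, config$length_log10_mean,
                             config$length_log10_sd, config$length_bounds))
    len <- pmin(pmax(len, config$length_bounds[1]), config$length_bounds[2])
    frac <- runif(n, 0.2, 1)
    exon <- pmin(pmax(round(len * frac), 1), len)
    biotype <- rep("protein_coding", n)
    n_nc <- floor(config$noncoding_fraction * n)
    if (n_nc > 0L) biotype[sample.int(n, n_nc)] <- "lincRNA"
    GeneAnnotation(
      gene_id = sprintf("G%06d", seq_len(n)),
      gene_length = len, exon_length = exon, biotype = biotype
    )
  })
}

#' Simulate a two-condition expression matrix with a planted length effect
#'
#' Case samples' expected log2 expression for gene g is
#' `baseline(g) + beta * (log10 length(g) - center)` with `center` the
#' mean log10 length, so the planted fold change averages zero over
#' genes; control expectation is `baseline(g)`. Intensity mode adds
#' Gaussian noise on the log2 scale and returns `log2` values; counts
#' mode exponentiates to the linear scale, allocates the configured
#' sequencing depth proportionally and draws Poisson counts.
#'
#' @param config a [syntheticConfig()].
#' @param annot optional [GeneAnnotation-class]; simulated from `config`
#'   when omitted.
#' @return list with `matrix` (an [ExpressionMatrix-class] with
#'   condition labels `case`/`control`), `annotation`, and `truth`
#'   (list: `beta`, `center`, named `expected_logfc`, `seed`).
#' @export
simulateExpression <- function(config, annot = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(annot)) annot <- simulateLengths(config)
  stopifnot(is(annot, "GeneAnnotation"))
  lens <- geneLengths(annot)
  n <- length(lens)
  l10 <- log10(unname(lens))
  center <- mean(l10)
  expected_lfc <- config$beta * (l10 - center)
  withSeed(config$seed + .SEED_EXPRESSION, {
    baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
    n_case <- config$n_case; n_control <- config$n_control
    mu <- cbind(
      matrix(baseline + expected_lfc, n, n_case),
      matrix(baseline, n, n_control)
    )
    log2_expr <- mu + matrix(rnorm(n * (n_case + n_control), 0,
                                   config$noise_sd),
                             n, n_case + n_control)
    sample_ids <- c(sprintf("case_%02d", seq_len(n_case)),
                    sprintf("control_%02d", seq_len(n_control)))
    condition <- rep(c("case", "control"), c(n_case, n_control))
    dimnames(log2_expr) <- list(names(lens), sample_ids)
    mat <- if (config$platform == "intensity") {
      ExpressionMatrix(log2_expr, scale = "log2", condition = condition)
    } else {
      lin <- 2^log2_expr
      p <- sweep(lin, 2, colSums(lin), "/")
      cnt <- matrix(rpois(length(p), config$count_depth * p),
                    n, ncol(p), dimnames = dimnames(p))
      ExpressionMatrix(cnt, scale = "counts", condition = condition)
    }
    list(matrix = mat, annotation = annot,
         truth = list(beta = config$beta, center = center,
                      expected_logfc = setNames(expected_lfc, names(lens)),
                      seed = config$seed))
  })
}

#' Simulate tissue samples as shifting mixtures of cell-type profiles
#'
#' Builds one log2 expression profile per cell type
#' (`shared baseline(g) + type baseline + type slope * (log10 length - center)`,
#' plus the type's `case_shift_slope` in case samples), then forms
#' tissue samples as proportion-weighted sums of the cell-type profiles
#' on the linear scale (mRNA pools add linearly) before logging.
#' Per-sample Gaussian noise is applied on the log2 scale to cell-type
#' samples and to the mixed tissue samples. With a positive neuron slope
#' and a neuron fraction that drops from control to case, the tissue
#' fold-change curve decreases with length even while the within-neuron
#' contrast increases with length — a composition effect.
#'
#' @param mix a [mixtureConfig()].
#' @param config a [syntheticConfig()] (supplies gene/sample counts,
#'   baselines and noise).
#' @param annot optional [GeneAnnotation-class].
#' @return list with `cell_types` (named list of
#'   [ExpressionMatrix-class], case+control samples per type), `tissue`
#'   (an [ExpressionMatrix-class] of mixed case/control samples),
#'   `annotation` and `truth`.
#' @export
simulateCellMixture <- function(mix, config, annot = NULL) {
  stopifnot(inherits(mix, "MixtureConfig"),
            inherits(config, "SyntheticConfig"))
  if (is.null(annot)) annot <- simulateLengths(config)
  lens <- geneLengths(annot)
  n <- length(lens)
  l10 <- log10(unname(lens))
  center <- mean(l10)
  ct <- mix$cell_types
  nm <- as.character(ct$name)
  n_case <- config$n_case; n_control <- config$n_control
  condition <- rep(c("case", "control"), c(n_case, n_control))
  sample_ids <- c(sprintf("case_%02d", seq_len(n_case)),
                  sprintf("control_%02d", seq_len(n_control)))
  withSeed(config$seed + .SEED_MIXTURE, {
    baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
    noise <- function() {
      matrix(rnorm(n * (n_case + n_control), 0, config$noise_sd),
             n, n_case + n_control)
    }
    # per-type expected log2 profiles, control and case
    prof_control <- lapply(seq_len(nrow(ct)), function(i) {
      baseline + ct$baseline[i] + ct$slope[i] * (l10 - center)
    })
    prof_case <- lapply(seq_len(nrow(ct)), function(i) {
      prof_control[[i]] + ct$case_shift_slope[i] * (l10 - center)
    })
    names(prof_control) <- names(prof_case) <- nm
    cell_mats <- lapply(nm, function(ty) {
      mu <- cbind(matrix(prof_case[[ty]], n, n_case),
                  matrix(prof_control[[ty]], n, n_control))
      v <- mu + noise()
      dimnames(v) <- list(names(lens), sample_ids)
      ExpressionMatrix(v, scale = "log2", condition = condition)
    })
    names(cell_mats) <- nm
    mix_linear <- function(profiles, fractions) {
      Reduce(`+`, lapply(nm, function(ty) {
        fractions[[ty]] * 2^profiles[[ty]]
      }))
    }
    tissue_mu <- cbind(
      matrix(log2(mix_linear(prof_case, mix$fraction_case)), n, n_case),
      matrix(log2(mix_linear(prof_control, mix$fraction_control)), n,
             n_control)
    )
    tissue <- tissue_mu + noise()
    dimnames(tissue) <- list(names(lens), sample_ids)
    list(
      cell_types = cell_mats,
      tissue = ExpressionMatrix(tissue, scale = "log2",
                                condition = condition),
      annotation = annot,
      truth = list(center = center, cell_types = ct,
                   fraction_case = mix$fraction_case,
                   fraction_control = mix$fraction_control,
                   seed = config$seed)
    )
  })
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits `matrix.tsv` (expression), `annotation.tsv`, `conditions.tsv`
#' and `truth.json` (the generating parameters and per-gene expected
#' log fold change), all deterministic under the config seed.
#'
#' @param outdir output directory, created if needed.
#' @param config a [syntheticConfig()].
#' @return named character vector of the four file paths, invisibly.
#' @export
writeFixtureBundle <- function(outdir, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateExpression(config)
  paths <- c(
    matrix = file.path(outdir, "matrix.tsv"),
    annotation = file.path(outdir, "annotation.tsv"),
    conditions = file.path(outdir, "conditions.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  writeExpressionMatrix(sim$matrix, paths[["matrix"]])
  writeGeneAnnotation(sim$annotation, paths[["annotation"]])
  cond <- sampleConditions(sim$matrix)
  write.table(data.frame(sample_id = names(cond), condition = unname(cond)),
              paths[["conditions"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- c(sim$truth["beta"], sim$truth["center"], sim$truth["seed"],
             list(platform = config$platform,
                  n_genes = config$n_genes,
                  noise_sd = config$noise_sd,
                  expected_logfc = as.list(sim$truth$expected_logfc)))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
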