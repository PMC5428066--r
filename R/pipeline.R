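#' @include bootstrap.R detest.R
NULL

#' Assemble and validate a pipeline run configuration
#'
#' Defaults follow the standard analysis parameters: 200-gene windows
#' with a 40-gene step, 100 shuffle iterations, a 95% envelope and a
#' per-gene DE threshold of 0.01.
#'
#' @param matrix path to the expression matrix TSV.
#' @param annotation path to a gene annotation TSV or a GTF (detected by
#'   a `.gtf` extension).
#' @param conditions path to the sample-condition TSV.
#' @param outdir output directory.
#' @param case,control condition labels of the contrast.
#' @param scale declared scale of the matrix values.
#' @param platform `"intensity"` or `"counts"`; decides the
#'   normalization route (probe-style log2 intensities vs exon-density
#'   normalized counts).
#' @param probe_map optional probe-to-gene map TSV; when given, probe
#'   rows are collapsed to genes (intensity platform).
#' @param quantile_scale quantile-normalize on the `"log"` or `"linear"`
#'   scale; defaults to log for intensity data and linear (exon
#'   density, then logged) for counts.
#' @param pseudocount pseudocount for the counts route (added to counts
#'   before the exon-density division; default 1).
#' @param window,step,n_iterations,ci,de_alpha,family_size,seed analysis
#'   parameters; see [binCurve()], [bootstrapEnvelope()],
#'   [perGeneTTest()], [lengthShiftTest()].
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(matrix, annotation, conditions, outdir,
                      case = "case", control = "control",
                      scale = "log2",
                      platform = c("intensity", "counts"),
                      probe_map = NULL,
                      quantile_scale = NULL,
                      pseudocount = 1,
                      window = 200L, step = 40L,
                      n_iterations = 100L, ci = 0.95,
                      de_alpha = 0.01, family_size = 2L,
                      seed = 1L) {
  platform <- match.arg(platform)
  if (is.null(quantile_scale)) {
    quantile_scale <- if (platform == "intensity") "log" else "linear"
  }
  quantile_scale <- match.arg(quantile_scale, c("log", "linear"))
  cfg <- list(matrix = matrix, annotation = annotation,
              conditions = conditions, outdir = outdir,
              case = case, control = control, scale = scale,
              platform = platform, probe_map = probe_map,
              quantile_scale = quantile_scale, pseudocount = pseudocount,
              window = as.integer(window), step = as.integer(step),
              n_iterations = as.integer(n_iterations), ci = ci,
              de_alpha = de_alpha, family_size = as.integer(family_size),
              seed = as.integer(seed))
  stopifnot(cfg$window >= 2L, cfg$step >= 1L, cfg$step <= cfg$window,
            cfg$ci > 0, cfg$ci < 1, cfg$de_alpha > 0, cfg$de_alpha < 1,
            cfg$n_iterations >= 1L, cfg$pseudocount >= 0)
  for (field in c("matrix", "annotation", "conditions", "outdir")) {
    if (is.null(cfg[[field]]) || !nzchar(cfg[[field]])) {
      stop(sprintf("run config field '%s' is required", field), call. = FALSE)
    }
  }
  structure(cfg, class = "RunConfig")
}

#' Read a pipeline run configuration from a YAML file
#'
#' Keys mirror the arguments of [runConfig()]; `overrides` (typically
#' from command-line flags) take precedence over file values.
#'
#' @param path YAML file.
#' @param overrides named list of values overriding the file's.
#' @return a validated `RunConfig`.
#' @export
readRunConfig <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals <- modifyList(vals, overrides)
  do.call(runConfig, vals)
}

#' Run the full length-effect analysis pipeline
#'
#' Executes, in order: read inputs, platform normalization (probe
#' collapsing for intensity data, exon-density normalization for
#' counts), quantile normalization, log transform where needed,
#' protein-coding filter, per-gene fold change, length-binned curve,
#' shuffle-null envelope, window flags and envelope distance, and the
#' per-gene DE + length-shift test. Writes `curve.tsv`, `envelope.tsv`,
#' `de_genes.tsv`, `length_shift.tsv`, `boxplot_summary.tsv` and
#' `run_log.txt` into the output directory; every file header embeds
#' the configuration and seed, and the log records the gene count
#' surviving each stage. All outputs are deterministic for a fixed
#' config, so reruns are byte-identical.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return invisibly, a list with the in-memory results (`matrix`,
#'   `profile`, `curve`, `envelope`, `flags`, `distance`, `de`, `shift`,
#'   `boxplot`) and `paths` of the written files.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines[[length(log_lines) + 1L]] <<- sprintf(fmt, ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  x <- stage("read_matrix", readExpressionMatrix(
    config$matrix, scale = config$scale, condition_map = config$conditions))
  note("read_matrix: %d genes x %d samples (scale %s)", nrow(x), ncol(x),
       exprScale(x))
  annot <- stage("read_annotation", {
    if (grepl("\\.gtf(\\.gz)?$", config$annotation, ignore.case = TRUE)) {
      geneLengthsFromGTF(config$annotation)
    } else {
      readGeneAnnotation(config$annotation)
    }
  })
  note("read_annotation: %d genes annotated", length(annot))

  if (config$platform == "intensity") {
    if (exprScale(x) %in% c("counts", "linear")) {
      x <- stage("log_transform", logTransform(x, base = 2))
      note("log_transform: intensity values moved to log2")
    }
    if (!is.null(config$probe_map)) {
      pm <- stage("read_probe_map", readProbeMap(config$probe_map))
      n_before <- nrow(x)
      x <- stage("collapse_probes", collapseProbes(x, pm))
      note("collapse_probes: %d probes -> %d genes", n_before, nrow(x))
    }
    x <- stage("quantile_normalize", quantileNormalize(x))
    note("quantile_normalize: applied on log2 scale")
  } else {
    x <- stage("exon_density_normalize",
               exonDensityNormalize(x, annot,
                                    pseudocount = config$pseudocount))
    note("exon_density_normalize: counts -> reads/base (pseudocount %g)",
         config$pseudocount)
    if (config$quantile_scale == "linear") {
      x <- stage("quantile_normalize", quantileNormalize(x))
      note("quantile_normalize: applied on linear exon-density scale")
      x <- stage("log_transform", logTransform(x, base = 2, pseudocount = 0))
    } else {
      x <- stage("log_transform", logTransform(x, base = 2, pseudocount = 0))
      x <- stage("quantile_normalize", quantileNormalize(x))
      note("quantile_normalize: applied on log2 exon-density scale")
    }
  }

  n_before <- nrow(x)
  x <- stage("filter_protein_coding",
             suppressMessages(filterProteinCoding(x, annot)))
  note("filter_protein_coding: %d -> %d genes", n_before, nrow(x))

  profile <- stage("fold_change",
                   computeFoldChange(x, config$case, config$control, annot))
  note("fold_change: %d genes in profile (%s vs %s)", length(profile),
       paste(config$case, collapse = "+"),
       paste(config$control, collapse = "+"))
  curve <- stage("bin_curve",
                 binCurve(profile, window = config$window,
                          step = config$step))
  note("bin_curve: %d windows of %d genes, step %d", length(curve),
       config$window, config$step)
  env <- stage("bootstrap_envelope",
               bootstrapEnvelope(profile, window = config$window,
                                 step = config$step,
                                 n_iterations = config$n_iterations,
                                 ci = config$ci, seed = config$seed))
  flags <- callSignificantWindows(curve, env)
  dist <- envelopeDistance(curve, env)
  note("envelope: %d above, %d inside, %d below; mean distance %.4g",
       sum(flags == "above"), sum(flags == "inside"),
       sum(flags == "below"), dist$mean_distance)

  delen <- stage("de_length_test",
                 deLengthPipeline(x, config$case, config$control, annot,
                                  de_alpha = config$de_alpha,
                                  family_size = config$family_size))
  note("de_length_test: %d up, %d down at alpha %g",
       length(upGenes(delen$de)), length(downGenes(delen$de)),
       config$de_alpha)

  meta <- config[c("case", "control", "scale", "platform", "quantile_scale",
                   "window", "step", "n_iterations", "ci", "de_alpha",
                   "family_size", "seed")]
  paths <- c(
    curve = file.path(config$outdir, "curve.tsv"),
    envelope = file.path(config$outdir, "envelope.tsv"),
    de_genes = file.path(config$outdir, "de_genes.tsv"),
    length_shift = file.path(config$outdir, "length_shift.tsv"),
    boxplot = file.path(config$outdir, "boxplot_summary.tsv"),
    log = file.path(config$outdir, "run_log.txt")
  )
  writeCurve(curve, paths[["curve"]], extra_meta = meta)
  writeEnvelope(env, curve, paths[["envelope"]], extra_meta = meta)
  de_df <- as.data.frame(delen$de)[, c("gene_id", "logfc", "p_value",
                                       "direction")]
  writeTsvWithHeader(de_df, paths[["de_genes"]], meta)
  writeTsvWithHeader(delen$shift, paths[["length_shift"]],
                     c(meta, list(quartile_type = 7,
                                  test = delen$de@method,
                                  length_units = "bp")))
  writeTsvWithHeader(delen$boxplot, paths[["boxplot"]],
                     c(meta, list(quartile_type = 7)))
  writeLines(c("# lendex pipeline run log", log_lines), paths[["log"]])

  invisible(list(matrix = x, profile = profile, curve = curve,
                 envelope = env, flags = flags, distance = dist,
                 de = delen$de, shift = delen$shift,
                 boxplot = delen$boxplot, paths = paths))
}
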