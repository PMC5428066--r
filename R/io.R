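#' @include AllClasses.R
NULL

#' Read a genes-by-samples expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; remaining cells are numeric. Lines starting with `#` are
#' treated as metadata comments and skipped.
#'
#' @param path path to a TSV/CSV file.
#' @param scale declared units of the values (`"counts"`, `"linear"`,
#'   `"log2"`, `"log10"`).
#' @param condition_map optional condition labels: a named character
#'   vector (names = sample ids) or the path of a two-column TSV
#'   `sample_id<TAB>condition`. Every sample named in the map must appear
#'   in the matrix header.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @param transpose set `TRUE` for files with samples in rows and genes in
#'   columns; the matrix is transposed to the genes-in-rows orientation
#'   after reading.
#' @return an [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path, scale, condition_map = NULL,
                                 sep = "\t", transpose = FALSE) {
  df <- readTsvNoComments(path, sep = sep)
  if (ncol(df) < 2L) stop("matrix file needs an id column plus >= 1 sample")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopListing("duplicate gene ids in matrix", dup)
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop(sprintf(
        "non-numeric value '%s' at row %d (gene '%s'), column '%s'",
        col[bad], bad, ids[bad], names(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  condition <- NULL
  if (!is.null(condition_map)) {
    if (is.character(condition_map) && length(condition_map) == 1L &&
        is.null(names(condition_map)) && file.exists(condition_map)) {
      condition_map <- readConditionMap(condition_map)
    }
    missing <- setdiff(names(condition_map), colnames(m))
    if (length(missing)) {
      stopListing("condition_map names samples absent from the matrix header",
                  missing)
    }
    condition <- setNames(rep(NA_character_, ncol(m)), colnames(m))
    condition[names(condition_map)] <- condition_map
  }
  ExpressionMatrix(m, scale = scale, condition = condition)
}

#' Write an expression matrix as TSV
#'
#' Emits a `gene_id` column followed by one column per sample, readable
#' back with [readExpressionMatrix()].
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(x), exprValues(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-condition map from a two-column TSV
#'
#' @param path TSV with columns `sample_id`, `condition` (header optional
#'   but recommended).
#' @return named character vector, names are sample ids.
#' @export
readConditionMap <- function(path) {
  df <- readTsvNoComments(path, header = TRUE)
  if (ncol(df) < 2L) stop("condition map needs two columns")
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a gene annotation table
#'
#' TSV with header; requires columns `gene_id` and `gene_length`, and
#' optionally `exon_length` and `biotype` (missing biotype defaults to
#' `protein_coding`, matching tables exported for coding genes only).
#'
#' @param path TSV path.
#' @return a [GeneAnnotation-class].
#' @export
readGeneAnnotation <- function(path) {
  df <- readTsvNoComments(path)
  if (!all(c("gene_id", "gene_length") %in% names(df))) {
    stop("annotation table needs columns gene_id and gene_length")
  }
  GeneAnnotation(
    gene_id = df$gene_id,
    gene_length = df$gene_length,
    exon_length = if ("exon_length" %in% names(df)) df$exon_length else NA_real_,
    biotype = if ("biotype" %in% names(df)) df$biotype else "protein_coding"
  )
}

#' Write a gene annotation table as TSV
#'
#' @param annot a [GeneAnnotation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(annot, path) {
  stopifnot(is(annot, "GeneAnnotation"))
  write.table(annot@data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive gene and exon lengths from a GTF file
#'
#' Gene length is the genomic span of the `gene` feature
#' (`end - start + 1`); exon length is the total length of the union of
#' the gene's exon intervals, with overlapping exons merged and strand
#' ignored (lengths are strand-symmetric). The biotype is taken from the
#' `gene_biotype` attribute when present, otherwise left `NA`.
#'
#' Exon records whose `gene_id` matches no `gene` feature are skipped
#' with a warning.
#'
#' @param path GTF file (Ensembl-style attributes `gene_id`,
#'   `gene_biotype`); coordinates 1-based inclusive.
#' @return a [GeneAnnotation-class].
#' @export
geneLengthsFromGTF <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"type" %in% names(S4Vectors::mcols(gr))) {
    stop("GTF has no feature type column")
  }
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) stop("GTF contains no 'gene' features")
  gene_ids <- as.character(genes$gene_id)
  if (anyDuplicated(gene_ids)) {
    stopListing("duplicate gene features in GTF",
                unique(gene_ids[duplicated(gene_ids)]))
  }
  exons <- gr[gr$type == "exon"]
  exon_len <- setNames(rep(NA_real_, length(gene_ids)), gene_ids)
  if (length(exons)) {
    ex_gene <- as.character(exons$gene_id)
    unknown <- setdiff(unique(ex_gene), gene_ids)
    if (length(unknown)) {
      warning(sprintf("skipping exons of %d unknown gene(s): %s",
                      length(unknown), paste(head(unknown, 5), collapse = ", ")))
      keep <- !(ex_gene %in% unknown)
      exons <- exons[keep]
      ex_gene <- ex_gene[keep]
    }
    if (length(exons)) {
      by_gene <- GenomicRanges::split(exons, ex_gene)
      merged <- GenomicRanges::reduce(by_gene, ignore.strand = TRUE)
      lens <- sum(GenomicRanges::width(merged))
      exon_len[names(lens)] <- as.numeric(lens)
    }
  }
  biotype <- if ("gene_biotype" %in% names(S4Vectors::mcols(genes))) {
    as.character(genes$gene_biotype)
  } else NA_character_
  GeneAnnotation(
    gene_id = gene_ids,
    gene_length = as.numeric(GenomicRanges::width(genes)),
    exon_length = unname(exon_len),
    biotype = biotype
  )
}

#' Read a probe-to-gene map
#'
#' Two-column TSV: `probe_id<TAB>gene_ids` with the second column a
#' comma-separated list of gene identifiers.
#'
#' @param path TSV path.
#' @return named list mapping probe id to a character vector of gene ids.
#' @export
readProbeMap <- function(path) {
  df <- readTsvNoComments(path)
  if (ncol(df) < 2L) stop("probe map needs two columns")
  probes <- as.character(df[[1L]])
  if (anyDuplicated(probes)) {
    stopListing("duplicate probe ids", unique(probes[duplicated(probes)]))
  }
  genes <- strsplit(as.character(df[[2L]]), ",[ ]*")
  if (any(lengths(genes) == 0L)) stop("probe map has probes with no gene")
  setNames(genes, probes)
}

#' Restrict a matrix to annotated protein-coding genes
#'
#' Keeps exactly the genes that are (i) present in the annotation,
#' (ii) annotated with biotype `protein_coding`, and (iii) present in the
#' matrix, preserving the matrix row order and the full sample set. Genes
#' dropped because they are missing from the annotation or non-coding are
#' reported via [message()].
#'
#' @param x an [ExpressionMatrix-class].
#' @param annot a [GeneAnnotation-class].
#' @return the filtered [ExpressionMatrix-class].
#' @export
filterProteinCoding <- function(x, annot) {
  stopifnot(is(x, "ExpressionMatrix"), is(annot, "GeneAnnotation"))
  bt <- bioTypes(annot)
  coding <- names(bt)[!is.na(bt) & bt == "protein_coding"]
  keep <- rownames(x) %in% coding
  if (!any(keep)) {
    stop("no protein-coding annotated genes in the matrix; nothing to analyze")
  }
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf(
      "filterProteinCoding: dropped %d of %d genes (non-coding or unannotated); %d retained",
      n_drop, nrow(x), sum(keep)))
  }
  x[keep, ]
}
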