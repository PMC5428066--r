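# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded operations do
#' not perturb the global random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Row-wise sample variance with n-1 denominator; 0 when a row has one column.
rowVarsMat <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

# Write a data.frame as TSV preceded by '#'-prefixed metadata lines.
# Deliberately timestamp-free so reruns are byte-identical.
writeTsvWithHeader <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key,
                       paste(format(meta[[key]], trim = TRUE), collapse = ",")),
               con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsvNoComments <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# Abort with the offending values listed (truncated for readability).
stopListing <- function(msg, items, max_show = 5L) {
  shown <- head(items, max_show)
  suffix <- if (length(items) > max_show) {
    sprintf(", ... (%d total)", length(items))
  } else ""
  stop(sprintf("%s: %s%s", msg, paste(shown, collapse = ", "), suffix),
       call. = FALSE)
}
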