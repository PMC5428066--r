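#' @include foldchange.R
NULL

#' Randomly re-pair per-gene statistics with gene lengths
#'
#' Returns a profile in which the multiset of log fold changes and the
#' multiset of lengths are both preserved but the pairing between them is
#' a uniform random permutation — an "unnatural" pairing that destroys
#' any length dependence while keeping both marginals intact. The
#' per-gene variance travels with its log fold change.
#'
#' @param profile a [FoldChangeProfile-class].
#' @param seed optional integer seed; when supplied the permutation is
#'   drawn under that seed without disturbing the caller's RNG state.
#' @return a [FoldChangeProfile-class] with permuted pairing.
#' @export
permuteLengthAssignment <- function(profile, seed = NULL) {
  stopifnot(is(profile, "FoldChangeProfile"))
  n <- length(profile@gene_id)
  perm <- if (is.null(seed)) sample.int(n) else withSeed(seed, sample.int(n))
  FoldChangeProfile(
    gene_id = profile@gene_id,
    logfc = profile@logfc[perm],
    variance = profile@variance[perm],
    length = profile@length
  )
}

#' Shuffle-null envelope for the length-binned curve
#'
#' Repeatedly randomizes the pairing between per-gene log fold changes
#' and gene lengths, recomputes the sliding-window means for each
#' replicate, and returns the pointwise empirical quantile band (linear
#' interpolation between order statistics) across replicates. By default
#' the shuffle is a permutation (sampling without replacement), which
#' preserves the exact multiset of statistics; `replace = TRUE` gives
#' classical resampling with replacement for comparison.
#'
#' @param profile a [FoldChangeProfile-class].
#' @param window,step window size and step, as in [binCurve()].
#' @param n_iterations number of shuffle replicates (default 100). Fewer
#'   than 20 triggers a warning for a 95% band, whose tail quantiles are
#'   then unstable.
#' @param ci central coverage of the band, in (0, 1) (default 0.95).
#' @param seed integer seed; required and recorded in the result.
#' @param replace draw statistics with replacement instead of permuting.
#' @param sampler advanced hook: function mapping the sorted statistic
#'   vector to one null replicate; overrides `replace` when supplied.
#' @return a [BootstrapEnvelope-class] over the same windows as
#'   `binCurve(profile, window, step)`.
#' @export
bootstrapEnvelope <- function(profile, window = 200L, step = 40L,
                              n_iterations = 100L, ci = 0.95, seed,
                              replace = FALSE, sampler = NULL) {
  stopifnot(is(profile, "FoldChangeProfile"))
  if (missing(seed)) stop("bootstrapEnvelope requires an explicit seed")
  if (ci <= 0 || ci >= 1) stop("ci must lie in (0, 1)")
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (n_iterations < 20L && ci >= 0.95) {
    warning(sprintf(
      "only %d iterations: %.0f%% envelope quantiles will be unstable",
      n_iterations, 100 * ci))
  }
  n <- length(profile@gene_id)
  window <- as.integer(window)
  starts <- windowStarts(n, window, step)
  ord <- lengthOrder(profile@length, profile@gene_id)
  s <- profile@logfc[ord]
  L <- profile@length[ord]
  mean_length <- windowMeans(L, starts, window)
  if (is.null(sampler)) {
    sampler <- if (replace) {
      function(v) sample(v, length(v), replace = TRUE)
    } else {
      function(v) sample(v)
    }
  }
  null_means <- withSeed(seed, {
    vapply(seq_len(n_iterations),
           function(i) windowMeans(sampler(s), starts, window),
           numeric(length(starts)))
  })
  null_means <- matrix(null_means, nrow = length(starts))
  # type-6 empirical quantiles: with 100 iterations the 2.5%/97.5% bounds
  # interpolate between the 2nd-3rd and 98th-99th order statistics, which
  # keeps the pointwise exceedance rate of an exchangeable observed curve
  # at the nominal 1 - ci
  probs <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  qs <- apply(null_means, 1L, quantile, probs = probs, type = 6,
              names = FALSE)
  new("BootstrapEnvelope",
      windows = data.frame(
        start = as.integer(starts),
        mean_length = mean_length,
        lower = qs[1L, ],
        upper = qs[2L, ]
      ),
      n_iterations = n_iterations, ci = ci, seed = as.integer(seed),
      window = window, step = as.integer(step), replace = replace)
}

# Both objects must describe the same windows of the same binning.
checkSameWindows <- function(curve, env) {
  if (!identical(curve@window, env@window) ||
      !identical(curve@step, env@step) ||
      !identical(curve@windows$start, env@windows$start)) {
    stop("curve and envelope describe different windows", call. = FALSE)
  }
}

#' Flag windows of an observed curve against a null envelope
#'
#' A window is `above` iff its observed mean strictly exceeds the upper
#' null quantile, `below` iff it falls strictly under the lower quantile,
#' and `inside` otherwise (so a mean exactly on a bound is `inside`).
#'
#' @param curve a [BinnedCurve-class].
#' @param env a [BootstrapEnvelope-class] over the identical windows.
#' @return factor with levels `below`, `inside`, `above`, one element per
#'   window, named by window start.
#' @export
callSignificantWindows <- function(curve, env) {
  stopifnot(is(curve, "BinnedCurve"), is(env, "BootstrapEnvelope"))
  checkSameWindows(curve, env)
  obs <- curve@windows$mean_stat
  flag <- ifelse(obs > env@windows$upper, "above",
                 ifelse(obs < env@windows$lower, "below", "inside"))
  factor(setNames(flag, curve@windows$start),
         levels = c("below", "inside", "above"))
}

#' Signed distance of an observed curve from a null envelope
#'
#' Per window: `mean_stat - upper` when above, `mean_stat - lower` when
#' below, 0 inside; the summary is the mean over windows. Larger absolute
#' summaries indicate observed curves further outside the null band — a
#' scalar measure of effect strength comparable across datasets.
#'
#' @param curve a [BinnedCurve-class].
#' @param env a matching [BootstrapEnvelope-class].
#' @return list with `distance` (numeric per window, named by start) and
#'   `mean_distance` (scalar summary).
#' @export
envelopeDistance <- function(curve, env) {
  stopifnot(is(curve, "BinnedCurve"), is(env, "BootstrapEnvelope"))
  checkSameWindows(curve, env)
  obs <- curve@windows$mean_stat
  d <- numeric(length(obs))
  above <- obs > env@windows$upper
  below <- obs < env@windows$lower
  d[above] <- obs[above] - env@windows$upper[above]
  d[below] <- obs[below] - env@windows$lower[below]
  list(distance = setNames(d, curve@windows$start), mean_distance = mean(d))
}

#' Write an envelope (with the observed curve and flags) as TSV
#'
#' Columns `window_start`, `mean_length_bp`, `lower`, `upper`,
#' `observed`, `flag`; `#` metadata lines record `n_iterations`, `ci` and
#' `seed`.
#'
#' @param env a [BootstrapEnvelope-class].
#' @param curve the matching observed [BinnedCurve-class].
#' @param path output path.
#' @param extra_meta named list of additional metadata lines.
#' @return `path`, invisibly.
#' @export
writeEnvelope <- function(env, curve, path, extra_meta = list()) {
  stopifnot(is(env, "BootstrapEnvelope"), is(curve, "BinnedCurve"))
  checkSameWindows(curve, env)
  flags <- callSignificantWindows(curve, env)
  df <- data.frame(
    window_start = env@windows$start,
    mean_length_bp = env@windows$mean_length,
    lower = env@windows$lower,
    upper = env@windows$upper,
    observed = curve@windows$mean_stat,
    flag = as.character(flags)
  )
  meta <- c(list(n_iterations = env@n_iterations, ci = env@ci,
                 seed = env@seed, window = env@window, step = env@step,
                 shuffle = if (env@replace) "with_replacement" else "permutation"),
            extra_meta)
  writeTsvWithHeader(df, path, meta)
}
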