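---
title: "Detecting gene-length-dependent misexpression with lendex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-length-dependent misexpression with lendex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lendex)
```

## The question and the statistic

Neurons express long genes more strongly than other cell types, and
several brain disorders perturb that preference: expression changes can
depend systematically on a gene's genomic length. Two features make
this effect awkward to test gene by gene. The per-gene fold-change
signal is weak and noisy, and the quantity of interest is not any
single gene but a *trend in length* across the entire transcriptome.

`lendex` implements the sliding-window statistic that makes the trend
visible. For a case/control contrast, each gene $g$ contributes a log2
fold change

$$\mathrm{logFC}_g = \overline{x}^{(case)}_g - \overline{x}^{(ctrl)}_g,$$

the difference of its per-condition mean log2 expression, with a
per-gene dispersion recorded as the sum of the two per-condition sample
variances. Genes are then sorted by genomic length and grouped into
overlapping windows of `window` consecutive genes advanced by `step`
(defaults 200 and 40); the curve of per-window mean logFC against mean
window length is the object of inference. Windowing by *rank* rather
than by fixed length intervals keeps every window at the same sample
size, so the curve's sampling error is homogeneous along the x-axis;
the window SEM is the standard deviation of the member statistics over
$\sqrt{\texttt{window}}$. Trailing genes that do not fill a complete
window are dropped rather than emitted as a smaller, noisier window.

## The shuffle null

A smooth curve invites over-reading, so significance comes from an
explicit null: the pairing between per-gene statistics and gene lengths
is destroyed by a uniform random permutation, the curve is recomputed,
and this is repeated `n_iterations` times (default 100). The pointwise
band between the 2.5% and 97.5% empirical quantiles of the null window
means is the 95% envelope; observed windows strictly above or below it
are flagged. Because the permutation preserves both marginals exactly
— the multiset of fold changes and the multiset of lengths — the
envelope asks precisely "could this curve arise if length carried no
information?", with no distributional assumptions.

Two numerical choices matter here:

* **Quantile estimator.** Envelope bounds use type-6 quantiles (linear
  interpolation between order statistics at plotting positions
  $k/(n+1)$). With 100 iterations the 97.5% bound interpolates between
  the 98th and 99th order statistics, and an exchangeability argument
  then puts the null probability of a window falling outside the band
  at very nearly the nominal 5%. R's default type-7 estimator places
  the same bound between the 97th and 98th order statistics and
  measurably over-flags (about 7% exceedance at 100 iterations) — the
  calibration study in the acceptance suite exists to pin this down.
* **Boundary convention.** A window mean exactly on a bound counts as
  `inside`; flags use strict inequalities.
* **Permutation, not resampling.** The shuffle draws without
  replacement, so every null replicate uses each observed value exactly
  once. A with-replacement mode (`replace = TRUE`) is available for
  comparison; it widens the envelope slightly because resampling adds
  multinomial noise to the marginal.

The signed distance of the observed curve beyond the envelope
(`envelopeDistance()`), averaged over windows, is a scalar effect-size
summary that lets different datasets or brain regions be ranked by how
far outside the null their curves sit.

Envelopes are pointwise. No simultaneous (family-wise) band is
computed: with a 95% pointwise band and ~100 overlapping windows, some
excursions are expected under the null, and the intended reading is the
coherent trend of many consecutive windows, not any single window.

## The threshold-based companion test

The curve treats all genes equally; a complementary analysis asks
whether *called* genes are length-biased. `perGeneTTest()` applies a
two-sided two-sample t-test per gene (Welch by default; the pooled
option exists) and splits genes with $p < 0.01$ — deliberately
uncorrected, since the threshold only defines gene sets — into up- and
down-regulated sets by the sign of the fold change.
`lengthShiftTest()` then compares the lengths of each set against the
lengths of **all** analyzed genes with a two-sample t-test and applies
a Bonferroni factor equal to the number of direction-by-contrast tests
in the family (e.g. 6 for two directions across three brain regions).
The set-versus-all comparison includes the set in its own reference;
this is the convention followed, with a disjoint set-versus-complement
option behind a flag. Lengths enter in raw base pairs by default —
heavy-tailed, which the t-test tolerates at these set sizes — with a
log-length option for sensitivity analysis.

Boxplot summaries of set lengths (median, type-7 quartiles, whiskers at
the most extreme values within 1.5×IQR, notch half-width
$1.58 \cdot \mathrm{IQR}/\sqrt{n}$) are emitted so the standard figure
can be redrawn from any dataset. Note the deliberate asymmetry: boxplot
quartiles use the common type-7 convention, envelope quantiles type 6;
each is stated in the corresponding output header.

## Getting data into the analysis

Expression arrives as a genes-by-samples delimited matrix with a
declared scale (`counts`, `linear`, `log2`, `log10`); the scale tag
gates which operations apply, so mixing counts into a log-scale
pipeline fails loudly rather than silently. Platform-specific
preprocessing mirrors standard practice:

* **Microarray intensities**: probes mapping to more than one gene are
  discarded; each gene's value is the mean of its probes' log2 rows
  (`collapseProbes()`).
* **RNA-seq counts**: counts are divided by the total length of the
  union of the gene's exons (`exonDensityNormalize()`), giving reads
  per exonic base — without this, long genes would trivially dominate.
* Samples are then quantile normalized to a shared distribution (the
  across-sample mean of order statistics). Ties receive the mean of the
  reference over their tied rank span, so tied inputs stay tied; on
  tie-free data the transformation is exactly idempotent, while under
  cross-column tie-pattern differences idempotence is only approximate
  — one reason the implementation states its tie convention in code
  and tests it directly.

Whether to quantile-normalize on the log or linear scale is genuinely
underdetermined; the driver's convention is log scale for intensity
data (where values are already logs) and the linear exon-density scale
for counts (then logged), with a config switch (`quantile_scale`) and a
log line recording which order ran. In the counts route a pseudocount
of one read per gene is added before the density division so that
densities are strictly positive ahead of the log; a pseudocount on the
density scale itself would be orders of magnitude larger than typical
densities (~10⁻³ reads/base) and was rejected.

Gene lengths come either from a two-column annotation table or from a
GTF, where gene length is the genomic span of the `gene` feature and
exon length the strand-ignored union of its exons. Genomic span (not
merged transcript length) is the interpretation adopted for "total gene
length", matching the default gene start/end fields of annotation
exports. Only protein-coding genes are analyzed; matrix genes that are
non-coding or unannotated are dropped with a logged count, and the
filter is idempotent.

## What the synthetic generator emulates

Because the method targets public expression datasets that cannot ship
with a package, every stage is exercised against a generator that
plants known structure:

* **Lengths** are truncated log-normal on the log10 scale (default
  mean 4.2, sd 0.5, truncated to 1 kb–1 Mb), spanning the three decades
  real gene lengths span.
* **Expression**: per-gene baseline $\sim N(6, 1)$ on the log2 scale;
  case samples add a planted slope $\beta$ in log2-fold-change units
  per log10 bp, centred on the mean log10 length so the planted fold
  change averages zero; per-sample Gaussian noise (default sd 0.5) on
  the log scale for intensity mode, Poisson counts at a configured
  depth for counts mode. Defaults (10+10 samples, 5,000 genes) describe
  a modest two-condition cohort.
* **Tissue mixtures**: cell types with their own baselines and length
  slopes are combined on the *linear* scale (mRNA pools add linearly)
  with per-condition proportions, then logged. A neuron type with a
  positive slope whose proportion falls from control to case produces a
  tissue-level curve that declines with length while the within-neuron
  contrast (with a planted positive case shift) rises — the composition
  effect that makes tissue-level down-regulation of long genes
  compatible with cell-level up-regulation.

The generator aims at statistical structure, not realism: no
gene-gene correlation, no batch structure, no mean-variance trend, no
dropout. Passing tests therefore demonstrate that the machinery
recovers planted effects and holds its nominal error rates under the
model's assumptions — not that any particular real dataset satisfies
those assumptions.

One subtlety: the generator derives sub-seeds by fixed offsets (lengths
at `seed`, expression at `seed + 1`, mixtures at `seed + 2`). Reusing
one stream for both the length draws and the baseline draws would make
the two sequences deterministic functions of the same uniforms and
plant a spurious length-baseline correlation; the offsets keep each
operation individually reproducible while decoupling the quantities.

## Reproducibility and the pipeline driver

Every stochastic operation takes an explicit seed and records it in its
output; `runPipeline()` writes TSVs whose `#` headers embed the full
configuration, and a run log records the gene count surviving each
stage. Outputs contain no timestamps, so a rerun with the same config
is byte-identical — this is asserted, not aspired to. The
`inst/scripts/lendex` Rscript exposes `simulate`, `curve`, `bootstrap`,
`detest` and `run` subcommands over the same functions.

## Problem sizes used in validation

The package's statistical checks run at sizes chosen to make their
Monte-Carlo error small relative to the bands they assert: envelope
calibration uses 200 replicates of 2,000 genes with 5+5 samples; slope
recovery averages 20 independent 5,000-gene datasets; the t-test
type-I rate uses 10,000 null genes; length-shift null uniformity uses
500 random subsets of a 10,000-gene annotation. The full-transcriptome
window count (19,881 genes into 493 windows of 200 at step 40) is
checked against brute-force enumeration.

## Known limitations

* The envelope is pointwise; no family-wise band across windows.
* The length-shift t-test treats genes as exchangeable units; gene-set
  correlation structure (co-expression, clustering of long genes in
  pathways) is outside the model.
* Quantile normalization assumes comparable global distributions —
  i.e. that most genes do not change; gross composition shifts violate
  this, which is exactly why the mixture simulation matters for
  interpreting tissue-level results.
* `collapseProbes()` implements the "one probe, one gene" restriction
  generically; it does not consult any probe-annotation database.
* Counts mode models technical noise as Poisson; no overdispersion
  parameter is exposed.
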