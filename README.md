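# lendex

Gene-length-dependent expression analysis for transcriptomes.

Neurons preferentially express long genes, and diseases that damage
neurons — or change the cellular composition of a tissue — can shift
expression in a way that depends systematically on gene length rather
than on any individual gene. `lendex` is for analysts who want to test
a case/control expression dataset (microarray intensities or RNA-seq
counts, bulk tissue or sorted cells) for such a length effect.

## The statistic

For each gene $g$, the contrast is summarized by the log2 fold change
of per-condition mean log2 expression,

$$\mathrm{logFC}_g = \overline{x}^{(case)}_g - \overline{x}^{(ctrl)}_g ,$$

with variance recorded as the sum of the two per-condition sample
variances. Genes are sorted by genomic length and binned into sliding
windows of 200 consecutive genes advanced in steps of 40; the curve of
per-window mean logFC versus mean window length is the central
statistic. Significance is assessed against a shuffle null: the pairing
of per-gene statistics with gene lengths is randomly permuted 100
times, and the pointwise 95% empirical quantile band of the null
curves (the *envelope*) is compared with the observed curve. A
complementary threshold-based test calls per-gene differential
expression (two-sample t-test, $p < 0.01$, uncorrected) and asks, via
a Bonferroni-corrected two-sample t-test, whether the up- and
down-regulated gene sets are length-shifted relative to all analyzed
genes.

Everything is testable offline: a synthetic-data module plants known
length-effect slopes and cell-type composition shifts, so calibration
and power of every stage are verified in the test suite without any
external downloads.

## Worked example

Simulate a 4,000-gene two-condition study with a planted length effect
of +0.4 log2-fold-change units per log10 bp, then run the analysis:

```r
library(lendex)

cfg <- syntheticConfig(n_genes = 4000, beta = 0.4, noise_sd = 0.5,
                       n_case = 10, n_control = 10, seed = 7)
sim <- simulateExpression(cfg)
sim$matrix
#> ExpressionMatrix: 4000 genes x 20 samples [scale: log2]
#> conditions: case (10), control (10)

prof  <- computeFoldChange(sim$matrix, "case", "control", sim$annotation)
curve <- binCurve(prof, window = 200, step = 40)
env   <- bootstrapEnvelope(prof, window = 200, step = 40, seed = 7)
env
#> BootstrapEnvelope: 96 windows, 100 iterations, 95% CI, seed 7 (permutation)

table(callSignificantWindows(curve, env))
#>  below inside  above
#>     39     17     40

head(curveWindows(curve), 3)
#>   start mean_length  mean_stat        sem n_genes
#> 1     0    1870.105 -0.3681574 0.01697180     200
#> 2    40    2147.930 -0.3490589 0.01683922     200
#> 3    80    2408.005 -0.3140253 0.01712854     200
```

The planted slope is centred, so short-gene windows sit below zero
(flagged `below`), long-gene windows above (`above`): 79 of 96 windows
fall outside the 95% null band. The threshold-based companion test
shows the same effect as a length shift of the called gene sets:

```r
res <- deLengthPipeline(sim$matrix, "case", "control", sim$annotation,
                        de_alpha = 0.01, family_size = 2)
res$shift
#>   direction n_set mean_length_set mean_length_all          t         p_raw
#> 1        up    77      138925.636        31278.88   6.213082  2.523258e-08
#> 2      down    88        5058.807        31278.88 -27.652723 5.677025e-126
```

Up-regulated genes average ~139 kb against a transcriptome mean of
~31 kb; down-regulated genes average ~5 kb. Both shifts survive the
Bonferroni correction.

The same analysis runs from the shell over TSV inputs via the bundled
script (`inst/scripts/lendex`), with subcommands `simulate`, `curve`,
`bootstrap`, `detest` and `run`; `runPipeline()` /`run` execute the
whole chain (platform normalization, quantile normalization,
protein-coding filter, curve, envelope, DE length test) and write
TSV outputs whose headers embed the configuration and seed.

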