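# tadmlr

Identify the genomic features that drive the borders of topologically
associating domains (TADs).

Hi-C experiments partition chromosomes into TADs, and dozens of
DNA-binding proteins, functional elements and sequence motifs are
*enriched* at the borders between them. Enrichment, however, cannot
distinguish a true border **driver** from a **passenger** that merely
colocalizes with one. `tadmlr` is for epigenomics researchers who have
TAD calls and ChIP-seq peaks (or signal, or motif hits) and want to know
which features positively or negatively *influence* border presence.

## The model

The genome is tiled into fixed-size bins; `Y = 1` marks bins inside a
window centered on a TAD junction, and each feature `X_i` is encoded per
bin as fractional occupancy (coordinate mode, values in [0, 1]) or mean
signal (quantitative mode). The core is a multiple logistic regression

    logit P(Y = 1 | X) = beta0 + beta1 X1 + ... + betap Xp,

fitted by iteratively reweighted least squares, with Wald statistics
`W = beta / se(beta)`, 95% confidence intervals, Bonferroni-corrected
significance, a likelihood-ratio alternative `D = 2(lM1 − lM2) ~ chi2(1)`
for sparse matrices, and two-way interaction terms `X1 X2` on request.
Because each `beta_i` is conditional on all other features, a passenger
of a correlated driver gets `beta ≈ 0` while the classical marginal
enrichment test — the single-covariate case, whose slope is exactly the
log odds ratio of the 2×2 border-by-feature table — flags both. For
hundreds of correlated candidates (e.g. motif libraries), an
L1-regularized fit with cross-validated penalty selects the influential
set. Simulation generators, a method-comparison harness (enrichment
test, random forests), and IUPAC motif SNP-effect analysis round out the
toolkit; see the vignette in `vignettes/tad-border-drivers.Rmd`.

## Worked example

A 2 Mb chromosome with TADs every 100 kb; a "driver" protein binds every
junction plus background sites, and a "passenger" shares 75% of the
driver's sites plus random sites of its own:

```r
library(tadmlr)

layout <- genome_layout(c(chr2L = 2e6))
bins   <- make_bins(layout, bin_size = 50)
tads   <- tibble::tibble(chrom = "chr2L",
                         start = seq(0, 1.9e6, by = 1e5),
                         end   = seq(1e5, 2e6, by = 1e5))
Y   <- label_borders(bins, tads, window = 1000)
mat <- assemble_matrix(bins, Y, list(
  driver    = encode_coordinate_feature(bins, driver_peaks),
  passenger = encode_coordinate_feature(bins, passenger_peaks)))

enrichment_scan(mat, alpha = 1e-5)
#>   feature   estimate std.error   p.value significant
#> 1 driver        4.07     0.112 2.80e-288 TRUE
#> 2 passenger     3.00     0.114 4.22e-152 TRUE

wald_inference(fit_mlr(mat), alpha = 1e-5)
#>   term      estimate std.error statistic   p.value conf.low conf.high significant
#> 1 driver       4.23      0.177     23.9  5.13e-126    3.89      4.58  TRUE
#> 2 passenger   -0.218     0.190     -1.15 2.50e-  1   -0.589     0.153 FALSE
```

The marginal enrichment test declares both proteins strongly enriched
(log odds ratios 4.07 and 3.00, both far past the Bonferroni threshold).
The joint model tells the real story: the driver keeps a large positive
beta (4.23), while the passenger's conditional effect is indistinguishable
from zero (−0.22, p = 0.25) — its enrichment was pure colocalization.

The same object supports `tidy()`, `glance()`, `fit_metrics()` (deviance
ratio, AIC) and `autoplot()`; `lrt_test(mat, "driver")` gives the
likelihood-ratio p-value; `fit_mlr(mat, estimator = "l1")` the penalized
fit. A command-line wrapper with `bin`, `enrich`, `mlr`, `simulate`,
`benchmark` and `motif-snp` subcommands is installed as
`inst/cli/tadborder.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/tadborder.R", package="tadmlr"))') \
  bin --tads tads.bed --peaks ctcf.bed,cp190.bed \
  --chrom-sizes genome.sizes --bin-size 50 --border-window 1000 \
  --out matrix.tsv
```

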