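# betastab

Analysis toolkit for post-transcriptional gene regulation in pancreatic
β cells, built around the question: *when a deadenylase subunit is lost,
which mRNAs go up because they are transcribed more, and which because they
are degraded less?*

## Who this is for

Researchers with bulk RNA-seq of control vs knockout islets quantified
separately over exonic and intronic regions, plus the companion functional
assays of a β-cell study: islet Ca²⁺ imaging, actinomycin-D decay courses,
qPCR (∆∆CT), RNA immunoprecipitation, bulk poly(A) gel densitometry, and
gene-set enrichment. Every analysis also runs end-to-end on built-in seeded
generators with recorded ground truth, so the statistical behaviour of the
whole pipeline is testable.

## The core statistic

Exonic reads track steady-state mRNA; intronic reads track transcription.
For each gene the change in mRNA stability between knockout and control is
estimated as

```
δ = ∆exon − ∆intron        (difference of log2 fold changes)
```

with significance from a per-gene count model of the exon:intron ratio
(feature-class × group interaction, conditioned on per-sample totals) and
BH-FDR across genes. A transcript is a candidate target of the deadenylase
when it is both **stabilized** (δ > 0, interaction FDR < 0.05) and
**upregulated** (exon-level DE). The DE engine underneath is the classic
count workflow — CPM filter, TMM normalization, quantile-equalized
pseudo-counts, moderated conditional-ML dispersions, exact conditional NB
test — re-implemented and calibrated (type-I error and FDR checks are part
of the test suite).

## Worked example

```r
library(betastab)

# 2000 genes, 3 control vs 3 knockout samples; 10% of genes stabilized
# (+1.5 log2), a disjoint 10% transcriptionally induced (+1.5 log2)
sim <- simulate_exon_intron_counts(2000, n_reps = 3, seed = 1)
res <- analyze_stability(sim$exon, sim$intron, fdr_alpha = 0.05)
res$summary
#> $n_stabilized
#> [1] 204
#> $n_stabilized_and_up
#> [1] 135
#> $n_stabilized_not_up
#> [1] 69
#> $fraction_up
#> [1] 0.6617647

head(res$records[res$records$class == "stabilized_up", c(1, 4, 6, 7)], 3)
#>       gene_id    delta          fdr         class
#> 8  gene_00008 1.186213 9.113742e-16 stabilized_up
#> 11 gene_00011 1.540415 1.439597e-09 stabilized_up
#> 23 gene_00023 1.452028 1.987159e-19 stabilized_up
```

Of 200 genes simulated as stabilized, 204 are called (197 true, 7 false:
sensitivity 0.985, empirical FDR 0.034 against the recorded truth in
`sim$truth`), and two-thirds of the stabilized calls are also significant
exon-level upregulations — the signature of a decay-factor knockout in which
stabilization drives steady-state increases. The per-gene `delta` estimates
sit within 0.15 log2 of the planted effects on average.

The same package drives the other assays, e.g.

```r
d <- simulate_decay(c(control = 2, knockout = 6), cv = 0.05, seed = 1)
compare_decay(d[d$genotype == "control", ], d[d$genotype == "knockout", ])$p
#> [1] 2.162054e-07   # knockout decays significantly more slowly

fit_half_life(d[d$genotype == "control", ])
#> half-life 1.99 h (95% CI 1.93-2.06), k = 0.348 /h, R2 = 1.000
```

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study workflow on
synthetic data and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_data.R` | all synthetic inputs + ground truth |
| `02_differential_expression.R` | exon & intron DE tables |
| `03_stability.R` | δ statistic, classification, truth recovery, reference overlap |
| `04_connectivity.R` | Ca²⁺ Pearson connectivity, % connected, epoch AUC |
| `05_decay_kinetics.R` | half-life fits, stabilization tests, ∆∆CT / RIP / β-cell mass |
| `06_polya_gsea.R` | poly(A) >50 nt fractions, GSEA, mRNA-protein correlation |

Run them in order with `Rscript analysis/01_simulate_data.R` etc.

## Documentation

The methods vignette (`vignettes/exon-intron-stability-methods.Rmd`)
explains the models, their assumptions, what the generators do and do not
emulate, and the numerical choices; every exported function carries roxygen
documentation.
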