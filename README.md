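# translatome

Transcriptome/translatome uncoupling analysis with 3'UTR motif association,
for two-fraction (total and polysome-bound RNA) expression studies of the
kind used to dissect post-transcriptional regulation after CNS injury.

After an injury, changes in a transcript's total abundance and in its
ribosome-bound abundance frequently disagree — translation is regulated on
top of transcription. Because the polysome-bound fraction is a subset of
total RNA, the two fractions cannot be normalized together, and the
interesting biology lives in their *disagreement*. This package implements
that analysis end to end for array-style intensity data, plus the axon
regeneration quantification used to validate candidate regulators in vivo:

* **Per-fraction normalization** — affine calibration + generalized log,
  `h_i(x) = glog2((x − a_i)/b_i)`, fit by profile maximum likelihood with
  least-trimmed-squares robustness (trimming quantile 0.5) so the fit
  survives widespread differential expression.
* **Moderated differential expression** — empirical-Bayes variance
  shrinkage with intensity trend:
  `s̃²_g = (d0·s0²(Ā_g) + d_g·s²_g)/(d0 + d_g)`,
  `t_g = log2FC_g / (s̃_g·√(1/n1+1/n2)) ~ t(d0+d_g)`, BH FDR < 0.05.
* **Uncoupling classification** — per-gene (total, polysome) state pairs
  mapped to eight categories (total-only, polysome-only, concordant,
  opposing, null), with z-score heatmap data and a marker-gene composition
  QC (Pearson r of naive vs injured marker profiles per fraction).
* **3'UTR motif association** — regex scanning for CPE, Hex, PBE, MBE and
  ARE elements (overlap-aware, fully configurable), two-sample
  Kolmogorov–Smirnov comparison of log2 fold-change distributions
  (`D = sup|ECDF₁ − ECDF₂|`; exact p for combined n ≤ 20), density-curve
  data, GO-subset analyses, ARE co-occurrence/synergy tests, and 5'UTR +
  random-motif negative controls.
* **GO enrichment** — exact hypergeometric over/under tails in two designs:
  up-regulated genes against the DE background per fraction, and genes
  whose transcripts all carry a motif against all unambiguous genes
  (experimental evidence codes only), with Cytoscape-ready node/edge
  export.
* **Axon regeneration** — the section-count estimator
  `Σa_d = πr²·(avg axons per mm)/t` and an exponential-decrease model
  `N(d) = N0·e^(−kd)` compared between groups via log-linear Wald tests,
  plus mean ± SEM / pooled-t sprout summaries.
* **Synthetic data** — `simulate_experiment()` generates a fully labelled
  two-fraction dataset (2 conditions × 3 replicates, planted uncoupling
  categories, planted motifs, a motif-dependent attenuation of
  injury-induced down-regulation in the total fraction, per-array affine
  distortions, intensity-dependent raw variance) so every stage is testable
  offline; `truth_report()` scores any pipeline output against the truth.

Functions take tibbles and return tibbles; fitted objects have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(translatome)

cfg <- sim_config(n_genes = 2000, seed = 7)      # study-like conditions
sim <- simulate_experiment(cfg)

res <- run_tsaa(sim$raw_total, sim$raw_polysome, sim$samples)
calls <- classify_uncoupling(res$total, res$polysome)
count_uncoupling(calls)
#> # A tibble: 8 × 2
#>   category            n
#>   <chr>           <int>
#> 1 total_up_only     103
#> 2 total_down_only    98
#> 3 poly_up_only       70
#> 4 poly_down_only     95
#> 5 concordant_up      58
#> 6 concordant_down    56
#> 7 opposing           35
#> 8 null             1585

scan <- scan_utrs(sim$utr3)                       # built-in motif set
assoc <- associate_motif(res$total, scan, sim$probeset2transcript, "CPE")
assoc
#> <motif_association> CPE (total, subset: all)
#>   n_with = 801, n_without = 1199; KS D = 0.3755, p = 3.01e-59 (asymptotic)
#>   median log2FC: with 0.190, without -0.104
```

The category counts show the planted design: more changes in total than in
polysome-bound RNA. The association result is the package's core readout —
CPE-containing transcripts sit ~0.29 log2 units higher than CPE-free ones
in the total fraction (the planted attenuation of injury-induced
down-regulation plus planted effects), and the KS test rejects
emphatically; running the same call on `res$polysome` gives p ≈ 0.91,
because nothing was planted there. `autoplot(assoc)` draws the two density
curves with per-transcript rugs.

For the regeneration module:

```r
est <- estimate_axons(sections)      # sections: per-section counts + widths
fit <- fit_exponential_decrease(est)
tidy(fit)                            # per-group N0 and decay rate k
glance(fit)                          # p-values for N0 and k differences
```

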