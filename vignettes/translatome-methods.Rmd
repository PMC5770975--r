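---
title: "Models and methods behind translatome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind translatome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translatome)
```

# The scientific problem

After a CNS injury, the change in a transcript's total abundance and the
change in its ribosome-engaged (polysome-bound) abundance can disagree:
transcription and translation are regulated separately, and stress responses
in particular remodel translation without matching changes in mRNA levels.
`translatome` implements the computational core of a *translation state
array analysis* (TSAA): both RNA fractions are profiled on separate arrays,
normalized separately, tested for differential expression separately, and
then compared gene-by-gene to classify the mode of regulation. Downstream,
3'UTR cis-elements (CPE, Hex, PBE, MBE, ARE) are scanned for and associated
with the injury-induced fold changes, GO enrichment is computed in two
designs, and a separate module quantifies axonal regeneration from
optic-nerve section counts.

Every stage is exercised end-to-end on a synthetic-data generator that
emulates the statistical structure of the real experiment, so the whole
pipeline is testable without any external download.

# Per-fraction normalization

The polysome-bound fraction is a biased subsample of total RNA, so
normalization methods that equate intensity distributions across arrays
cannot be applied across fractions. Each fraction is normalized alone with
an affine-calibration + generalized-log model: array $i$ is mapped by

$$h_i(x) = \operatorname{glog}_2\!\left(\frac{x - a_i}{b_i}\right),\qquad
\operatorname{glog}_2(y) = \log_2\!\left(y + \sqrt{y^2 + 1}\right),$$

which behaves like $\log_2(2y)$ for bright probesets and stays linear near
zero, stabilizing the variance of data with additive background noise plus
multiplicative signal noise. Base 2 is used so that downstream differences
are exactly log2 fold changes.

Parameters are fit by profile maximum likelihood under
$h_i(x_{gi}) \sim N(\mu_g, \sigma^2)$, i.e. by minimizing
$\tfrac{M}{2}\log \mathrm{RSS} - \sum_{g,i} \log h_i'(x_{gi})$ jointly over
all arrays. The Jacobian term matters: a pure least-squares fit can only
calibrate arrays *relative to one another* and would leave any background
offset shared by all arrays in the data, compressing the variance of dim
probesets. With the Jacobian the absolute offsets are identified by the
low-intensity (background) probesets. One near-flat direction remains — a
common rescaling of all $b_i$, which shifts every normalized value by a
constant — so the calibration table reports both absolute parameters and
values relative to the first array (`rel_offset`, `rel_scale`), the
quantity that is sharply identified. Fold changes and all downstream
statistics are invariant to the flat direction.

Robustness to widespread differential expression comes from least-trimmed
squares: each outer iteration keeps only the fraction `q` (default 0.5) of
probesets with the smallest residual sum of squares around their
across-array mean profile, and the likelihood is optimized on that subset
(`nlminb` with an analytic gradient). Convergence is declared when the
maximum relative parameter change drops below `tol` (default `1e-6`);
non-convergence warns and exposes the per-iteration trace. Constant arrays
and negative intensities are rejected.

# Moderated differential expression

Within a fraction, injured and naive arrays are compared per probeset with
an empirical-Bayes moderated t-test. The residual variances $s_g^2$ (with
$d_g$ degrees of freedom) are assumed to follow a scaled-F marginal around a
prior $(d_0, s_0^2)$, estimated by matching the first two moments of
$\log s_g^2$ (trigamma inversion by Newton's method). With the intensity
trend enabled (the default, matching the source protocol), $s_0^2$ becomes a
lowess smooth of the log-variances on average intensity (span 0.5, exposed
as an argument), and $d_0$ is estimated from the residual spread around the
smooth. The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ yields

$$t_g = \frac{\overline{z}_{g,\mathrm{injured}} - \overline{z}_{g,\mathrm{naive}}}
{\tilde s_g \sqrt{1/n_1 + 1/n_2}} \sim t_{d_0 + d_g},$$

two-sided. $d_0 = 0$ recovers the classical pooled t; $d_0 = \infty$ (no
excess spread in the log-variances, a legitimate boundary on homogeneous
data) uses the normal reference. BH adjustment is applied across probesets
and significance means FDR strictly below 0.05. The unit tests cross-check
the estimator and the full test against limma on shared data; the
implementation itself is self-contained.

Probesets mapping to more than one gene (or, for the UTR analyses, more
than one transcript) are excluded before any gene-level interpretation.

# Uncoupling classification

A probeset/gene is `up`, `down`, or `ns` in each fraction (FDR < threshold
and fold-change sign; a value exactly at the threshold is non-significant).
The pair of states maps through the 3×3 grid to eight categories
(total-only up/down, polysome-only up/down, concordant up/down, opposing,
null); "opposing" requires significance in *both* fractions with opposite
signs. The grid reconstruction is our reading of the figure-level grouping
in the source study, which does not enumerate its categories in text; the
mapping is a single documented lookup table and trivially replaceable.
Z-score heatmap data uses sample (n−1) standard deviations. The
marker-panel QC averages normalized marker-gene intensities over replicates
per condition and reports the naive-vs-injured Pearson correlation per
fraction: values near 1 indicate the injury did not change cellular
composition, so fraction-level differences are not driven by cell-type
shifts.

# UTR motif association

Motifs are POSIX/PCRE regular expressions over the DNA alphabet. The
defaults are literature-derived stand-ins (CPE `TTTTA{1,2}T`, Hex
`A[AT]TAAA`, PBE `TGTA[ACGT]ATA`, MBE `[GA]T{1,3}AGT`, ARE `ATTTA`); every
definition is overridable through a motif table or config file, and all
outputs record the regex actually used. Scanning counts overlapping
occurrences (the search resumes one position past each match start,
implemented as a zero-width lookahead), `N` never matches, `U` is folded to
`T`, and sequences are taken as the delivered sense strand. Association
uses presence (count ≥ 1), not count.

Transcripts are split by motif presence and their log2 fold-change
distributions compared with a two-sided Kolmogorov–Smirnov test: exact
(full enumeration of pooled-rank arrangements) when the combined sample is
at most 20, otherwise the asymptotic Kolmogorov distribution at
$\sqrt{n_e}\,D$ with $n_e = n_x n_y/(n_x + n_y)$. Density-curve output uses
a Gaussian KDE per group with Silverman's rule-of-thumb bandwidth on a
512-point grid spanning the pooled range ± 3 bandwidths, plus per-transcript
rug values. Groups smaller than 10 are flagged low-power but still
computed. GO-subset analyses restrict to transcripts of genes in the
supplied categories via the transcript→gene map.

Three negative-control designs guard against artefacts: (i) the same
pipeline on 5'UTRs, where the elements under study should be inert;
(ii) random motifs — literals of the template's canonical-literal length
drawn from the empirical mononucleotide composition of the scanned UTRs —
summarized as the fraction rejecting at $\alpha$; (iii) co-occurrence and
ARE-synergy analyses using one-sided exact hypergeometric tails on the 2×2
presence table.

# GO enrichment

Two designs share an exact hypergeometric core (`p_over = P(X ≥ k)`,
`p_under = P(X ≤ k)`; each tail BH-adjusted separately across terms,
matching the dual red/blue reporting convention in which
under-representation of up-regulated genes is displayed as enrichment of
down-regulated ones):

* **Directional**: hits are up-regulated DE genes; the universe is all DE
  genes of the fraction, so the test asks about direction within the
  response, not expression per se.
* **Genome-wide motif**: genes are collapsed over their protein-coding
  transcripts to `all` / `mixed` / `none` motif classes; hits are
  all-motif genes, the universe excludes mixed genes, and annotations are
  restricted to experimental evidence codes (EXP, IDA, IPI, IMP, IGI, IEP)
  so cross-genome comparisons cannot be inflated by homology-derived
  annotation.

Terms with fewer than 3 in-universe genes are skipped (configurable). When
a parent–child edge table is supplied, annotations are propagated to
ancestors before testing (transitive closure); without edges, membership is
used as given. Network export keeps terms significant in at least one
comparison at the display threshold (presets `1e-4` and `1e-5`), colors
nodes by direction with white above FDR 0.05, sizes them by −log10 FDR, and
induces the edge set on retained nodes.

The DE background for enrichment is taken at gene level after multi-mapper
exclusion; a probeset-level background is the obvious alternative and can
be had by passing probeset-keyed tables.

# Axonal regeneration

Counts of labelled axons in longitudinal optic-nerve sections are converted
to an estimated number of axons crossing distance $d$ from the lesion:

$$\sum a_d = \pi r^2 \cdot \frac{\text{average axons per mm}}{t},$$

with $r$ half the nerve width at the counting site, the per-mm average
taken over the sections at that site (typically 4 per animal), and $t$ the
section thickness (default 8 µm). All lengths are millimetres internally;
the estimate is invariant to any consistent unit change.

Group comparison fits $N(d) = N_0 e^{-kd}$ per group as a log-linear model
`log(N) ~ distance * group` with the animal×distance estimate as the
observational unit: the group main effect tests the difference in starting
axon number $N_0$ and the interaction the difference in decrease rate $k$,
each as a Wald t-test. Zero estimates cannot enter a log fit; rather than
silently adding an offset we exclude them with a reported count and provide
a `log(N + 0.5)` sensitivity refit alongside. Whether the original analysis
used per-animal or per-section units is not stated in the source; the
animal-level choice is ours and is the more conservative one. Sprout
metrics are summarized as mean ± SEM with two-tailed pooled-variance
Student t-tests.

# The synthetic-data generator

`sim_config()` / `simulate_experiment()` produce a fully labelled dataset
with the design of the motivating study: 2 fractions × 2 conditions ×
3 replicates. Its defaults are the package's statement of the study
conditions:

* Latent baseline expression on the glog2 scale: a 70/30 mixture of
  expressed probesets (mean 9, sd 1.5) and array background (mean 4, sd 1).
  The background component mirrors the many unexpressed genes on a real
  array and is what identifies absolute calibration offsets.
* Replicate noise: additive on the glog2 scale, sd 0.3 (a constant — i.e.
  weakly monotone — map of the latent mean, exposed as a function). On the
  raw scale this produces strongly intensity-dependent variance, so
  variance stabilization is verifiable by construction.
* Per-array affine distortions: offsets Uniform(0, 20), scales
  exp(N(0, 0.15)) by default, or exactly the vectors you pass.
* Injury effects of 1 log2 unit planted by uncoupling category; the default
  category mix (5%/5% total up/down, 2%/4% polysome up/down, 4%/4%
  concordant, 3% opposing, 73% null) reflects the study's qualitative
  description: more changes in total than polysome-bound RNA, with the
  polysome changes mostly down.
* The polysome fraction derives from the *same* latent expression through a
  per-gene loading factor Uniform(0.2, 1) (a subset-like signal, never an
  independent redraw), plus its own planted effects.
* 3'UTRs (AT-rich) and 5'UTRs (GC-rich) are random sequences with
  log-normal lengths; motif canonical literals are planted by per-motif
  Bernoulli draws. Truth motif flags are defined by *rescanning the emitted
  sequences*, so flags can never disagree with the FASTA, and background
  chance matches are treated identically to planted ones.
* The CPE attenuation: transcripts whose emitted 3'UTR contains the
  attenuation motif get +0.3 log2 added to their total-fraction injury
  effect — the mechanism under study (resistance to injury-induced
  down-regulation), planted only in the total fraction so the polysome
  fraction serves as a built-in negative control.
* Synthetic GO annotation with two designated development terms into which
  motif-carrying genes are enriched at odds 4; a 103-gene marker panel
  drawn from unaffected genes; 5% multi-mapping probesets and 5% non-coding
  biotypes to exercise the filters.

All randomness flows from one seed through fixed per-stage derived seeds,
so outputs are bit-for-bit reproducible. What the generator does *not*
emulate: probe-level summarization (data are generated at probeset level;
the upstream array-summarization step is out of scope), correlated noise
between genes, batch structure, cell-type mixtures beyond the marker table,
and realistic UTR sequence composition beyond mononucleotide frequencies.
Tests passing on this generator therefore demonstrate the statistical
contracts of the methods, not robustness to every artefact of real arrays.

# Problem sizes and numerical choices

The test suite and the acceptance script run the generator at 3000–5000
genes with 3 replicates per group, 20 seeds for the end-to-end
total-vs-polysome CPE contrast, 100 random-motif controls, and 10⁴ genes
for variance-prior recovery — sizes at which the stochastic checks have
comfortable margins while a full run stays within a few minutes on one
core. Other numerical choices: trigamma inversion by Newton iteration with
the standard asymptotic start; lowess for the variance trend; `nlminb` with
analytic gradients for calibration; KS exactness switched at combined
n = 20; density bandwidths by `bw.nrd0`. Degenerate inputs (constant
arrays, all-zero variances, empty groups, missing conditions, zero axon
estimates) error or are excluded with an explicit report rather than being
patched silently.

# Known limitations

* The motif regexes are defaults from the cited motif literature, not a
  reproduction of any specific supplementary table; analyses report the
  regex used and accept overrides.
* The glog calibration's flat direction means absolute normalized values
  carry an arbitrary common shift; only differences (fold changes,
  z-scores) and relative calibration are interpretable.
* The uncoupling category definitions are a reconstruction from the 3×3
  state grid (see above).
* GO propagation is only as good as the supplied edge table; no ontology
  release is bundled.
* The exponential-decrease comparison assumes log-normal errors and a
  common error variance across groups.
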