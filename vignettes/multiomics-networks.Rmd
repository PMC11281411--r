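---
title: "Multiomics co-occurrence networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiomics co-occurrence networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`momnet` implements the statistical core of a multiomics co-occurrence
network study contrasting a patient group with healthy controls across
three gut abundance layers — virome contigs (RPKM), bacterial OTU counts
and metabolite intensities — optionally augmented with clinical
questionnaire items (a 7-item gastrointestinal symptom scale and the
20-item Zung depression and anxiety scales). This vignette records the
models, the tunable parameters, and the design decisions a maintainer
would want to know about.

## The pipeline

1. **Normalisation** — virome contigs are quantified as
   RPKM = reads / ((length/10^3) × (library/10^6)); any layer can be
   converted to relative abundance. Before network construction the
   retention filter keeps the most abundant fraction of features (top 5%
   of virome contigs, top 15% of OTUs in the emulated study), which guards
   against correlations driven by shared zeros.
2. **Diversity** — Shannon index (natural log) per sample, Bray–Curtis
   dissimilarity between samples, classical-scaling PCoA, and a PERMANOVA
   group test using Anderson's pseudo-F with seeded label permutations.
3. **Differential abundance** — per-feature two-sided Mann–Whitney tests
   (exact for tie-free groups of ≤ 8, otherwise tie-corrected normal
   approximation with continuity correction) with Benjamini–Hochberg
   adjustment, combined with a LEfSe-style LDA effect size; features pass
   at p < 0.05 and LDA score > 2.
4. **Networks** — tie-corrected Spearman correlations for every feature
   pair, p-values from the t approximation on n − 2 degrees of freedom,
   BH q-values over all pairs tested in the same call. An edge requires
   |r| > 0.8 AND p < 0.001 AND q ≤ 0.05 (all configurable). Three network
   families: within-layer (`single`), between-layer only (`cross`), and
   cross plus symptom–feature edges (`symptom`). Group-specific networks
   are built from group-subset samples.
5. **Topology** — degree, normalised betweenness, within-component
   closeness, |r|-weighted eigenvector centrality and local clustering;
   Louvain modules on |r| weights with the modularity Q; Zi–Pi node roles;
   log–log least-squares power-law fit of the degree distribution;
   module-overlap and symptom-concentration summaries; Mann–Whitney
   contrasts of node-level metrics between networks.

## The synthetic-data generator

No sequencing data are deposited for the emulated study, so the package
ships a generator that plants known structure for every downstream stage.

It is a latent Gaussian factor copula. Each of `n_modules` blocks has a
latent factor $Z_b \sim N(0,1)$ over samples. A feature assigned to block
$b$ has latent value $a Z_b + \sqrt{1-a^2}\,\varepsilon$; background
features are pure noise. Because Spearman correlation is invariant under
strictly monotone marginal transforms, the pairwise *observed* rank
correlation inside a block is controlled by the latent Pearson correlation
$a^2$ through the bivariate-normal relation
$\rho_S = \tfrac{6}{\pi}\arcsin(\rho_P/2)$; `rho_within` is specified on
the Spearman scale and converted internally, so it is a target for the
data users actually see.

Per layer the latent values are pushed through a marginal transform:
bacterial counts are negative binomial with mean $\exp(\mu_f + \sigma y)$
and dispersion $\phi$ (variance $\mu + \phi\mu^2$); virome and metabolite
layers are log-normal intensities. Defaults: latent scale $\sigma = 1.5$,
between-feature spread of baseline log-abundance 1.0, $\phi = 0.1$,
baseline log-means 2 (RPKM-like), 5 (counts), 10 (intensities). These
were calibrated once, at design time, so that the realised Spearman
correlation of block pairs tracks `rho_within` closely (count noise at
these levels attenuates it by only a few percent); they correspond to
deeply sequenced, abundant features — i.e. the post-retention-filter
feature set that networks are actually built from.

Differential features are drawn from the background set (so differential
and correlation structure stay identifiable) and receive a
`effect_log2fc` shift of the case-group mean, alternating direction.

**Zero inflation.** Zeros are injected after the marginal transform. The
default mechanism (`zero_mode = "censor"`) zeroes the lowest `zero_prob`
quantile of each feature, emulating detection-limit dropouts and creating
the zero-ties that exercise the tie-corrected Spearman path. An
independent Bernoulli mask (`zero_mode = "independent"`) is available but
not the default: masking independently of abundance zeroes high-abundance
observations, which real zeros essentially never are, and even a few
percent of such zeros sharply attenuates the rank correlations the
generator is supposed to plant (the test-suite verifies that planted
blocks retain substantially stronger observed correlations under
censoring than under independent masking at the same zero fraction).

**Symptoms.** Questionnaire items are produced by discretising
$\lambda Z_b + \sqrt{1-\lambda^2}\,\varepsilon$ at equiprobable normal
quantiles onto the item grid — 0–4 for the gastrointestinal items (the
source study does not state the grid; this is a configurable generator
convention) and 1–4 for the Zung items. Which items load on which block,
and how strongly, is configuration; loaded items are the ground truth for
symptom–omics edges. Scale scoring follows the standard conventions:
plain item sum for the GSS, `round(raw × 1.25)` for the Zung indices, and
the Zung SDS sub-scales (2 affective, 8 physiological, 10 psychological
items).

**What the generator does not emulate:** phylogenetic correlation
structure, compositional closure effects, sequencing-depth variation,
abundance-dependent dispersion, and longitudinal structure. Passing the
recovery suites therefore shows that the pipeline is correct and well
calibrated on block-structured copula data, not that it is robust to
every failure mode of real microbiome data (compositional artefacts in
particular are explicitly out of scope — no CLR/SparCC-style correction
is applied).

## Numerical and design choices

- **Spearman p-values** use the t approximation at all sample sizes. It
  is accurate by n ≈ 30 (the test-suite measures the null rate of
  p < 0.001 at n = 60 and finds it within Monte-Carlo error of nominal)
  but anticonservative at very small n — at n = 12 the realised rate of
  p < 0.001 is roughly 1.7× nominal. At the study's own sizes the
  |r| > 0.8 cut, not the p cut, is usually the binding constraint
  (for n > 13 the two-sided p < 0.001 boundary lies at |r| < 0.8), and
  the joint false-edge rate under independence is below nominal.
- **BH families** are per network-construction call, not global across
  networks, matching per-network construction practice; there is no
  explicit q cutoff in the source description of the thresholds, so the
  default q ≤ 0.05 is a third conjunctive threshold and configurable.
- **Symptom-edge thresholds** default to the network thresholds; the
  cross-omics heatmap preset (|r| > 0.6, p < 0.05) is available through
  `correlation_screen()`. Which of the two the source study used for its
  symptom network is not stated; neither is asserted.
- **Retention ranking** is by mean relative abundance pooled over all
  samples (group-agnostic); prevalence ranking is offered as an option
  because the source study does not define "top". The retained count is
  `ceiling(fraction × n)` so a positive fraction never empties the table,
  and ties at the cut break lexicographically by feature id.
- **PERMANOVA** uses the add-one permutation estimator
  p = (1 + #{F* ≥ F})/(1 + n_perm), so p = 0 is never reported; the
  permutation count defaults to 999 (unstated in the source). The
  implementation is cross-checked against `vegan::adonis2` in the tests.
- **PCoA** drops negative-eigenvalue axes rather than applying a Lingoes
  correction, and reports all eigenvalues so users can inspect them;
  two-dimensional ordinations are the only use in the emulated analyses.
- **Shannon** uses the natural log (source silent); a `base` argument is
  provided.
- **LDA effect size** is a documented two-class variant of LEfSe, not a
  clone: no subclass stage (the design has no subclasses), 30 bootstrap
  rounds on a 2/3 subsample, abundances rescaled to a fixed total of 10^6
  so scores are comparable to published LEfSe scores. On a one-dimensional
  discriminant axis the projected class-mean difference reduces to the
  feature's class-mean gap; the score is log10 of that gap floored at 1.
  Bootstrap membership is drawn in sample-name order, making scores
  invariant to column permutations at a fixed seed.
- **Centralities** are computed on the unweighted thresholded graph
  (the threshold already binarises association strength); a weighted-path
  variant sits behind a flag. Closeness uses the Wasserman–Faust
  per-component normalisation so disconnected networks yield finite
  values. Eigenvector centrality uses |r| weights (tolerance 1e-8,
  max 1000 iterations).
- **Zi–Pi roles** use the Guimerà–Amaral thresholds Zi ≥ 2.5,
  Pi ≥ 0.62; the source reports role counts but not cutoffs. A module
  with zero within-module-degree variance gives Zi = 0; degree-0 nodes
  have undefined Pi and are flagged peripheral.
- **"Top 25% of the largest modules"** is interpreted as the
  `ceiling(0.25 × n_modules)` largest modules by node count. Module
  labels are assigned by descending size with deterministic tie-breaks,
  and Louvain runs are seeded.
- **Power-law check** is a descriptive log–log least-squares fit over
  observed degrees ≥ 1 (≥ 5 distinct degrees required); the source
  asserts but does not quantify scale-freeness, so no MLE/KS machinery is
  attached to it.

## Problem sizes used in validation

The recovery suites run at 60 samples per group with 150/120/80 features
per layer, four planted blocks of 10 features per layer at
`rho_within = 0.95`, and 20 differential features per layer at a log2
fold change of 3 (differential recovery is evaluated at 20 samples per
group). Null calibration uses 2000 synthetic datasets for the PERMANOVA
type-I error and ~60k feature pairs at n = 60 for the Spearman
false-edge rate. These sizes were chosen to give stable Monte-Carlo
estimates at desk scale; the generator's *defaults* mirror the emulated
cohort (12 patients vs 8 controls), which the `analysis/` scripts use.

## Known limitations

- Cross-sectional co-occurrence networks are associational; edges are not
  interactions, and compositional effects can induce spurious negative
  correlation (uncorrected here by design).
- Spearman p-values default to the t approximation;
  `spearman_matrix(..., exact_p = TRUE)` switches to a seeded permutation
  null (add-one estimator), which is preferable at the small-n end —
  though there the |r| threshold usually binds anyway.
- Multi-class LEfSe, taxonomy cladograms, rarefaction, CLR transforms and
  the machine-learning stages of the emulated study are out of scope.
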