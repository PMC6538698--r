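---
title: "Modelling and correcting terminal-sequence bias in small RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and correcting terminal-sequence bias in small RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endbias)
```

## Why terminal bases, and why a reference pool

Small RNA library construction touches each molecule's ends twice: a
single-stranded ligase joins an adapter to one end of the cDNA, and a
template-switching reverse transcriptase initiates from a base pair between
a one-nucleotide DNA overhang and the RNA's 3′-terminal base.  Both steps
have sequence preferences — the ligase at the few bases nearest the ligation
junction, the template switch essentially at the single 3′-terminal base —
so the measured abundance of a species depends on its terminal sequence,
not only on its input amount.

An equimolar reference pool turns this from a nuisance into something
measurable.  When every species is known to be present at the same
concentration, the per-species measurement error is directly observable:

$$\Delta\log_{10}\mathrm{CPM}_m \;=\;
  \log_{10}(\mathrm{CPM}_m + pc) \;-\; \log_{10}(\mathrm{CPM}_{\exp}),
  \qquad \mathrm{CPM}_{\exp} = 10^6/n .$$

`endbias` models this error from each species' first three and last three
bases, corrects abundances by subtracting the prediction on the log scale,
and provides the surrounding profiling, evaluation, and design utilities.

## The regression model

`fit_bias_model()` regresses $\Delta\log_{10}\mathrm{CPM}$ on 24 indicator
features: positions $(+1,+2,+3,-3,-2,-1)$ × bases (A, C, G, T), one-hot
encoded by `encode_end_features()`.  The regressor is a random forest.
That choice reflects the structure of the problem: effects of terminal
bases are not additive across positions in general (the template switch
and the ligase can interact with dinucleotide context), a forest captures
such interactions without specifying them, and with 24 binary features and
hundreds of species it is essentially tuning-free.

Configuration and defaults:

| parameter | default | why |
|---|---|---|
| `ntree` | 500 | variance of impurity importances stabilises well before this |
| `mtry`  | features/3 = 8 | the classical regression-forest default |
| `seed`  | 20190528 | fixed so refits are bit-identical; any integer works |
| `pc`    | 0.5 CPM (and 0.5 counts) | half-count convention for zeros, applied inside every log |
| `min_species` | 50 | below this a 24-feature forest mostly memorises noise |

Determinism is part of the contract: `set.seed(seed)` immediately precedes
the forest construction, so the same data and seed give identical
predictions, and cross-validation derives per-fold seeds as `seed + fold`.

**In-sample versus out-of-fold.**  Correction defaults to in-sample
prediction (train on the pool, correct the pool), which is the
proof-of-concept setting for a reference pool; the CLI's `--cv-correct`
applies out-of-fold predictions instead for users worried about
self-fitting.  Model *assessment* must distinguish the two: in-sample
$R^2$ of a forest is inflated by memorisation (a forest given only
internal, causally irrelevant positions still reaches in-sample $R^2
\approx 0.5$ on our simulations, purely by fitting noise).  The package
therefore evaluates the internal-position control out of fold
(`cross_validate_bias_model()`, 8 folds), where it drops to $R^2 \approx
-0.1$ — no skill.  Out-of-fold $R^2$ on pure noise is systematically
*negative*, not zero, because the regressor's own variance adds to the
test error; a near-zero-from-below value is the expected signature of
"nothing to learn".

**Importances.**  Feature importance is the mean decrease in node impurity
(variance), summed over the four bases of each position and normalised to
1 by `positional_importance()`.  The 5′ and 3′ shares of this distribution
attribute the bias between the ligation and template-switching ends.
Impurity importances are biased toward high-cardinality features in
general; here all features are binary indicators, the setting where the
measure is unproblematic.

## Normalisation and error statistics

* `cpm_normalize()` scales columns to $10^6$; for 962 equimolar species at
  depth $10^6$ the expectation is $10^6/962 = 1039.5$ CPM per species.
* `median_normalize()` is the median-of-ratios construction: per-species
  geometric-mean pseudo-reference across samples (species with any zero
  excluded), per-sample factor = median ratio to it.  It degenerates
  correctly on proportional samples and, for a single sample, is the
  identity — so expectations can be stated in counts.
* `measurement_errors()` averages replicate columns on the log scale
  (arithmetic mean of per-replicate $\log_{10}$ CPM), matching the
  log-scale regression target.
* Reporting follows the field's mixed conventions: errors and correction in
  $\log_{10}$; `rmse_log2()` and `ecdf_points()` in $\log_2$.  Both bases
  are exposed; nothing downstream depends on the choice beyond a constant.
* `classify_representation()` flags species beyond $k$ SD of the mean
  error — $k=1$ for bias analysis, $k=2$ for the stricter outlier set used
  in sequence-factor comparisons.  The rule is invariant to additive
  shifts, hence to whether errors or raw log abundances are supplied, and
  to the log base given a consistent spread.

## PCA of end features

`pca_end_features()` restricts to the flagged (over ∪ under) species,
centres the one-hot columns, and uses the singular value decomposition
(`prcomp`).  Columns are *not* rescaled to unit variance: they share units
(indicator of a base at a position), and rescaling would inflate rare-base
positions into apparent importance.

## The simulator

`simulate_pool()` draws unique i.i.d.-uniform sequences (default $n=962$,
lengths 19–25 nt, the size and length range of a commercial equimolar
miRNA set).  `simulate_counts()` samples a multinomial of size `depth`
(default $10^6$, chosen so counts and CPM coincide) with species weights

$$p_m \propto 10^{\sum_i \mathrm{effect}(i,\, \mathrm{base}(m,i))
  \;+\; s \cdot \mathrm{len}_m},$$

i.e. biases compose multiplicatively across positions — the log-additive
structure the regression assumes.  Replicates are independent draws from
the same $p$ (technical replicates of reference pools are essentially
perfectly correlated, so no extra between-replicate dispersion is
modelled).  The recorded truth $\delta_m = \log_{10}(p_m n)$ is the exact
deviation from uniformity the model should recover.

The default effect sets used in tests place $\pm 0.3$–$0.5$ log10 effects
at $+1..+3$ (ligase-style) and $-1$ (template-switch-style), producing
uncorrected log2 RMSEs near 2 — the order observed for real end-biased
reference-pool libraries.

What the simulator deliberately does **not** emulate: PCR duplication and
amplification noise, adapter-dimer reads, multi-template switching
artifacts, cross-mapping between near-identical species, internal-sequence
(structure-mediated) effects, and concentration spread in biological
samples.  Passing tests therefore demonstrate that the estimator recovers
log-additive terminal effects from multinomial sampling — not that any
real library's bias is exactly log-additive.  For real data the terminal
three positions dominate but correlations between end positions of natural
miRNAs can alias 5′ against 3′ effects; the importance split should be
read with that caveat.

## Alignment filtering

`counts_from_alignments()` keeps primary alignments that are mapped,
unique, and whose aligned query length (soft clips excluded — the filter
targets the insert, not adapter remnants) is within 15–40 nt.  "Unique" is
not encoded uniformly across aligners, so the rule is: `NH` tag present →
`NH == 1`; otherwise `MAPQ >= 5`.  Secondary and supplementary records are
never counted: one read, one vote.

## Fold proxies

Self-fold and adapter/cDNA co-fold scores exist to ask a rank question —
do outlier species differ from the rest in structure?  For that purpose
the package uses base-pair maximisation, not thermodynamics:
`self_fold()` is the classical nested-pairing dynamic programme
(Watson–Crick + G:U, minimum hairpin loop 3), with free 5′/3′ end counts
taken from one maximal traceback that prefers pairing the outermost
compatible partner (ties elsewhere do not change the pair count, only the
traceback; the preference makes end counts deterministic).  `co_fold()`
scores the longest contiguous complementary duplex between the adapter and
the species' cDNA, optionally with the second adapter attached — the
ligation geometry in which co-folding would sequester the acceptor.  Both
are monotone stand-ins for stability: rank tests on them are robust to
monotone substitution, and a thermodynamic engine can be plugged in via
`sequence_factors(provider = ...)`.  Outputs are labelled proxies and are
not free energies.

## Overhang design and the adapter screen

`design_overhang_ratio()` implements first-order compensation: new weight
of overhang $d$ ∝ current weight × expected/recovered fraction of the
complementary RNA 3′ base, ratios clipped at 10 to keep nearly-unrecovered
classes from exploding the mix.  The empirically titrated compensating mix
(A:C:G:T = 6.6:0.4:1:1, preset `NTTR`) was found by experiment, not by
this formula; the rule is exposed as *advisory* — it is idempotent at the
fixpoint and moves the 3′ composition in the right direction, which is
what the tests verify.  `adapter_ligation_screen()` encodes only the
ligase's −3 acceptor rule (A/C favoured, G neutral, T/U disfavoured);
full ligase-bias modelling is out of scope.

## Numerical choices and degenerate inputs

* Pseudo-count 0.5 inside every log; zero-count species stay finite.
* All-zero samples are errors in `cpm_normalize()`; species with any zero
  are excluded from median-of-ratios factors; a table where no species is
  usable is an error.
* Constant error vectors train with a warning (importances meaningless);
  zero-spread classification labels everything `normal` with a warning.
* Trinucleotide reweighting clips weights to $[0.1, 10]$ and rescales to
  conserve total abundance; an unobserved trinucleotide class warns and
  takes the clip value.  The scheme is a reconstruction of the read-start
  trinucleotide reweighting approach and is retained chiefly as the
  baseline the regression corrector outperforms.
* Saturation curves subsample the empirical read multiset without
  replacement under a fixed seed; the plateau equals the number of species
  with ≥ threshold total reads by construction.
* Rank-sum tests use `wilcox.test`: exact for small tie-free groups,
  midranks with normal approximation otherwise.

## Problem sizes in the test suite

Unit tests run pools of 60–500 species so the whole suite finishes in
under a minute; the end-to-end checks (parameter recovery, correction
efficacy, conservation laws) run the full study conditions — 962 species
at depth $10^6$ — where a forest fit takes about two seconds and an
8-fold cross-validation about ten.  The convergence and length-slope
checks use depth $10^7$ on smaller pools.

## Known limitations

* Correction requires a ground-truth equimolar pool.  Applying a model
  fitted on a reference pool to biological samples needs parallel
  validation; concentration-dependent effects are not identifiable from a
  single-concentration pool.
* The model sees only terminal trinucleotides; residual length dependence
  (≈ 0.09 log10 CPM per nt in reference data, recoverable with
  `length_abundance_fit()`) and rare structure-mediated outliers are not
  corrected.
* In-sample correction partially fits sampling noise; at depth $10^6$ this
  shrinks, rather than inflates, apparent RMSE on unbiased data, so
  in-sample RMSE improvements slightly overstate out-of-sample gains.
  `--cv-correct` avoids this at the cost of two-stage prediction.
* The overhang design rule is linear in recovery ratios; real
  template-switching response to the primer mix saturates, so iterative
  application with re-measurement, not a single large step, is the
  intended use.
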