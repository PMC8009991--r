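---
title: "Functional-network markers of cathodal tDCS response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-network markers of cathodal tDCS response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdcsnet)
```

## The analysis in one paragraph

Cathodal transcranial direct current stimulation (ctDCS) is an inhibitory
neuromodulation therapy for focal epilepsy whose clinical benefit is
heterogeneous: some patients' seizure frequency drops, others' does not.
`ctdcsnet` implements a whole-brain functional-network analysis of this
problem: parcellated resting-state fMRI time series recorded before and
after a 5-day ctDCS course are turned into Fisher-z Pearson connectivity
matrices, thresholded to fixed-density weighted graphs across a density
sweep, summarised by graph-theoretical measures, compared pre versus post
within clinical groups under FDR correction, and finally used to predict
treatment response (a responder has at least a 20% reduction in 4-week
seizure count relative to baseline) with an RBF-SVM over change-rate
features. Because the patient fMRI underlying the design is not publicly
deposited, the package ships a synthetic cohort generator that reproduces
the statistical structure the analysis assumes, so every stage is testable.

## Sample preparation

Scans contribute 230 retained volumes at TR = 2 s. Each regions-by-230
series is cropped into overlapping windows of `T = 90` time points taken
every 35 points, giving five windows per scan that overlap by 55 points —
a five-fold augmentation of a small cohort (20 subjects become 100 samples
per condition). Pre- and post-stimulation windows are paired by window
index for all paired statistics and change rates; the windowing is a pure
column slice and is tested as such.

Response labelling uses exact integer arithmetic on seizure counts
(`(baseline - followup) >= 0.2 * baseline` with a numeric guard), so a
count pair like 5 → 4 — exactly 20% — counts as response. Active-arm
subjects split into responders and non-responders; sham subjects never
carry a response label.

## Network construction

Pearson correlations between all region pairs are variance-stabilised with
Fisher's r-to-z. Graphs are thresholded *proportionally*: at density `d`
the `round(d * N(N-1)/2)` largest-z edges are retained with their z values
as weights, so every sample has identical node and edge counts — at 90
regions and `d = 0.3`, exactly 1202 edges. Conventions the thresholding
needs but that are easy to get wrong are fixed and documented:

* edge counts round half away from zero (1201.5 → 1202);
* ties at the cut keep lexicographically smallest `(i, j)` pairs, making
  the edge set platform-independent;
* densities come from an integer-hundredths grid (17…46)/100, avoiding
  floating-point drift across the 30-value sweep 0.17–0.46;
* retained weights must be positive — reaching negative correlations is an
  error instructing a lower density;
* a disconnected graph is a recorded flag, not an error: efficiency is
  well defined under disconnection (unreachable pairs contribute zero)
  while path lengths go infinite and are handled downstream.

## Graph measures

All measures operate on weighted undirected graphs. Edge lengths for
shortest paths are reciprocal weights `1/w`, the standard mapping for
connectivity strengths. Per node: weighted degree `K_i = sum_j w_ij`;
Onnela clustering `C_i = e_i / (k_i (k_i - 1)/2)` where `e_i` is the sum of
geometric means of triangle weights normalised by the network maximum and
`k_i` the *binary* neighbour count; mean shortest path length `L_i`; local
efficiency `E_i` (global efficiency of the neighbour-induced subgraph).
Globally: `C_net` and `L_net` are nodal means, `E_net` is the mean inverse
distance, and small-worldness `sigma = (C_net/C_R)/(L_net/L_R)` against 100
Maslov–Sneppen rewired null networks that preserve the binary degree
sequence exactly and carry each weight with its edge (so the weight
multiset is preserved too).

Two definitional ambiguities had to be resolved. The clustering
denominator uses the binary neighbour count rather than the weighted
degree: with sub-unit weights a weighted-degree denominator is
dimensionally inconsistent and can divide by values below one, and the
binary count is the convention of the standard connectivity toolboxes this
formula comes from. Likewise, whether rewired nulls preserve weights is
usually left unstated; we rewire topology and keep the weight multiset,
which leaves `sigma = 1` for graphs the rewiring cannot alter (e.g.
complete graphs). Every measure is verified against an independent oracle
in the test suite — exhaustive triangle enumeration for clustering, igraph
all-pairs distances for paths and efficiencies — to 1e-10 on random graphs.

Stimulation-site measures map each cathode electrode (10-10 labels,
including two-electrode midpoints such as "C3-FC1") to parcellation
regions and average nodal measures over the union of mapped regions. The
default electrode-to-region map is an anatomically plausible convention —
in the clinical workflow this mapping is made per patient by clinicians —
and is user-overridable; for reduced synthetic parcellations it is
rescaled and explicitly flagged synthetic.

## Statistics across the density sweep

For each (group, measure, density) cell, paired pre/post values are
compared with a normality-gated test: Shapiro–Wilk on the paired
differences at alpha = 0.05 selects a paired t-test or a Wilcoxon
signed-rank test. Benjamini–Hochberg FDR correction is applied within each
(group, measure) family across the 30 densities — the most common reading
of correcting "over the density range"; q < 0.05 and q < 0.01 flags are
both reported.

Two practical choices: by default samples (subject × window) are the
paired units, replicating the augmented analysis, with a `unit =
"subject"` mode that averages windows first and is free of window-overlap
dependence; and pairs with non-finite values (disconnected graphs) are
dropped per cell with counts recorded, a cell with fewer than five usable
pairs yielding an NA test rather than an error. Overlapping windows
violate the independence assumptions of the paired tests; this is inherent
to the augmented design, is flagged here, and is why the subject-level
mode exists. The type-I error of the sweep machinery is verified
empirically in the acceptance suite: over 200 sham-only synthetic cohorts
with no effect, the fraction of cells significant at the 0.05 FDR level
stays below 0.08 (observed ≈ 0.03).

## Outcome prediction

The features are per-window change rates `(post - pre)/pre` of the four
measures that discriminate responders — `C_net`, `L_net`, `E_net` and
`L_local` at the stimulation sites — at density 0.3, for active-arm
samples only. Feature selection is two-step: ranking by the maximal
information coefficient (MIC) against the responder label, then sequential
forward selection keeping the smallest prefix with the best
cross-validated accuracy of a default RBF-SVM. The classifier is an
RBF-SVM tuned by nested cross-validation: five outer folds estimate
accuracy, sensitivity and specificity, five inner folds grid-search `C in
2^{-5..15}` and `gamma in 2^{-15..3}` (powers of two). Standardisation is
fitted on training folds only. Pooled outer-fold decision values give the
ROC and AUC.

MIC is computed with the published MINE approximation: grid resolution
bounded by `B(n) = max(n^0.6, 4)`, one axis equipartitioned with ties kept
together, the other optimised exactly by dynamic programming over clumps
of tied values, both orientations searched. For a binary target the
tie-respecting equipartition coincides with the class split, so the
approximation is provably exact there — which is the package's actual use
— and the tests verify equality with an exhaustive-partition oracle at
small n for binary targets, plus the inequality (approximation never
exceeds the exhaustive maximum) for continuous pairs.

Window augmentation can leak information across cross-validation splits
when windows of one subject land on both sides. The default mode is
therefore *group-aware*: folds are built over subjects, stratified by
label, and feature selection runs inside each outer training fold. A
`pooled_mode` reproduces sample-level splitting with selection on the full
data set and no class weights; it is retained for comparability and
documented as leakage-prone. Class imbalance (responders are a minority)
is handled by inverse-frequency class weights in the default mode.

## The synthetic cohort generator

The generator emulates what the analysis assumes about the data, not raw
fMRI: no volumes, motion or scanner artifacts are simulated.

* **Covariance.** Regions fall into modules (blocks) with within-module
  correlation `rho_within = 0.5` and baseline between-module correlation
  `rho_between = 0.25`. On top of the two-level structure, a small number
  of deterministic "long-range" region pairs per module pair are
  correlated at the within-module level. These shortcuts give the
  thresholded graphs genuine small-world topology and keep them connected
  across the 0.17–0.46 density sweep even at reduced region counts, where
  the mean degree `d(N-1)` is low; without them low-density graphs
  fragment into modules. If the shortcut entries cost positive
  definiteness, all off-diagonal entries are shrunk uniformly just enough
  to restore it (entry ordering, hence thresholded topology, is
  unchanged).
* **Signals.** BOLD-like series are AR(1)-coloured multivariate Gaussians:
  innovations are Cholesky draws from the target covariance, every region
  shares lag-1 autocorrelation `ar_coef = 0.4`, and the process starts in
  its stationary distribution. Because the AR coefficient is common to all
  regions the stationary zero-lag cross-correlation equals the target
  covariance analytically, while the autocorrelation supplies the temporal
  smoothness that 0.01–0.08 Hz band-limited BOLD at TR = 2 s implies. The
  tests verify convergence of sample correlations to the target within
  0.05 at 10,000 time points.
* **Responder effect.** For true responders the post-stimulation series
  are drawn from a covariance whose within-module correlations are
  multiplied by `1 - responder_effect` (default 0.4), diagonal and
  between-module entries untouched. This provably weakens the strongest
  (retained) edges, lowering clustering and efficiency and lengthening
  shortest paths — the qualitative signature the sweep statistics are
  expected to recover for the responder group only, which the acceptance
  suite confirms.
* **Seizure diaries.** Baseline counts are Poisson with mean
  `baseline_rate`; follow-up means are multiplied by
  `responder_rate_ratio` for true responders. Downstream labels always
  come from the simulated counts via the 20% rule, mirroring the
  operational clinical definition, so diary noise can flip a label
  relative to the generator's ground truth — exactly as placebo effects
  and reporting noise do clinically. The defaults (`baseline_rate = 40`
  per 4 weeks, `responder_rate_ratio = 0.2`) are chosen for testability:
  at lower, more typical seizure rates the Poisson noise flips labels so
  often that no pipeline could recover the planted effect. Real
  connectivity distributions are not characterised by any public data for
  this design, so the defaults aim at testable structure, not empirical
  realism — passing tests demonstrate correctness of the machinery, not
  properties of patient data.

All randomness is seeded: a master seed fans out deterministically
(counter-based) to per-subject, per-stage and per-null seeds, so cohorts,
measure tables and CV reports regenerate byte-identically.

## Problem sizes used by tests and the acceptance script

The published design (90 regions, 230 time points, 12 active / 8 sham
subjects, 30 densities, 100 rewired nulls) is what the defaults encode.
The test and acceptance runs exercise the identical code paths at reduced
sizes chosen as a deliberate package policy so the whole suite completes
in minutes: 20 regions in four modules of five for the signature-recovery
and prediction checks (12 active / 8 sham subjects, full 30-density
sweep), 12 regions for bookkeeping of the 720-cell sweep (with 2 rewired
nulls per graph for sigma), 8 sham subjects × 200 replicate cohorts for
the type-I check, and 20 cross-validation seeds for the above-chance
prediction check. Oracle-equivalence tests run on random graphs of up to
10 nodes, where exhaustive enumeration is exact.

## Known limitations

* The electrode-to-region map is a stand-in convention; clinical use
  requires per-patient mapping.
* Window-level paired tests inherit the dependence of overlapping
  windows; prefer `unit = "subject"` when augmentation is not needed.
* `L_net` is infinite on disconnected graphs; such pairs are dropped per
  cell and counted, which slightly biases low-density path-length
  comparisons on small parcellations.
* The generator's modular-plus-shortcuts covariance is a deliberately
  simple stand-in for real functional connectivity; effect sizes measured
  on it do not transfer to patient data.
* MIC uses the published approximation; it can fall below the true
  supremum for continuous variables at larger grid resolutions.
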