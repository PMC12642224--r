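---
title: "Models and methods behind phenomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenomod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomod)
```

phenomod quantifies four phenotyping modalities of a two-factor mouse cross
— wild-type (WT), humanized APOE4 knock-in (E4), humanized-Abeta App
knock-in (NLF), and the double knock-in (E4NLF) — and asks, for each
modality, whether the two genetic factors act additively or synergistically.
The factorial structure is encoded by two binary indicators, `e4` (present
in E4 and E4NLF) and `nlf` (present in NLF and E4NLF), so every statistic
can be decomposed into an E4 effect, an NLF effect, and their interaction.

This vignette documents the models, the tunable parameters, the synthetic
data the package tests itself against, and the numerical choices made where
the design was open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The contribution decomposition

The centerpiece is a decomposition that apportions co-expression network
dysregulation among the two factors and their combination. Per cell type,
single-cell counts are aggregated to pseudobulk sample profiles, normalized
to log2 counts per million (pseudocount 1, so zero counts map to zero),
filtered (housekeeping gene patterns `Rpl`/`Rps`/`mt-`/`Hist`; genes below
the 10th percentile of median absolute deviation; then the top 5,000 most
variable genes — variance of log2CPM is the ranking statistic after the MAD
step), and assembled into an unsigned weighted co-expression network
$a_{ij} = |\mathrm{cor}(g_i, g_j)|^\beta$ with topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
                           {\min(k_i, k_j) + 1 - a_{ij}}.$$

Modules come from average-linkage clustering of $1-\mathrm{TOM}$ with a
height-fraction cut and eigengene-based merging; each module's eigengene
(ME) is the first principal component of its gene-standardized submatrix,
one value per sample. Module membership (kME) is the Pearson correlation of
each gene with an ME, hub genes are the top 25 by |kME|, and ME polarity is
aligned so each ME correlates positively with the mean expression of its
top 50 hubs.

MEs are then WT-centered: subtract the WT group mean and divide by the WT
standard deviation (`wt_sd` mode; the `pooled_sd` mode, dividing by the
pooled within-genotype SD, is used for effect-size heatmaps and contrasts).
For each module the absolute shift of each mutant group from the WT mean,

$$d_g = \left| \overline{\mathrm{ME}}_g - \overline{\mathrm{ME}}_{WT}
\right|, \qquad g \in \{E4, NLF, E4NLF\},$$

is summed across modules into totals $T_g$, and proportions
$c_g = T_g / \sum_g T_g$ apportion the cell type's overall transcriptional
disruption. Per-module shares $d_g/\sum_g d_g$ support class-level
comparisons (neuronal vs glial modules, two-sided Wilcoxon rank-sum with
Bonferroni correction over the three components).

Two closed forms anchor the implementation. A purely additive E4-only shift
$\delta$ moves both the E4 and the E4NLF group by $\delta$, so
$d = (|\delta|, 0, |\delta|)$ and $c = (1/2, 0, 1/2)$; a pure interaction
moves only E4NLF, giving $c = (0, 0, 1)$. Both are recovered exactly (to
floating-point) by the pipeline on noiseless planted data. Note the
structural consequence: additive single-factor modules always feed the
E4NLF total as much as their own factor's, so a cell type shows a
*sub-dominant* interaction proportion only when some modules respond to the
two factors in opposite directions — which is the glial condition the
generator emulates.

## Factorial statistics

Gene-level two-way ANOVA fits `y ~ e4 * nlf` per gene via sequential sums
of squares (orthogonal under a balanced design), with eta-squared as effect
size. Per module and term, p-values are combined by Fisher's method
($X^2 = -2\sum\ln p$, $\chi^2_{2k}$), with Benjamini-Hochberg control
across modules within each term. ME contrasts versus WT use ordinary
per-module linear-model t-tests with BH correction across all
module-by-contrast tests; no empirical-Bayes moderation is applied, since
each module contributes a single response with ~28 samples and moderation
across modules would share variance between unrelated eigengenes.

## Behavior: motif and transition statistics

Motif sequences (one label per video frame from unsupervised pose
segmentation) yield per-animal usage vectors (frame fractions, rows sum
to 1), a dissimilarity of $1 - r$ against the WT mean profile for
average-linkage clustering, and transition matrices. Self-transitions are
excluded at the count stage — remaining in a motif is trivial — and the
remaining counts are row-normalized, so rows with at least one off-diagonal
transition are stochastic; rows with none are carried as missing, never as
zero probability mass. Community-level matrices average motif-level values
over all motif pairs of a community pair, unweighted, counting observed
zeros as zeros and excluding only missing rows. Session matrices are
averaged within animal before any group statistics.

Genotype effects are `delta = genotype mean - WT mean` per cell, tested by
an animal-block permutation: group labels are shuffled across animals
(never frames or sessions), preserving group sizes, and two-sided p-values
use add-one smoothing, $p = (1 + \#\{|\Delta^{perm}| \ge |\Delta^{obs}|\})
/ (B + 1)$, so the smallest attainable p is $1/(B+1)$. The movement-state
threshold is strict (`displacement > threshold`); a displacement exactly at
the threshold is "not moving".

## Sleep EEG

Recordings are scored in 10 s epochs (configurable) from four features:
delta power (1–4 Hz), theta power (6–9 Hz) via Hann-windowed periodograms,
EMG root-mean-square, and mean movement. Staging is rule-based: Wake when
EMG or movement is high; among the rest, REM when the theta/delta ratio is
high and the previous epoch was not Wake (REM is never entered from Wake,
and never assigned to the first epoch); otherwise NREM when delta is high,
else quiet wakefulness. Thresholds default to per-recording percentiles
(EMG and movement 60th, ratio 85th, delta median). Percentile calibration
presumes the recording samples all states; a recording of continuous
wakefulness would still be split by its own percentiles, so degenerate
recordings should be staged with thresholds taken from a state-mixed
recording of the same animal (the `thresholds` argument).

Spindles are detected inside NREM by band-passing (10–14 Hz, Butterworth
order 4, zero-phase), rectifying, smoothing over 0.1 s, and thresholding at
the NREM envelope mean plus 2.5 SD. A single threshold on the envelope of a
tapered burst systematically truncates its duration, so event boundaries
are extended to mean + 1 SD (dual-threshold detection); events merge across
gaps under 0.1 s, must keep the envelope above the core threshold for at
least 0.2 s, and must last 0.5–3 s wholly within NREM. Oscillation
frequency comes from zero crossings between the first and last crossing of
the core span — exact for pure sinusoids to one crossing quantum — and
abundance is normalized to NREM minutes, not total time.

Epileptiform spikes are deflections exceeding 6 robust SD (scaled median
absolute deviation of the raw EEG) on a 1 s running-median-detrended copy
of the trace; the detrending removes slow sleep oscillations — whose
troughs would otherwise mask spikes riding them — while a 30 ms transient
passes through unchanged, and keeping the threshold on the raw-EEG scale
leaves ordinary spindles far below it. Deflections within 200 ms merge; a
full width at half maximum of 5–100 ms is required. On recordings
containing both planted spikes and spindles, rare
spindle-delta-noise coincidences can add a few percent extra detections;
spike-only recovery is exact at the default 7-robust-SD planted amplitude.

## Slice electrophysiology

fEPSP amplitude is the negative peak relative to the mean of a 5 ms
pre-stimulus baseline; the first 1 ms after the stimulus is excluded as
artifact/fiber volley. The initial slope is a least-squares fit over the
rising-phase samples whose deflection lies between 10% and 40% of the peak;
the window is located on a 3-point median-smoothed copy of the trace but
fitted on raw samples, which keeps the estimator exact on noiseless sweeps
and stable under noise. Input-output curves take the plateau as the maximum
observed response (with a warning when non-monotone) and interpolate the
intensity reaching a requested fraction of it. LTP series are normalized
sweep-wise to the mean baseline slope (baseline = 100%) with early/late
window means; the induction schedule validator enforces the theta-burst
arithmetic (5 trains x 10 bursts x 4 pulses = 200 pulses).

## What the generators emulate — and what they do not

Every stage is validated against seeded generators with known ground truth:

* **Pseudobulk** (`simulate_pseudobulk`): module genes are
  `loading x latent + noise`, with the latent mean per sample set by
  `effect_e4*e4 + effect_nlf*nlf + effect_interaction*e4*nlf`. A single
  `noise_sd` drives both the per-sample latent scatter and gene-level
  noise, so `noise_sd = 0` gives exact genotype means (the closed-form
  oracles above) and effects are in noise-SD units otherwise.
  `neuron_module_specs()` and `glia_module_specs()` fix the study
  conditions: interaction-dominated programs in neurons; purely additive
  programs in glia, partly with opposite-signed factor effects. Defaults —
  7 samples per genotype, noise 0.3, module sizes 20–30 over a 100–200 gene
  background — are desk-scale stand-ins for the study's 26–28 pseudobulk
  samples. Not emulated: count-level sampling noise, dropout, or
  compositional effects of cell-type abundance.
* **Motif sequences** (`simulate_motif_sequences`): first-order Markov
  chains per animal; empirical transition matrices converge to the
  generator (total variation < 0.05 at 10^5 frames). Real motif sequences
  have longer-range temporal structure; the permutation test does not rely
  on the Markov property, only on exchangeability of animals under the
  null.
* **EEG** (`simulate_eeg`): band-limited oscillators (delta 2 Hz, theta
  7.5 Hz, per-state amplitudes) on a 1/f noise floor with 0.25 s onset
  tapers, Hann-windowed spindle bursts (amplitude = `spindle_snr` times the
  local NREM background SD), Gaussian spike transients whose peak is
  defined against the local 1 s median baseline, state-scaled EMG noise,
  and movement only in Wake. The default hypnogram cycles
  Wake/QW/NREM/REM at fractions 0.40/0.10/0.35/0.15 with REM always
  entered from NREM, matching what the percentile staging thresholds
  assume. Event counts are deterministic (`round(rate x exposure)`);
  placement is random under the seed. Not emulated: artifacts, electrode
  drift, microarousals, or realistic spectra beyond the staged bands — so
  passing tests show the detectors' logic is correct, not that their
  default thresholds transfer to any particular recording system.
* **fEPSP** (`simulate_fepsp`): a linear rise to a negative peak with
  exponential recovery and a biphasic stimulus artifact; `noise_sd = 0`
  makes slope and amplitude estimators exact.

## Numerical and design choices

* Module detection maps `deep_split` levels 0–4 to cut fractions
  0.97–0.89 of the maximum merge height. The topological-overlap transform
  compresses between-module dissimilarities toward ~0.96–0.98, so cuts
  very close to the top of the tree cannot separate weakly coupled blocks;
  0.95 (level 1, the default) separates orthogonal planted programs while
  leaving background genes grey.
* Eigengene merging uses the *signed* ME correlation with each candidate
  ME oriented toward its module's mean profile: anti-correlated programs
  are distinct biology and must not merge, while sign-flipped halves of
  one program must.
* In an unsigned network, modules whose latent programs are strongly
  correlated or anti-correlated (e.g. several interaction-dominated
  modules) cluster together by construction; the contribution
  decomposition is invariant to this granularity, but per-module counts at
  desk scale are small, which limits the power of the neuron-vs-glia
  rank-sum comparison in the example analysis.
* The scale-free fit index for soft-threshold selection (binned log-log
  regression of the connectivity distribution) is noisy at a few hundred
  genes; known per-cell-type powers should be passed explicitly, which is
  how the pipeline is driven throughout.
* Hub ties break lexicographically by gene id; no randomized tie-breaking
  anywhere.
* Zero-variance guards: ME centering floors its divisor at machine
  epsilon and flags the module (shares survive exactly); gene-wise heatmap
  centering guards zero variance to one, following the corresponding
  convention for expression heatmaps.
* Degenerate transition rows propagate as missing through community
  averaging, animal averaging, and deltas; a permutation draw whose group
  mean is undefined for a cell counts as exceeding the observed value
  (conservative).
* The early/late LTP windows default to 0–30 and 30–60 min post
  induction; with a 40 min post period the late window is 30–40, as in the
  example analysis.
* "Percent REM bouts" is the fraction of all state bouts that are REM
  bouts (not only sleep bouts); bouts are attributed to the light phase of
  their first epoch and NREM-to-REM transitions to the phase of the REM
  epoch, so per-phase counts partition the totals exactly.
* The per-genotype usage "delta index" is implemented as the genotype
  mean usage minus the WT mean usage per motif — an interpretation, since
  no closed formula is standard.
* Pseudobulk aggregation sums counts per sample (each biological sample
  is one replicate); the grey module is excluded from both the ANOVA
  aggregation and the contribution totals.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
the sizes the package treats as its study conditions: 100 seeded
replicates of the neuron/glia contribution recovery (n = 7 per genotype,
noise 0.3); 500 null motif datasets of 10 animals x 10^4 frames with 200
permutations each for type-I calibration; one ~1 h recording carrying 100
planted spindles at SNR 3; 30 min recordings for staging; and exact
noiseless checks elsewhere. These sizes make the whole suite run in a few
minutes while keeping every statistical check at non-trivial scale.

## Known limitations

Detector thresholds (staging percentiles, spindle 2.5 SD, spike 6 robust
SD) are this package's explicit choices, validated on its generators, and
should be re-tuned against scored data before use on real recordings. The
module pipeline approximates dynamic tree cutting by a height cut plus ME
merging; granular sub-module structure that dynamic cutting would find can
land in one module here. Pseudobulk simulation is on the log scale
directly, so library-size artifacts and count overdispersion are out of
scope.
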