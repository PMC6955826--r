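---
title: "Methods: large-scale functional network connectivity with lagged distance correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: large-scale functional network connectivity with lagged distance correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fnconn` characterises the large-scale functional organisation of the
resting brain as a weighted network whose nodes are ten canonical
resting-state networks (RSNs): auditory, cerebellum, default mode (DMN),
left and right executive control, saliency, sensorimotor, and three visual
networks. The package covers the analysis chain from per-subject RSN
time-courses to between-group statistics, plus a synthetic-cohort generator
that makes the whole chain testable without access to patient recordings.
This vignette records the model, the conventions we adopted where the
underlying methods literature leaves choices open, and what the synthetic
benchmarks do and do not demonstrate.

## Connectivity model

For one subject, the data are a $T \times 10$ matrix of standardised
component time-courses sampled every `sampling_interval` seconds (the
default, 2 s, mirrors a common fMRI repetition time; the default
$T = 297$ mirrors a 300-volume acquisition with three dummy scans
discarded). The dependency between two series $x, y$ is the distance
correlation (dCor), estimated with the biased V-statistic: with
$a_{ij} = |x_i - x_j|$ double-centered to $A_{ij}$ (row, column and grand
means removed) and likewise $B_{ij}$ from $y$,

$$\mathrm{dCov}^2 = \frac{1}{n^2}\sum_{ij} A_{ij}B_{ij},\qquad
  \mathrm{dCor} = \frac{\mathrm{dCov}}{\sqrt{\mathrm{dVar}_x\,\mathrm{dVar}_y}} \in [0,1].$$

dCor is zero in the population only under independence, so it captures the
nonlinear and anti-correlated coupling that plain Pearson correlation can
miss. We use the V-statistic (rather than the unbiased U-statistic)
because it is the original estimator of the method and keeps results
reproducible bit-for-bit against the common reference implementations.

Inter-network communication is not instantaneous, so the FNC entry
$c_{ij}$ is the **lag-maximised** dCor: the maximum of
$\mathrm{dCor}(x, \mathrm{rot}(y, \tau))$ over circular shifts
$\tau \in \{-L, \dots, L\}$. Shifts wrap around (no zero-padding dialect),
which keeps every lag evaluated on the full sample and makes the surrogate
null below exact. The default window is $L = 3$ samples (6 s at a 2 s
repetition time), configurable; tied maxima resolve toward smaller $|\tau|$
and then toward the negative lag, so results are deterministic.

A computational note: rotating $y$ permutes its distance matrix
symmetrically, and double-centering commutes with that permutation, so
$\mathrm{dCor}(x, \mathrm{rot}(y, k))$ for *all* $n$ rotations is a set of
circular cross-correlations along the diagonals of the two centered
matrices. The compiled kernel evaluates the whole rotation profile with
FFTs in $O(n^2 \log n)$; the lag window and the entire surrogate null are
then read off one profile, which is what makes cohort-scale simulation
cheap.

## Edge retention

A finite-sample dCor is almost surely positive, so "connected" must be
operationalised; with roughly 4 of 9 possible edges per node retained in
healthy-control data, the upstream analyses clearly applied some retention
rule, but none is specified. We default to a **circular-rotation surrogate
test**: the null distribution of the lag-maximised statistic is rebuilt
from `n_surrogates` (default 100) random rotations of one series, with
rotation magnitude at least $L + 1$ so the surrogate window never overlaps
true alignment. Rotation preserves each series' autocorrelation — which
inflates dCor between smooth signals — while destroying cross-dependence,
so the empirical $1-\alpha$ quantile is a calibrated threshold
($\alpha = 0.05$ by default). On independent synthetic subjects the
realised retention rate sits near the nominal level (the acceptance suite
checks the band 0.02–0.10). A fixed threshold rule
(`edge_rule_fixed()`) is provided for explorations where a common absolute
cut-off across subjects is preferable.

Components flagged non-neuronal have their rows and columns set to zero
and are never retained, encoding "no interaction" rather than missingness.

## Network measures

On the retained weighted graph we compute, per node: degree and strength
(integration), the Onnela weighted clustering coefficient (segregation),

$$C_i = \frac{\sum_{j \ne h}(w_{ij} w_{ih} w_{jh})^{1/3}}{k_i (k_i - 1)},$$

with raw weights (they are already bounded by 1 as distance correlations;
renormalising by a per-subject maximum would make subjects incomparable),
and two centralities: betweenness on edge lengths $1/w$ with fractional
credit across tied geodesics, normalised by $(n-1)(n-2)/2$ over the $n$
neuronal nodes so values lie in $[0,1]$; and eigenvector centrality, the
leading eigenvector of the retained adjacency restricted to neuronal
nodes, non-negative, unit Euclidean norm. The eigenvector is obtained by
power iteration on $A + I$ — the shift separates the dominant eigenvalue
even for bipartite-like retained graphs, where plain power iteration can
oscillate — to a relative tolerance of $10^{-10}$. Degenerate cases are
defined explicitly: nodes with degree $< 2$ have clustering 0, isolated
and non-neuronal nodes score 0 on the centralities, and an entirely empty
network returns all-zero eigencentrality with a warning. Network averages
are plain means over all ten nodes, zeroed nodes included, so a
disconnected component genuinely drags the global summary down.

Both centralities are property-tested against independent oracles:
exhaustive enumeration of all simple paths for betweenness and a dense
eigendecomposition for the eigenvector, on hundreds of random graphs of up
to 8 nodes.

## Group statistics

Groups are compared with Welch's unequal-variance $t$ test, two-sided,
with Welch–Satterthwaite degrees of freedom, over the pairs HC–MCS,
HC–UWS, HC–DOC (DOC pooling the two patient groups) and MCS–UWS. Nodal
tests are Bonferroni-corrected over the family of 10 RSNs — the
$p < 0.005$ convention at $\alpha = 0.05$; pairs are reported separately
and not additionally corrected, and the single network-average test per
measure is reported at $\alpha$. The family size is configurable because
the exact family used in the source analyses is not stated; the
$p < .005$ reporting convention pins our default.
`welch_t_from_summary()` applies the same formulas to published means and
standard deviations, which is how the acceptance script re-derives the
printed test statistics for average degree (HC vs UWS) and average
clustering (HC vs MCS) from summary tables alone.

## The synthetic cohort generator

No patient data are distributed, so the generator defines the study
conditions under which the pipeline is validated. Its model is a
**latent-driver** construction rather than a full vector-autoregression:
every edge of a ground-truth coupling graph owns a band-limited
(0.01–0.1 Hz) Gaussian driver that is injected into both endpoint nodes —
into the lagged endpoint after a delay of the edge's structural lag and
after the edge nonlinearity (identity, squaring, or a monotone cubic) —
scaled by the edge weight, plus independent Gaussian node noise
(`noise_sd`, default 0.5 relative to unit-variance drivers). This gives
direct, per-edge control of exactly the three things the lagged distance
correlation is supposed to detect: coupling strength, time delay, and
nonlinearity. The pass band mirrors the conventional neuronal band of
resting fMRI (fluctuations above 0.1 Hz are treated as artifact
signatures). Columns are standardised, and delays wrap circularly,
matching the statistic's shift convention.

The default cohort reproduces the target study design: 27 healthy
controls, 24 MCS and 24 UWS subjects, 297 samples at 2 s. Disease
severity is modelled as graded degradation of a common base graph
(density 0.4, weights uniform in 0.3–0.8, structural lags up to 3
samples): each edge independently deleted with probability 0, 0.25, 0.5
for HC, MCS, UWS; surviving weights attenuated by the same fractions; node
noise inflated by 1, 1.25, 1.5. The endpoints of that grading follow the
working hypothesis that disorders of consciousness delete and weaken
between-network coupling; the MCS level is the midpoint. No effect-size
calibration against real recordings exists, so these are stated
conventions, chosen once — the benchmarks ask for the *ordering*
HC > MCS > UWS and for detectability of the HC–UWS contrast, not for
reproduction of published group means. Subject-level seeds are derived
deterministically from the master seed, group index and subject index, so
any subject is independently regenerable.

What the generator does *not* emulate: hemodynamics (no balloon/BOLD
forward model), scanner drift and physiological noise structure, spatial
dependence between component time-courses, non-stationarity, or
structural lesions. Passing benchmarks therefore demonstrate that the
estimator and statistics recover the coupling structure they assume, not
that the pipeline is robust to every pathology of real fMRI.

## RSN identification fixtures

Template matching assigns ten binary templates to independent components
by maximising the total goodness of fit — mean absolute amplitude inside
the mask minus outside, a score invariant to a component's arbitrary sign
(whether the original score used signed or absolute amplitudes is not
documented; we fix absolute) — under the constraint that no component is
claimed twice. That is a linear assignment problem; we solve it exactly
with a Hungarian solver rather than greedily, with ties broken by template
order, and property-test it against exhaustive search on small instances.
Synthetic component sets place jittered, noisy copies of the templates
among random distractor blobs on a 32×32×16 toy grid (30 components in
total by default, the usual decomposition order).

Component fingerprints are the conventional 11 features: spatial degree of
clustering, skewness, excess kurtosis and histogram entropy; temporal
one-lag autocorrelation, histogram entropy, and five band-power fractions
(0–0.008, 0.008–0.02, 0.02–0.05, 0.05–0.1, 0.1–0.25 Hz, summing to 1).
Conventions the source literature leaves open are fixed as: excess
kurtosis (normal = 0); Shannon entropy in nats over an equal-width
histogram with $\lceil\sqrt{n}\rceil$ bins; band powers from a smoothed
periodogram, as fractions of total power below 0.25 Hz; and degree of
clustering defined as the fraction of suprathreshold voxels ($|z| > 1.5$
after standardising the map) lying in the largest 6-connected cluster.
The neuronal/artifactual classifier reproduces the published contract — a
maximum-margin linear SVM on standardised fingerprints — but is trained
on labelled synthetic fingerprints, since the original training cohort is
not available. Artifact exemplars follow the three signal signatures that
motivate the features: high-frequency components (> 0.1 Hz), spike trains
(> 5 SD excursions, heavy-tailed), and sawtooth ramps (40 s period, strong
one-lag autocorrelation). The anatomical artifact rule (signal in the
superior sagittal sinus) needs an atlas and is out of scope.

## Motion quality control

Frame-wise displacement is the Power convention: summed absolute
frame-to-frame differences of the three translations plus the three
rotations converted to arc length on a 50 mm sphere; the first frame is 0.
Frames above a threshold (default 0.5 mm, configurable — no published
cut-off exists for the target analyses) are flagged but not censored,
since repair happened upstream of this package's inputs in the original
processing chain.

## Interface conventions

The package is tidyverse-shaped: metric tables and comparisons are long
tibbles (`subject`, `group`, `rsn`, `measure`, `value`), fitted objects
have `tidy()`/`glance()` methods, result types have `autoplot()`/`plot_*`
helpers, and `run_pipeline(pipeline_config(...))` chains simulation or
file input through connectivity, measures and statistics with every seed
recorded in the run report. Time-courses exchange as labelled TSV with a
YAML sidecar; volumes as NIfTI; there is no separate command-line binary —
the exported functions and `scripts/acceptance.R` are the entry points.

## Problem sizes and numerical tolerances

The validation suite uses: 100 random pairs ($n \le 50$) for oracle
equivalence of dCor at $10^{-10}$; 200 random graphs ($\le 8$ nodes) for
the centrality oracles at $10^{-8}$; 50 null subjects (297 samples) for
surrogate calibration; 20 replicates of the full 27/24/24 cohort for
deficit recovery; and 100 seeded fixtures for template matching. These
sizes were chosen so the whole suite completes in minutes on a laptop
while leaving the Monte-Carlo bounds loose enough to be stable across
seeds (binomial tolerance at each scale).

## Known limitations

* The lag window length and the exact edge-retention rule of the original
  analyses are unknown; both are configurable and our defaults are
  documented conventions, so absolute degree/strength levels are not
  comparable to published group means — only orderings and test behaviour
  are.
* dCor levels depend on series length and autocorrelation; comparisons
  are only meaningful within a cohort processed with identical settings.
* The surrogate test assumes approximate stationarity under rotation.
* Betweenness on 10-node networks is coarse (many exact zeros), which is
  why it is excluded from the ordering benchmark.
* The classifier is only as good as its synthetic training distribution;
  on real components it should be retrained on labelled fingerprints.
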