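---
title: "Methods: from roaming entropy to covariance networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from roaming entropy to covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

`roamnet` implements the analysis chain of the individuality paradigm:
genetically identical mice share one large enriched enclosure, their
movements are recorded as RFID antenna contacts over roughly three months,
and the question is whether the behavioral trajectories that emerge —
despite identical genes and a shared environment — are mirrored in brain
structure. The chain has a behavioral arm (roaming entropy, trajectory
slopes, stratification, repeatability) and an imaging arm (atlas-ROI
volumetry, structural covariance networks, network-based statistics), and
the package provides both plus seeded generators that emulate the two raw
data types with known ground truth.

# Roaming entropy

For mouse $i$ on night $t$, with $c_{ij}$ contacts at antenna $j$ out of
$k$ antennae and $p_{ij} = c_{ij} / \sum_j c_{ij}$,

$$\mathrm{RE}_{it} = -\sum_{j=1}^{k} p_{ij}\log p_{ij} \;/\; \log k .$$

The $\log k$ normalizer makes the value base-invariant and confines it to
$[0,1]$: 0 means the whole night at a single antenna, 1 means uniform use
of every antenna. Choices worth stating explicitly:

* **Counts, not dwell times.** The event log records contacts; the
  roaming distribution is the contact distribution. Dwell-time weighting
  would need inter-event intervals, which confound antenna spacing with
  behavior.
* **Dark phase only.** Mice are nocturnal; only contacts inside a clock
  window (default 18:00–06:00, configurable, may wrap midnight) are used.
  A night is one contiguous dark period indexed by its start date, so a
  02:00 contact belongs to the previous evening's night.
* **Empty nights are missing, not zero.** $\mathrm{RE}=0$ is a real
  behavior (sitting at one antenna); a night with no contacts is absence
  of data and propagates as `NA`.

Nightly values are averaged into consecutive blocks (default four blocks
of 21 nights), and each mouse's trajectory is summarized by the ordinary
least-squares slope of block means against block index $1\ldots4$, in RE
units per block.

# Stratification into flat and down roamers

Two modes are provided. The *threshold* mode applies the published
cutpoints as defaults: slopes $\le -0.006$ are "down" (habituating),
slopes in $[-0.003, 0.004]$ are "flat" (sustained exploration), slopes in
between are excluded as intermediate and slopes above the flat band are
excluded as positive. The source analyses state the lower boundary
inconsistently in two places ($-0.006$ vs $-0.008$); we default to
$-0.006$ and expose both cutpoints as arguments, so either reading is one
keyword away. The *rank* mode is the objective alternative: the
`group_size` most negative slopes are "down" and the `group_size` slopes
nearest zero among the rest are "flat", with ties broken by mouse id. The
rank mode is what the demo and recovery tests use, since it needs no
dataset-specific cutpoints. A k-means/silhouette helper
(`choose_k_clusters`) supports checking that two trajectory clusters are
the right description of the data before stratifying.

# Repeatability via block-wise variance components

Standardized nightly entropy (global mean 0, variance 1) is modeled as

$$y_{itn} = \beta_t + u_{it} + \varepsilon_{itn}, \qquad
  u_{it} \sim N(0, V_{\mathrm{ind},t}), \quad
  \varepsilon_{itn} \sim N(0, V_{\mathrm{res},t}),$$

with block $t$ a fixed effect and the mouse-by-block interaction a random
effect, giving a separate interindividual variance per block; residual
variances are also block-specific by default (a homoscedastic switch
exists). The model is deliberately fit on *nightly* values within blocks:
with a single observation per mouse and block the interaction and the
residual are not separately identifiable, so block means alone cannot
support this decomposition.

Estimation is by Gibbs sampling with conjugate updates: flat priors on the
$\beta_t$ and inverse-gamma(0.001, 0.001) priors on every variance — the
one-dimensional case of an inverse-Wishart prior, weakly informative, and
configurable. Defaults are 13,000 iterations, 3,000 burn-in, thinning 10.
Each variance chain gets a split-half Gelman–Rubin diagnostic; values
above 1.1 produce a warning and are stored in the fit. Repeatability is
computed per draw as $R_t = V_{\mathrm{ind},t}/(V_{\mathrm{ind},t} +
V_{\mathrm{res},t})$ and summarized by posterior mode (kernel density),
mean, and central 95% interval. Cross-block covariance of a mouse's random
effects is not modeled: repeatability needs only the per-block variances,
and with four blocks and tens of mice a free 4×4 covariance would be
poorly identified.

# ROI volumetry

The imaging arm starts from a subject × region volume table (mm³) with
group labels; no image processing happens in this package. Conventions:

* total brain volume is the sum of the atlas ROI volumes; relative
  volumes are percent of that total, so each subject's relative row sums
  to 100;
* left/right labels can be merged — summed for volumes, averaged when the
  merged value will be a network node;
* group differences use Welch's unequal-variance two-tailed $t$ test per
  region, Benjamini–Hochberg FDR across regions (the source states only
  "FDR at 5%"; BH is our documented reading), and the standardized mean
  difference $(\mu_{\mathrm{test}} - \mu_{\mathrm{ref}})/\sigma_{\mathrm{ref}}$
  with the *reference-group* SD as denominator — not a pooled SD;
* NBS node sets are the regions passing the FDR threshold on the
  directional contrast (enriched above standard by default);
* the voxel-wise slope regression of the source study is represented at
  ROI level by `slope_volume_correlation` (per-region Pearson correlation
  of trajectory slope with volume, FDR across regions).

# Structural covariance and matrix equality

A group's structural covariance network is the $p \times p$ Pearson
correlation matrix of (by default relative) region volumes across the
group's subjects. For display, regions are ordered once by average-linkage
hierarchical clustering on $1-r$ of a chosen group's matrix and that order
is reused everywhere, so matrices are visually comparable.

Whole-matrix equality between two groups is tested by summing squared
Fisher-z differences over the $p(p-1)/2$ distinct pairs,

$$\chi^2 = \sum_{i<j}
  \frac{(z^{(1)}_{ij} - z^{(2)}_{ij})^2}{1/(n_1-3) + 1/(n_2-3)},
  \qquad z = \operatorname{atanh}(r),$$

referred to $\chi^2_{p(p-1)/2}$. This is the package's largest judgment
call and deserves a plain statement: the classical Jennrich test for
equality of correlation matrices needs an invertible pooled correlation
matrix, which cannot exist when the region count (182) exceeds the group
sizes (tens of mice). The Fisher-z sum form keeps the same degrees of
freedom, is well defined for $p \gg n$, and reduces to a textbook
two-sample correlation comparison at $p=2$; the Jennrich variant is
retained for small-$p$ problems and refuses to run on singular pooled
matrices rather than silently regularizing. Because adjacent pairs share
subjects the summed statistic is only approximately chi-square; the null
calibration we maintain (independent regions, $p=10$, $n=50$) shows mean
statistic within 5% of the nominal df and type-I error near 0.05, while
correlated-background nulls inflate mildly (~0.09 at background
$\rho=0.2$) — so for strongly dependent data its p-values should be read
as descriptive, which is also how the source uses them.

Per-region variability is summarized by the coefficient of variation
(sample SD over mean) within each group, compared between groups by a
two-sided Mann–Whitney test: exact by enumeration of group assignments
when feasible (valid under ties), normal approximation with tie
correction otherwise.

# Network-based statistics

Edges are pairs of selected nodes; the edge statistic for a covariance
contrast $A > B$ is the two-sample Fisher-z score

$$z_{ij} = \frac{\operatorname{atanh}(r^A_{ij}) -
  \operatorname{atanh}(r^B_{ij})}{\sqrt{1/(n_A-3) + 1/(n_B-3)}} .$$

The conventional "$t$" primary threshold for covariance NBS is therefore a
normal quantile: one-sided $\alpha = 0.001$ maps to 3.09, the familiar
3.1. The three steps are: threshold the statistic matrix, take connected
components of the suprathreshold graph (component size counted in
*edges*), and compare each observed component's size to the permutation
null of the maximum component size obtained by reshuffling subject group
labels (group sizes preserved) and recomputing correlations and statistics
each time, with

$$p_{\mathrm{FWE}} = \frac{1 + \#\{\text{perm max} \ge \text{size}\}}
  {n_{\mathrm{perm}} + 1}.$$

The $+1$ convention avoids zero p-values; when the number of distinct
label assignments is at most `n_perm` the test enumerates all of them and
flags the result as exhaustive. Contrasts are one-sided (increased
covariance) by default because the hypotheses of interest are directional;
every component is reported with its own $p_{\mathrm{FWE}}$, not only the
largest. A threshold sweep utility reports largest-component size across a
threshold grid (monotone non-increasing by construction).

# Synthetic data: what it emulates and what it does not

**Tracking generator.** Each mouse performs a lazy random walk on a
connected antenna graph during each dark phase: per contact it either
re-triggers its current antenna or moves to a uniform neighbour, with move
probability $\operatorname{logit}^{-1}(\theta_0 e^{-\delta t})$ on night
$t$. $\theta_0$ sets baseline exploration breadth; $\delta = 0$ gives flat
roamers and $\delta > 0$ habituating ones, so expected nightly RE is
monotone in $\theta_0 e^{-\delta t}$. Nightly contact counts are Poisson.
Defaults mirror the study design (38 enriched + habituation split, 115
antennae, 84+ nights are all reachable by arguments; the demo uses 20 mice
/ 40 antennae / 84 nights to run in seconds). The generator does *not*
model physical cage geometry, social interaction, dwell times, or
circadian structure within the dark phase, and its contact rates are not
calibrated to any real colony — recovery tests on it show the pipeline's
statistical machinery works, not that real mice look like this.

**Volume generator.** Subject volumes are multivariate normal per group:
region means (with group shifts specified in SMD units), region SDs, and
a correlation matrix assembled from a background correlation (optionally
per group) plus a planted set of elevated-correlation edges restricted to
chosen groups. Configurations whose implied correlation matrix is not
positive semi-definite are rejected at construction with the offending
group named — a deliberately loud failure, because silently repairing an
infeasible correlation specification would hide user error; only
eigenvalues above $-10^{-8}$ (numerical noise) are floored. Negative
volume draws are truncated at a small positive floor, relevant only for
extreme configurations.

One generator subtlety matters for interpreting the demo: covariance
networks are computed on *relative* volumes, and the ratio transform
removes variance shared across all regions. A globally elevated background
correlation is therefore invisible after normalization — it acts like a
common size factor. The demo consequently plants the flat subgroup's
elevated correlatedness as block-structured cliques (five blocks of eight
regions, within-block $\rho = 0.6$ against a 0.05 background), which
survives the compositional transform the way system-structured anatomical
covariance would; demo groups are equally sized (10/10/10) so the
$1/\sqrt{n}$ upward bias of mean $|r|$ under noise cannot masquerade as a
group difference.

# Numerical and design choices

* Natural log inside the entropy; the normalizer makes the base
  irrelevant. Zero-probability terms contribute zero by convention.
* $|r| = 1$ is clamped to $0.999999$ before $\operatorname{atanh}$ with a
  warning (both in the equality test and in edge statistics).
* Hierarchical-clustering linkage is *average*; the source does not state
  a linkage, and average linkage is the common choice for correlation
  distances. `hclust` leaf order is deterministic given the input order,
  so a region ordering is reproducible.
* All simulators and samplers take explicit integer seeds and restore the
  caller's RNG state; the pipeline derives fixed per-stage sub-seeds from
  one master seed, so a config plus seed pins every output byte.
* k-means uses 25 restarts under the given seed; silhouette width is
  averaged over points.
* Stratification tie-breaks (rank mode) are by mouse id, documented and
  deterministic.

# Problem sizes used by the test suite

The suite exercises the statistical claims at deliberately chosen sizes:
NBS null calibration at 20 nodes, 15 + 15 subjects, 200 permutations, 100
replicates; planted-component recovery (a 10-edge clique at $\rho = 0.75$
vs 0.1) at 20 + 20 subjects, 25 replicates, primary threshold 2.4 — the
same threshold used for the source's network visualizations, selected for
this effect size by a pilot power sweep; variance-component recovery at 40
mice × 4 blocks × 21 nights; matrix-equality calibration at $p = 10$,
$n = 50$, 500 replicates; oracle equivalences (BH, connected components,
exact Mann–Whitney) against brute-force enumerations. The full demo
(tracking through NBS) runs from one seed in well under a minute.

# Known limitations

* The equality-test statistic's chi-square reference is approximate under
  strong inter-pair dependence (see above); exact replication of published
  chi-square magnitudes additionally depends on an unidentified test
  variant in the source and is not attempted.
* The Gibbs model assumes Gaussian nightly residuals of standardized RE;
  heavy-tailed nights (e.g. sensor dropouts) should be screened upstream.
* Group-level covariance NBS cannot produce subject-level inference; with
  one covariance matrix per group, permutation of subjects is the only
  available null, and small groups (< ~8) leave it coarse.
* The generators are statistical stand-ins, not behavioral or anatomical
  models; parameters were chosen for plausibility, not fit to the
  archived colony data.
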