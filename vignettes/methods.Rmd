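---
title: "Models and methods behind paleoniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleoniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`paleoniche` reconstructs the climatic niche of a montane endemic carnivore
through the Pleistocene and into future warming scenarios, and classifies a
fossil mandible against a comparative sample of living canids. This vignette
is the package's own account of the models it implements, the assumptions
they carry, the defaults and why they were chosen, and what the synthetic
study system can and cannot show.

## The maximum-entropy niche model

The core estimator is a presence-background maximum-entropy model. With
features $z(x)$ (transformations of the environmental layers) and a prior
$Q$ given by the background sample, the fitted relative occurrence rate is
the Gibbs distribution

$$P^*(z(x_i)) = \frac{Q(x_i)\,e^{z(x_i) I}}{\sum_i Q(x_i)\,e^{z(x_i) I}},$$

the distribution of maximum entropy subject to the constraint that feature
expectations match their presence-sample means. Fitting maximizes the
presence log-likelihood penalized by an L1 term,
$\lambda_j = r \,\max(s_j, 0.01)/\sqrt{m}$ per feature, with $r$ the
regularization multiplier, $s_j$ the feature's presence-sample standard
deviation and $m$ the number of presences.

**Optimization.** The objective is convex but non-smooth; the package uses
proximal gradient descent (FISTA with backtracking and a monotone
safeguard), which treats the L1 term exactly through soft-thresholding
rather than smoothing it. Tolerance is $10^{-6}$ on the step norm, capped
at 500 iterations; the per-iteration penalized objective is stored so the
descent property is testable.

**Features.** Linear, quadratic, product, hinge and threshold classes, all
mapped into $[0,1]$ on calibration bounds with clamping outside them. The
candidate class sets for tuning are L, LQ, LQH and H with regularization
multipliers 0.5, 1, 2 and 4; the classes actually selected are recorded in
the ensemble table (on the default synthetic data the search settles on LQ —
a peaked thermal response needs the quadratic term, and hinge knots add
little on smooth synthetic fields).

**Output scale.** The logistic (habitat suitability) output is
$c\,r/(1+c\,r)$ with $c = e^H$, $H$ the entropy of the fitted raw
distribution over the background, so a cell with a typical background score
maps to 0.5. A cloglog-style transform was considered and rejected to keep
the single canonical definition.

**Projection convention.** Raw scores sum to one over the calibration
background. When a model is projected onto another stack (a past bin, a
future scenario), the calibration partition function is kept rather than
renormalizing per stack: a cell's suitability is then a function of its own
environment alone and is comparable across time bins. Per-stack
renormalization would make any purely linear model invariant to spatially
uniform climate shifts and would dilute per-cell scores exactly when the
suitable band widens — erasing the range dynamics the hindcast is meant to
measure.

**Background convention.** Presences are appended to the background for
normalization by default (`add_presences = TRUE`), the usual convention for
a random background sample. When the background already covers the
landscape exhaustively — as in the simulation oracles, where every presence
cell is a background cell — appending would double-count them and tilt the
prior, so those analyses pass `add_presences = FALSE`.

## Ensembles of small models

Rather than one model on all variables, the pipeline fits every subset of a
fixed size — five 4-of-5 models for the hindcast (on PC scores), 28 6-of-8
models for the forecast (on VIF-filtered layers) — and averages predictions
with accuracy weights. Cross-validation uses twelve spatially separated
folds: occurrences inherit their source polygon, polygons are ordered south
to north and grouped into twelve contiguous blocks (a k-means fallback
covers point sets without polygon structure). Held-out AUC scores the
fold's presences against the full background; the background is not folded.
Member weights are Somers' D, $2(\mathrm{AUC}-0.5)$ floored at zero and
normalized — a member that cannot beat chance contributes nothing.

## Variable pre-processing

* **PCA** (hindcast): correlation-matrix PCA on the five present-day
  hindcast layers, all components kept, past stacks transformed with the
  present-day loadings. Sign convention: each loading column's
  largest-magnitude entry is positive.
* **VIF** (forecast): iterative removal of the layer with the largest
  variance inflation factor while any exceeds 3, ties broken by layer name.
* **MESS**: per-variable percentile similarity against a reference sample,
  map value the minimum across variables, negative exactly where a variable
  leaves the reference range. The reference is the variable values at the
  calibration points (presences + background), the standard practice; the
  whole present raster is available as an alternative reference via the
  function arguments. A variable is dropped when its mean out-of-range
  proportion across all time bins exceeds 20%.

## Range dynamics

Coarse-grid suitability maps are binarized with the **minimum useful
threshold**: scanning 0.01 to 1 in steps of 0.01, the MUT is the *largest*
threshold at which every time bin keeps at least one in-range cell. The
wording of the selection rule could also be read as the smallest such
threshold, but that reading is trivially 0.01; the implemented direction is
the one that serves the stated purpose — being as restrictive as possible
while never producing an empty range. Binarization uses $\ge$, so a cell
exactly at the threshold is in range.

Within the range, cells split into good-to-best (HSI > 0.5) and
good-to-worst (HSI $\le$ 0.5); a bin with a GB majority is flagged as
expansion. Each bin's in-range HSI sample is compared with the present's by
a two-sample rank-sum test (exact for small tie-free samples, normal
approximation with tie correction otherwise): "better" is the one-sided
greater test at $\alpha = 0.05$, "similar" the non-significant two-sided
test.

The variance of the per-bin mean HSI is compared between bins younger and
older than the glacial-cycle switch with the **Brown-Forsythe test** — a
one-way ANOVA on absolute deviations from group medians, implemented
directly from that definition and cross-checked against `aov()` on the
transformed values.

Trend regressions of log10 range area on mean temperature and on log10 mean
altitude guard against autocorrelated residuals: an OLS fit is checked with
a Ljung-Box test at lag $\min(10, n/5)$; if autocorrelation is present,
regression-with-ARIMA-errors candidates are generated two ways — AR order
estimated from the OLS residuals by maximum likelihood with $d \in \{0,1\}$
and MA order 0–6, plus an automatic AIC grid over $(p, d, q)$ with
$p, q \le 3$ — and the minimum-AIC candidate is reported. The automatic
search is a grid over `stats::arima` fits; slope inference uses the
asymptotic normal approximation.

## Landscape fragmentation

Suitability maps are cut into four classes at 0.25, 0.5 and 0.75 (class 4
closed above, so HSI = 1 is class 4). Patches are rook-connected components
(queen connectivity is a switch). Metrics follow the FRAGSTATS
definitions, with the exact formulas in the function documentation: np,
mean patch area in cell units, the aggregation index from single-count like
adjacencies against the maximally compact arrangement, clumpiness from the
double-count adjacency proportion against the class's landscape share,
cohesion from patch perimeters and areas, and division as the probability
that two random landscape locations fall in different patches.

Scenario comparisons use a two-way PerMANOVA (Euclidean distances,
sequential sums of squares in the order emulator, period) with permutations
restricted within emission-scenario strata, 9999 permutations by default,
and a pairwise follow-up for significant terms; `vegan::adonis2` provides
the permutation machinery. The worst class is excluded — it blankets the
landscape and would mask between-scenario differences — as is the division
metric, which is constant in this design. The log10 transform is applied to
the strictly positive metrics; clumpiness, which is signed, stays on its
natural scale. The class-on-metrics regression uses an ordinal
(proportional-odds) logit by default — the class response is ordered — with
a multinomial fallback on separation failures.

## Morphometrics

The comparative analysis uses the nineteen dentognathic measurements. The
PCA operates on log10 measurements (covariance matrix — the variables share
units after the log transform) over the extant specimens; the fossil is
projected passively. The discriminant analysis between the three jackals
and the Ethiopian wolf selects variables forward by the Wilks' lambda
criterion with an F-to-enter of 3.84 and reports Fisher's two-group
function with the midpoint constant, Bartlett's chi-square for the final
lambda, and leave-one-out reclassification via `MASS::lda`. The function is
applied to raw millimetre measurements by default — the magnitudes of the
published coefficients imply mm-scale inputs — with a log option in the
arguments. The published function itself ships as `phi_published` so a
specimen can be scored without refitting.

Bootstrap cluster analysis builds a UPGMA reference dendrogram on Euclidean
distances between taxon mean scores, then resamples specimens with
replacement within taxa, reclusters, and records node support (the share of
replicates preserving each node's taxon set) and the G similarity between
reference and replicate partitions at each level. G is implemented as the
pairwise co-membership agreement (Rand form), which has the stated 0–1
bounds; the null reference G° comes from matched replicates with specimen
labels permuted across taxa. The sharpness rule is applied exactly as
published — a level is sharp when $P(G^\circ \le G^*) > \alpha$ — even
though the direction reads unusually for a significance rule; both the
support percentages and the G-based decisions are reported so either
convention can be inspected.

## The synthetic study system

The generator supplies every input the pipeline needs, with the statistical
structure the analysis assumes:

* **Geometry.** An abstract equal-area grid (areas are cell counts times
  the squared cell size; no projection math). The default fine grid is
  180 x 180 cells aggregated by 4 for the coarse stacks.
* **Relief.** Three conical peaks on a north–south line. Conical slopes
  matter: the area of an altitude band grows downslope, as on a real
  massif, so a cooling that moves the suitable thermal band downhill
  expands its area. A ridge or a flat-topped dome lacks this hypsometry and
  cannot carry warm-small/cold-big range dynamics.
* **Species.** Twelve range polygons on an alpine band at 0.8 of the
  relief. Placing the species just below the summits gives it an interior
  thermal optimum (colder ground exists above, warmer below); a species on
  the absolute summits would have a boundary optimum, the fitted response
  would be monotone, and a spatially uniform climate shift would leave the
  (normalized) prediction unchanged.
* **Climate.** Layers are built from altitude (temperature with a 6.5
  deg C/km lapse rate, precipitation increasing with elevation, NPP from
  both) plus smooth Gaussian random fields — separable kernel smoothing of
  white noise, bandwidth 6 cells — for spatial autocorrelation. The past
  series oscillates between interglacial (present-like) and glacial states:
  ~41-ka cycles with 1.5 deg C amplitude older than 1 Ma, ~100-ka cycles
  with 4 deg C amplitude younger, at a default of 200 bins x 10 ka (a
  desk-scale stand-in for 2000 x 1 ka; both knobs are configuration).
  Glacial drying and productivity loss are deliberately mild (5 mm and 10
  NPP units per deg C) so the thermal axis dominates the niche shift, as
  for a thermal specialist. Future stacks add warming offsets monotone in
  emulator sensitivity, scenario severity and period.
* **Morphometrics.** Per-species multivariate normal draws at the
  comparative sample sizes (simensis 20, aureus 19, adusta 21, mesomelas
  21, latrans 21, lupus 22, pictus 19, alpinus 21), 5% coefficient of
  variation, with hypercarnivores scaled larger and more robust so the two
  guilds separate on PC1, and the wolf displaced from the jackals along the
  six variables of the published discriminant function.

**What passing tests show — and what they do not.** The synthetic fields
are smooth, stationary and free of the observation artifacts of real
rasters (coastlines, missing swaths, projection distortion, correlated
measurement error); occurrences are exactly one per cell by construction
rather than thinned GPS records. Green tests therefore demonstrate that the
algorithms are implemented correctly and that the pipeline recovers
structure it is known to contain — not that the ecological conclusions
would survive contact with any particular real dataset.

## Problem sizes and numerical choices

The default run — 200 presences, 10,000 background points, five small
models tuned over a reduced grid (L and LQ at multipliers 1 and 2) on
twelve folds, 200 projected bins — completes in about a minute on one CPU;
`tune_grid()` restores the full search. Simulation-based checks use 10,000
replicates for the Brown-Forsythe type-I error, 2000 observations for slope
recovery, and 1000 bootstrap replicates for BCA. Degenerate inputs are
handled explicitly: constant layers are guarded in the PCA scaling,
all-tied samples return p = 1 in the rank-sum comparison, zero within-group
spread makes the Brown-Forsythe statistic an error rather than a 0/0, and a
threshold grid that empties any bin names the offending bin. Ties in the
VIF filter and the greedy polygon placement are broken deterministically
(name order, altitude order), and every stochastic function takes an
explicit seed.
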