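---
title: "Quantifying primitive-streak cell dynamics with streakdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying primitive-streak cell dynamics with streakdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streakdyn)
```

## Scope and coordinate conventions

`streakdyn` implements the quantitative procedures used to establish the
existence, dynamics and maintenance of bipotent neuromesodermal progenitors
(NMPs) in the epiblast of the gastrulating amniote embryo, together with
synthetic-data generators that reproduce the statistical structure of each
input with known ground truth.

All spatial modules share one embryo coordinate frame: `x` is mediolateral in
micrometres with the midline (the primitive streak axis) at `x = 0`, and `y`
is anteroposterior, increasing posteriorly, with Hensen's node at the
anterior end. Motion toward `x = 0` from either side is *convergence* and is
reported with a positive lateral-to-medial speed `v_LM`; posterior motion has
positive `v_AP`. This convention makes "angle with the midline" unambiguous:
`atan(|v_LM| / |v_AP|)` is 0° for streak-parallel motion and 90° for pure
convergence. Because only the angle magnitude is biologically reported,
convergence and divergence fold together, and the statistic is invariant
under reflection of the embryo across its midline.

## Track kinematics

Tracks are plain tables of time-ordered positions with a final status
(`live`, `ingressed`, `divided`, `lost`). The analysis chain is:

1. **Node registration** (`register_to_node`): the node's contemporaneous
   position (linearly interpolated inside its observed span; extrapolation is
   refused) is subtracted from every sample, so all speeds are relative to
   the regressing node. Registration is exactly invertible, which the test
   suite checks to 1e-9 µm.
2. **Velocities** (`track_velocities`): discrete displacements between
   consecutive samples. Each velocity attaches to the *midpoint* time and
   position of its sample pair — a central convention chosen so that binned
   profiles are not systematically shifted by half a frame.
3. **Angles** (`angle_fraction_report`): the per-track mean angle is computed
   first and tracks are then binned into [0°, 45°) and [45°, 90°]. Averaging
   per track avoids overweighting long tracks; a `pooled = TRUE` switch bins
   individual steps instead. The 45° boundary goes to the upper (convergent)
   bin; the tie is a documented convention, as real data never lands on it
   exactly.
4. **Speed profiles** (`speed_profile`): mean, SD and n of `v_LM` and `v_AP`
   in AP-position × time bins. Defaults are 50 µm and 30 min; they are
   configurable because published profiles do not pin the bin geometry. Empty
   bins are flagged as missing, never imputed as zero, and single-sample bins
   report an undefined SD.
5. **Longevity** (`track_longevity`): for a cohort of tracks present in a
   region at `t0`, the fraction still uncensored 1 h and 2 h later. By
   default a division does not end a lineage — the lineage survives if any
   daughter survives — because a division is not an exit from the epiblast;
   `lineage = FALSE` reverts to raw track persistence. Ratios are
   non-increasing in the horizon by construction.
6. **Ingression intensity** (`ingression_intensity`): mean pixel intensity in
   bands along the streak axis of a ventral-view time series, with an
   ordinary-least-squares line per timepoint. The slope sign reads out the
   anteroposterior gradient of ingression. Timepoints with fewer than three
   populated bins, or with no intensity variation, are flagged rather than
   fitted.
7. **Inter-division times** (`interdivision_times`): lifetimes of tracks
   whose birth and division are both observed. Censored lifetimes are
   excluded and counted. Note one statistical subtlety probed by the test
   suite: in a growing population observed over a fixed window, the cells
   born most recently are disproportionately censored, so the mean of
   *complete* lifetimes is biased below the true cycle time unless the
   analysis restricts to cohorts born early relative to the window.

## Clone calling

Two labeling chemistries are supported.

**Barcodes.** Clones are identity groups of an exact 24-mer barcode string;
rows whose barcode contains non-ACGT characters (ambiguous base calls) are
excluded and logged. No edit-distance merging is attempted — retroviral
libraries are designed to be far apart, and the simulator never emits
colliding barcodes.

**Color codes.** Nuclear intensities in three channels are normalized to
percentages of their sum (`normalize_colors`), clustered by k-means on the
fraction triple (`cluster_colors`), scored with silhouettes, and filtered at
silhouette > 0.4 (`silhouette_filter`, strict inequality). Choices worth
recording:

* Clustering operates on normalized fractions, not raw intensities, because
  the color code is a ratio: total brightness varies with depth and
  expression level but the channel proportions are clonal.
* The number of clones is rarely known; `k = "auto"` sweeps `k_range`
  (default 2–15) and keeps the k with the highest mean silhouette — the same
  statistic already used as the per-cell quality filter. An explicit `k`
  overrides the sweep. K-means uses 25 restarts under a fixed seed so results
  are reproducible.
* Silhouettes are computed on the 3-channel fractions. The fractions lie on
  a 2-simplex, and the planar ternary embedding rescales all pairwise
  distances by exactly √2, so silhouette ratios — and therefore the filter —
  are identical in either representation.
* Ternary-plot coordinates (`triplot_coordinates`) use the standard
  equilateral-triangle map (pure channels at the vertices, equal mix at the
  centroid) and are exactly invertible.

Potency classification (`classify_clones`) is purely compositional: a clone
is `N` if all members are neural, `M` if all mesodermal, `NM` (bipotent) as
soon as both tissues are present. Anterior/posterior composition is counted
against a caller-supplied axial boundary; in real embryos this is the
somite-27 landmark separating primary from secondary neurulation, and the
image Y coordinate (ascending = posterior) is used as the axial proxy.
Calibration of that proxy to somite number is the caller's responsibility.

**A geometric limit of the silhouette filter.** The filter is meant to drop
cells whose color code cannot be attributed to a clone. Its power depends on
where the clone hues sit: a cell is kept only if its distance to the nearest
cluster is well under half its distance to the second-nearest (silhouette
> 0.4 requires roughly a 1:1.7 ratio). When ambiguous cells are uniform over
the whole color simplex and five clone centres are spread across it, about
half of the uniform draws land close enough to some centre to be kept —
they are genuinely indistinguishable from clone members on color alone. The
acceptance checks measure this discard fraction (~0.4–0.55 across seeds)
rather than assuming the filter removes nearly all ambiguous cells; with
clone hues confined to a small region of the simplex the discard rate rises
accordingly.

## The geometric-series population model

The anterior-streak progenitor pool self-renews while shedding a fraction of
daughters into the mesoderm at each division. With ingression fraction
`f` per division, each mother leaves `q = 2(1 − f)` daughters in the pool,
so after `n` divisions

\[ U_n = q^n \, U_0 . \]

With the measured anterior ingression fraction `f = 0.35`, `q = 1.3`; from
`U_0 = 50` cells, `U_9 ≈ 530` and `U_10 ≈ 689`, so reaching 550 cells takes
9–10 divisions (`divisions_to_reach` reports the bracketing pair rather than
choosing). Spread over a 40-hour expansion this implies a cell-cycle time of
about 4 h (`cycle_time`). Integer projections round half away from zero,
which reproduces the printed 530/689 from 530.22/689.29.

Two inverse/stochastic companions make the model testable:

* `fit_growth` recovers `q` (hence `f = 1 − q/2`) by ordinary least squares
  of log counts on the division index `time / assumed_cycle_time`, with a
  case-resampling bootstrap CI. A noiseless geometric series is recovered
  exactly; counts with 10% lognormal observation noise recover `f` to within
  ±0.05.
* `stochastic_growth_sim` is the branching-process counterpart: every cell
  divides, every daughter independently ingresses with probability `f`
  (ingression applied post-division, matching the construction of `q`). Its
  per-generation expectation equals the deterministic projection, which the
  suite verifies by Monte-Carlo within 2 standard errors over 500 replicates.

## Image quantification

Counting double-positive (SOX2+/T+) nuclei follows the classical
threshold–AND–particle pipeline: each channel is thresholded at the top 1.3%
of its intensity histogram (`percentile_threshold`; the fraction is a
parameter because the original setting was manual), the binary masks are
intersected, and 8-connected components with area strictly below 500 px² are
counted (`double_positive_count`). Connectivity is 8-neighbour, the common
particle-analysis default; there is no lower area bound by default, but a
`min_area` parameter is available for noisy data. A constant image has no
upper tail and yields an empty, flagged mask. Because the threshold is a
percentile, all counts are invariant under any monotone rescaling of either
channel — the suite checks this with affine, `asinh` and power transforms.

`mitotic_index` applies the same scheme to a mitosis marker (pH3) and a
nuclear counterstain (Hoechst) inside a square ROI (conventionally
250 × 250 µm) and reports `100 · n_pH3 / n_Hoechst`; an empty counterstain is
flagged undefined rather than divided through. `dual_threshold_mitosis`
handles single-channel live imaging, where condensed mitotic chromatin is
much brighter than interphase nuclei: a more selective high percentile
isolates mitoses, a permissive low percentile counts all nuclei.

Inputs are expected to be 2D maximum-intensity projections; 3D segmentation
and watershed splitting of touching nuclei are out of scope.

## Dynamic genes along a pseudotime ordering

Given a cells × genes matrix whose rows follow a supplied total ordering
(pseudotime is an input, not computed here), `dynamic_gene_test` scans all
stride-1 sliding windows of 100 cells per gene, takes the windows with the
highest and lowest mean expression (`extreme_windows`, ties to the earliest
start), and runs a two-sample t-test between those two sets of 100
measurements, Benjamini–Hochberg adjusted across genes at FDR < 0.01. Welch's
unequal-variance form is the default (`var_equal = TRUE` reverts to the
pooled test). Genes with zero variance in both windows get p = 1 and a flag.
Significant genes are z-scaled, smoothed with a centered 100-cell moving
average whose window shrinks at the edges (no padding — padding would bias
peak ranks at the boundaries), and ranked by the position of their smoothed
maximum for heat-map display (`smooth_and_rank`).

**The selection-inflation caveat.** The two tested windows are chosen as the
extremes of the same data that is then tested, so the raw p-values are
anti-conservative even for genes with no trend whatsoever: on pure-noise
simulations (1000 cells, window 100) the median null p-value is on the order
of 1e-3 and, with every gene drawn from that same inflated distribution, the
BH step-up flags the large majority of null genes at nominal FDR 0.01 (the
acceptance script measures this fraction; it is ~0.8, not 0.01). The
procedure is reported as defined — it is a ranking and visualization device
with high power (≥ 0.95 for 5-SD ramps at these sizes) rather than a
calibrated error-controlled test — and its realized null rate is measured and
reported, not assumed. Analyses that need calibrated significance should use
an independent split of cells for window selection and testing.

Reversing the cell order mirrors the window positions but leaves every
t-statistic, p-value and significance call unchanged; the suite checks this
symmetry.

## What the generators emulate — and what they do not

* **Tracks** (`simulate_tracks`): per-frame advection (AP drift following
  the regressing node, AP-position-dependent convergence clamped at the
  midline) plus Gaussian positional noise, per-frame ingression hazards, and
  divisions that end the mother track and spawn two linked daughters.
  Defaults: 4-min frames, node regression 1 µm/min, convergence rising
  posteriorly to 2 µm/min over a 2000-µm streak, ingression hazard rising
  posteriorly from 0.2% to 2% per frame, a uniform division rate of 0.22/h
  (≈ 4.5-h cycle), and 0.5 µm positional noise — values chosen to mirror the
  measured regimes (anterior: node-following, little convergence, rare
  ingression; posterior: strong convergence, frequent ingression). The
  magnitude of positional noise in real tracks is unreported, so it is a
  free parameter. The generator is phenomenological: there are no cell–cell
  forces, no chemorepulsion, no epithelial packing, so passing recovery
  tests demonstrates the *estimators*, not tissue mechanics.
* **Colors** (`simulate_clone_colors`): Gaussian channel noise is applied to
  raw intensities *before* normalization — as acquisition noise enters in
  reality — rather than drawing from a Dirichlet on the simplex. Default hue
  centres are three channel-dominant corners plus two edge midpoints
  (minimum pairwise simplex distance 0.49).
* **Barcodes** (`simulate_barcodes`): distinct random 24-mers, one per
  clone; collisions are redrawn so exact-match grouping is exact by
  construction.
* **Images** (`simulate_two_channel_image`): Gaussian nuclear blobs at
  centres with pairwise separation ≥ 4σ (+2 px placement margin), truncated
  at a 4σ radius so separated blobs never overlap; double positives share a
  centre across channels; centres snap to pixel positions so noise-free
  maxima equal the nominal intensity. Real confocal data have touching
  nuclei, uneven illumination and depth attenuation, none of which are
  simulated — counting accuracy on these images is an oracle check of the
  pipeline, not a claim about segmentation of hard images.
* **Expression** (`simulate_expression`): dynamic genes follow ramp, sigmoid
  or pulse trends with amplitude `effect_size` in noise-SD units on top of
  i.i.d. Gaussian noise; null genes are pure noise; genes are independent.
  Real single-cell data are counts with gene–gene correlation and
  mean–variance coupling, so measured power and null rates transfer only
  qualitatively.

Every generator is bitwise reproducible for a fixed seed, and every ground
truth object is sufficient to score its downstream stage (clone ARI,
survival and slope recovery, count accuracy, detection confusion) without
re-deriving labels.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run, by choice, at: 2000 tracks
for gradient recovery (weighted least squares over 50-µm AP bins, bins with
n ≥ 20), 500 tracks for survival against the binomial oracle (3-SE band),
300 + 100 cells for clone calling and the contamination experiment, 500
bootstrap/replicate draws for the growth model, 1000 cells × 250–500 genes
for the window statistic, and 256 × 256 px images. These sizes put the
Monte-Carlo error comfortably inside each check's tolerance while keeping
the whole suite in the minutes range.

Other numerical conventions: quantiles use R's default linear interpolation
(type 7); k-means uses `stats::kmeans` with 25 restarts and `iter.max` 100;
silhouettes come from `cluster::silhouette`; BH adjustment from
`stats::p.adjust`; ARI scoring from `mclust::adjustedRandIndex`; integer
projection rounds half away from zero; window ties resolve to the earliest
start; and degenerate inputs (constant images, identical colors, constant
expression) are flagged explicitly rather than silently propagated.

## Known limitations

* Nucleus detection/linking is out of scope: tracks are inputs, produced
  upstream by dedicated trackers.
* The dynamic-gene statistic is anti-conservative by construction (above);
  treat its gene lists as ranked candidates.
* The silhouette filter cannot reject ambiguous cells that happen to sit on
  a clone's hue (above).
* Pseudotime, batch correction, transport maps and cross-species
  classification are external stages; `streakdyn` consumes their outputs.
* The population model is unstructured (no division-age or spatial
  structure); `divisions_to_reach` requires a growing pool (`q > 1`).
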