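# streakdyn

Quantitative analysis of cell dynamics and clonal lineage tracing in the
gastrulating amniote embryo.

During primitive-streak regression, a small pool of bipotent progenitors —
neuromesodermal progenitors (NMPs), marked by co-expression of SOX2 and
T/Brachyury — sits in the anterior streak epiblast and feeds both the neural
tube and the paraxial mesoderm while maintaining itself. Establishing that
this pool exists and persists requires several independent quantitative
arguments, and `streakdyn` packages all of them for R users working with
imaging-derived data:

* **Track kinematics** — node-registered velocities of epiblast nuclei,
  angles with the midline, anteroposterior profiles of convergence speed
  (`v_LM`) and drift (`v_AP`), track longevity by region,
  ingression-intensity gradients along the streak, and inter-division times.
* **Clone calling** — clones from exact retroviral barcode matches, or from
  Brainbow-type nuclear color codes via intensity normalization, k-means
  clustering with a silhouette (> 0.4) quality filter and ternary-plot
  coordinates; clones are classified as neural (N), mesodermal (M) or
  bipotent (NM) and split anterior/posterior of an axial landmark.
* **Population model** — the geometric series
  `U_n = q^n · U_0` with `q = 2(1 − f_ingress)`: forward projection,
  bracketing division counts to reach a target size, implied cell-cycle
  time, least-squares parameter recovery from noisy counts, and a
  branching-process simulator whose mean reproduces the deterministic model.
* **Image quantification** — counting SOX2/T double-positive nuclei by
  upper-percentile (default 1.3%) thresholding, mask intersection and
  8-connected particle analysis (area < 500 px²); mitotic indices from
  pH3/Hoechst pairs in 250 µm ROIs or from dual-threshold live imaging.
* **Dynamic genes** — the sliding-window statistic along a supplied
  pseudotime ordering: extreme 100-cell windows per gene, Welch t-test,
  Benjamini–Hochberg FDR, and peak-ranked smoothed heat-map matrices.
* **Synthetic data** — generators for tracks, color codes, barcodes,
  two-channel nuclear images and pseudotime expression matrices, each with
  ground truth sufficient to score the corresponding analysis stage.

## Worked example

The arithmetic at the heart of the self-renewal argument: in the anterior
streak, 35% of tracked cells ingress within a few hours, so each division
leaves `q = 2 × 0.65 = 1.3` daughters in the epiblast pool. Starting from 50
SOX2/T cells:

```r
library(streakdyn)

m <- population_model(U0 = 50, f_ingress = 0.35)
m
#> Geometric-series population model
#>   U0 = 50 cells, f_ingress = 0.35, q = 2(1 - f) = 1.3

project_population(m, 9:10)
#>    n    cells cells_rounded
#> 1  9 530.2250           530
#> 2 10 689.2925           689

divisions_to_reach(m, 550)
#>  n_low n_high
#>      9     10

cycle_time(40, 10)
#> [1] 4
```

Reaching the observed ~550 cells takes 9–10 divisions (the pool passes 550
between `U_9 = 530` and `U_10 = 689`), and spreading those divisions over the
~40 h expansion window implies a cell cycle of about 4 h — matching the
cycle times measured directly on dividing epiblast cells.

Clone calling on simulated Nucbow color codes with known ground truth:

```r
cp <- clone_gen_params(n_clones = 5, cells_per_clone = 60,
                       hue_noise_sd = 0.03, seed = 1)
cells <- cluster_colors(normalize_colors(simulate_clone_colors(cp)),
                        k = "auto", k_range = 2:10, seed = 1)
attr(cells, "k")                                    # 5 clusters selected
score_clone_calls(cells$cluster_id, cells$clone_id) # adjusted Rand index: 1

calls <- classify_clones(silhouette_filter(cells)$kept, ap_boundary = 500)
attr(calls, "potency_table")
#>  N  M NM
#>  0  0  5
```

The silhouette sweep selects the generating clone number, every cell is
assigned to its true clone (ARI = 1), and all five clones — simulated as
bipotent — are called NM with their anterior/posterior cell counts.

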