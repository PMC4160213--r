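# wallfibril3d

Quantitative analysis of fibril networks in electron tomograms of plant
cell walls.

Growing plant cells are wrapped in a primary wall whose load-bearing
elements — cellulose microfibrils a few nanometres thick — run in stacked
lamellae, nearly parallel to one another, joined by short bridge-like
cross-links of matrix polysaccharides. Electron tomography reconstructs
this architecture in three dimensions, and its quality and biology are
summarized by a handful of geometric quantities: the microfibril diameter
*d*, the edge-to-edge gap *g<sub>e</sub>* and center-to-center distance
*g<sub>c</sub> = g<sub>e</sub> + (d<sub>i</sub> + d<sub>j</sub>)/2* between
neighboring fibrils in a lamella, and the surface-to-surface cross-link
length ℓ. Sample-preparation protocols and genotypes are compared with
notched boxplots: the notch `median ± 1.57·IQR/√n` approximates a 95%
confidence interval for the median, and two groups are called
significantly different exactly when their notches do not overlap.

The package is written for microscopists and cell-wall researchers who
want those numbers from reconstructed volumes without interactive tracing.
It provides:

* **Phantom generation** (`make_preset()`, `generate_wall_phantom()`,
  `apply_imaging_model()`) — layered fibril networks with known geometry,
  parameterized by published measurements of chemically fixed (`chem`),
  high-pressure-frozen (`hpf`), frozen-hydrated (`cryo`), wild-type and
  mutant (`wt_hypocotyl`, `cob6`) walls, plus an extraction control
  (`extracted`); corrupted by point-spread blur, the missing wedge or
  pyramid of tomographic acquisition, and noise.
* **Filtering** — nonlinear anisotropic diffusion (`nad_filter()`),
  structure-tensor orientation fields (`compute_structure_tensor()`),
  orientation-guided smoothing (`orientation_smooth()`).
* **Segmentation** — normalization, threshold and hysteresis segmentation,
  contour-spectrum isovalue selection
  (`normalize_density()`, `threshold_segment()`, `hysteresis_segment()`,
  `contour_spectrum()`, `select_isovalue()`, `clean_components()`).
* **Skeleton analysis** — topology-preserving 3D thinning (`thin3d()`),
  skeleton graphs (`build_skeleton_graph()`, `prune_spurs()`), and
  classification into fibrils and cross-links (`classify_segments()`).
* **Metrology** — cross-sectional plane sampling and the four measurements
  (`analyze_roi()` and the `measure_*()` functions), with
  intensity-profile estimators deblurred through an exact
  Gaussian-blurred-disk model.
* **Statistics** — notched-boxplot summaries and group comparison
  (`boxplot_stats()`, `notch_overlap_test()`, `threshold_sensitivity()`),
  with a base-graphics `plot()` method for the comparison figures.
* **I/O** — MRC (modes 0/1/2) and multi-page TIFF volumes
  (`read_volume()`, `write_volume()`, `bin_volume()`), CSV measurement
  tables, JSON provenance, YAML run configs, and a thin command-line
  driver (`inst/exec/wallfibril3d`) with `phantom`, `run`, `sweep`,
  `compare` and `recover` subcommands.

## A worked example

Generate a frozen-hydrated-style phantom at the study's voxel size
(0.87 nm), corrupt it with the cryo imaging model (SNR 3, 1 nm PSF, ±60°
single-axis wedge), and run the measurement pipeline:

```r
library(wallfibril3d)

spec <- make_preset("cryo", shape_voxels = c(160L, 160L, 48L), seed = 12)
ph   <- generate_wall_phantom(spec)           # volume + ground truth
vol  <- apply_imaging_model(ph$volume, spec)  # PSF, wedge, noise, polarity

m <- analyze_roi(vol, analysis_roi(group = "cryo", seed = 12),
                 wall_config(polarity = "dense_dark"))
summary(m)
#>            type  n   mean_nm    sd_nm   min_nm    max_nm
#> 1      diameter 60  5.493387 1.011433 4.073369  7.962436
#> 2   center_dist 34 12.141287 1.943215 9.572471 17.244839
#> 3      edge_gap 34  6.545160 1.432360 4.303327 11.948270
#> 4 crosslink_len  5  5.968863 1.013157 4.915497  7.136554

summarize_values(m$value_nm[m$type == "diameter"])$report
#> [1] "5.5±1.0 nm (range 4.1–8.0 nm, n = 60)"
```

The generating truth for this phantom was a mean diameter of 4.93 nm, a
mean within-lamella edge gap of 6.27 nm and a mean cross-link length of
5.00 nm — the pipeline recovers the diameter and spacing to well within a
voxel on this single region of interest; cross-links are detected
conservatively (see the vignette's limitations section). Group comparison
mirrors the notched-boxplot rule:

```r
cmp <- notch_overlap_test(rnorm(60, 5.2, 2.0), rnorm(60, 8.9, 3.8),
                          labels = c("WT", "mutant"))
cmp
#> <wall_comparison> WT vs mutant: medians 5.46 vs 9.03 -> significant
plot(cmp, ylab = "edge gap (nm)")
```

The methods vignette (`vignettes/wall-fibril-metrology.Rmd`) documents the
generator, the filters, every estimator and its calibration, the design
decisions, and the known limitations.

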