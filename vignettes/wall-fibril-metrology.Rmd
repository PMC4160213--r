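---
title: "Quantifying fibril networks in cell-wall electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibril networks in cell-wall electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wallfibril3d)
```

## The measurement problem

Plant primary cell walls are built from long, near-parallel cellulose
microfibrils (roughly 3–9 nm in diameter) arranged in stacked lamellae and
joined by short bridge-like cross-links (roughly 2–13 nm long) attributed
to hemicellulose or pectin. Electron tomography resolves this architecture
in three dimensions, and four geometric quantities summarize it:

* the cross-sectional **diameter** *d* of individual microfibrils,
* the **edge-to-edge gap** *g~e~* between neighboring microfibrils in a
  lamella,
* the corresponding **center-to-center distance**
  *g~c~ = g~e~ + (d~i~ + d~j~)/2*, and
* the surface-to-surface **cross-link length** ℓ.

Groups (sample-preparation protocols, wild type vs mutant) are compared
with notched boxplots: the notch `median ± 1.57·IQR/√n` approximates a 95%
confidence interval for the median, and two groups are called significantly
different exactly when their notches are disjoint.

Because no tomograms of this kind are publicly deposited, the package pairs
the analysis pipeline with a synthetic phantom generator whose parameters
are the published measurements themselves. Every stage can then be tested
by parameter recovery: generate a network with known geometry, corrupt it
with a realistic imaging model, run the pipeline, and compare the recovered
means with the generating truth.

## The phantom generator

`phantom_spec()` / `make_preset()` / `generate_wall_phantom()` build a
layered fibril network:

* Fibrils are soft-edged cylinders (density ramps from 1 to 0 over one
  voxel) along the y axis, laid out in lamellae stacked along the beam (z)
  axis. Per-fibril diameters, within-lamella surface gaps and lamella
  spacings are truncated-normal draws; diameters are floored at 2.2 nm and
  gaps at 2.0 nm, just below the smallest printed measurements.
* Per-fibril orientation jitter (default 2.5°, 4° for the disorganized
  mutant and 6° for chemically prepared material, whose fibril orientations
  are visibly less consistent) makes the local gap between neighbors vary
  along the axis, as in real walls. A clearance rule keeps the local
  surface gap above 3.2 nm — matrix polysaccharides keep microfibrils
  spaced, and closer approaches would be unresolvable at the imaging
  resolution anyway.
* Cross-links are short cylinders (3.0 nm diameter) joining two
  within-lamella neighbors at an axial position where the local gap admits
  the drawn surface-to-surface length (the drawn length must lie between
  the local gap and the gap divided by cos 50°, realized by tilting the
  bridge axially). This placement keeps the recorded truth lengths at the
  preset moments: printed cross-link lengths are *shorter* than the mean
  edge gap, so bridges must sit where neighbors locally approach.
* Lamella spacing defaults to `1.6·d + 3 nm`, wide enough that the
  beam-axis elongation of the missing wedge does not fuse adjacent
  lamellae.
* The ground truth records every fibril axis and radius, every cross-link
  with its attachment points (on the host surfaces to within a quarter
  voxel), and a neighbor-pair table obeying
  `center = edge + r_i + r_j` exactly.

The imaging model (`apply_imaging_model()`) applies, in order: stain
artifact blobs (stained mode), an isotropic Gaussian PSF (default σ = 1 nm),
the unsampled Fourier region of the acquisition, and white Gaussian noise.
Resin-embedded (stained) presets use a dual-axis scheme — a missing
*pyramid* — matching how such samples are acquired; frozen-hydrated (cryo)
sections allow only a single tilt series — a missing *wedge* — with the
tilt axis at 45° azimuth to the fibril direction (an aligned or
perpendicular tilt axis is a degenerate worst case that annihilates either
the fibril cross-sections or the bridges outright). Noise is scaled so that
the *delivered* volume has the requested SNR: its standard deviation is the
realized feature contrast (99.9th percentile minus median after blur and
wedge) divided by `snr`. Cryo volumes are finally negated, since dense
material is dark in unstained cryo data.

What the phantoms do **not** emulate: membranes and organelles, section
compression and knife marks, fibril bundling and branching, diameter
variation along a single fibril, and reconstruction-specific artifacts
beyond the ideal missing wedge. Recovery results therefore demonstrate the
pipeline's behavior under controlled geometry and idealized corruption, not
performance on arbitrary real tomograms.

## Filtering

`nad_filter()` implements nonlinear anisotropic diffusion in divergence
form with explicit time stepping (`∂u/∂t = div(D∇u)`, time step 0.1,
10 iterations by default; stability requires ≤ 0.15) and zero-flux
boundaries, so the intensity sum is conserved exactly. The diffusion tensor
comes from the structure tensor of the evolving image (gradient scale
1 voxel, integration scale 3 voxels). The default mode is the hybrid
edge-enhancing / coherence-enhancing scheme used for tomograms of
filamentous specimens: where the planar coherence `λ2 − λ3` dominates the
gradient contrast — as it does everywhere on a tube, whose two transverse
eigenvalues are both large — diffusion runs along the filament direction
(v3) only. Pure edge-enhancing diffusion is also available, but it diffuses
freely along v2, which for a tube is a *transverse* direction, and visibly
erodes thin bridges. The edge-stopping function is the exponent-8 form
`g(c; K) = 1 − exp(−3.315/(c/K)^8)` with `c = sqrt(λ1 − λ3)`; `K` defaults
to a robust background-noise scale estimated from the volume itself (bulk
median absolute deviation), so structure above the noise is edge-protected
without hand tuning.

A light isotropic Gaussian prefilter (σ = 1 voxel, `prefilter_sigma`)
precedes the diffusion in the pipeline: white voxel noise at the study's
SNR is far cheaper to suppress isotropically first, and the diffusion then
operates at a contrast where its edge protection is meaningful.

`compute_structure_tensor()` exposes the tensor field itself; its minor
eigenvector tracks filament axes (median alignment above 0.95 on noiseless
phantoms), and `orientation_smooth()` averages anisotropically along that
direction — the automated route's replacement for operator-guided
smoothing.

## Segmentation

Volumes are standardized (`normalize_density()`: zero mean, unit SD, dense
features positive regardless of stain polarity), so all thresholds are in
SD units and invariant to affine intensity rescaling.

The pipeline selects its working isovalue with the contour spectrum
(`contour_spectrum()` + `select_isovalue()`): isovalues are sampled between
the 1st and 99th intensity percentiles and the one maximizing the mean
gradient magnitude on the isosurface is chosen — intensity changes fastest
at the background/feature interface, so the gradient-weighted criterion
lands there without operator input. The spectrum's selection criterion is
not uniquely fixed by common usage; the gradient-weighted maximum is this
package's documented choice.

Detection then uses two-level hysteresis (`hysteresis_segment()`): weak
components (above `iso − 1.2` background SD) are kept only if they contain
a voxel above the isovalue. This mirrors what an operator does by eye —
faint stretches are kept when they continue a clearly visible feature —
and repairs fibrils whose cores dip below a single global threshold,
without admitting isolated noise blobs. Components smaller than 27 voxels
(a 3-voxel cube, below any real fibril cross-section) are removed
(`clean_components()`).

The simple global threshold route (`threshold_segment()`) remains available
and is what the sensitivity sweep perturbs conceptually; the sensitivity
offset δ moves the *measurement* surfaces (below) while detection is held
fixed, so sweeps quantify how measured sizes respond to the operator's
threshold choice.

## Skeletonization and classification

`thin3d()` reduces the segmentation to a one-voxel curve skeleton by
sequential deletion of simple points (26/6 digital topology) from the six
directional borders in a fixed order, re-testing simplicity at each
deletion, so connected components and loops are preserved exactly — the
suite verifies this against an independent Euler-characteristic oracle.
`build_skeleton_graph()` turns the skeleton into nodes (degree ≠ 2 voxels)
and polyline edges; `prune_spurs()` removes short terminal twigs
(default < 6 nm), protecting each component's longest edge.

`classify_segments()` then separates:

* **Fibrils** — maximal chains of edges aligned within 45° of the dominant
  network orientation, at least 20 nm long. Two artifacts of the missing
  wedge are suppressed at object level: *duplicate strands* (thinning can
  leave two parallel centerlines inside one beam-elongated cross-section;
  a shorter chain tracking an accepted one inside an ellipse 4.5 nm
  in-plane × 6.5 nm along the beam is dropped) and *ghost replicas*
  (wedge ringing copies a bright fibril to dim parallel strands further
  along the beam axis; a chain dimmer than the isovalue running near a
  twice-brighter accepted chain within 6 nm in-plane × 14 nm axially is
  dropped, while dim but isolated chains are kept).
* **Cross-links** — connected residual components whose shortest path
  joins junctions on exactly two distinct fibrils, with center-to-center
  chord at most 15 nm, both attachment junctions in the same lamella
  (height difference ≤ 6 nm; apparent vertical bridges between lamellae
  are elongation artifacts), both anchored in real fibril material
  (local radius ≥ 0.7 nm), and a surface-to-surface length of at least
  1.8 nm (excluding direct contacts). The printed cross-link range
  (≈ 2–13 nm) sits comfortably inside these gates.
* everything else is counted as unclassified.

Lamella assignment splits the sorted fibril center heights at jumps larger
than 4 nm. Fibril radius profiles come from the Euclidean distance
transform of the segmentation, corrected by the half-voxel the transform
measures beyond the surface.

## Metrology

Cross-sectional planes are lattice slices orthogonal to the dominant
orientation's principal axis (fibrils lie in-plane in section tomograms,
so these are the planes an operator inspects), with positions drawn
uniformly over the central 80% of the ROI; two planes per ROI by default.
Crossings whose tangent lies within 20° of the plane are skipped — an
oblique section inflates the apparent diameter by 1/cos of the angle, about
6% at the cutoff.

Measurements read the *density*, not the binary mask:

* **Diameter** is the full width of the intensity profile along the
  in-plane direction perpendicular to the fibril, at the level halfway
  between the local peak and the local background (the profile's own
  flanking minima — the missing wedge depresses the surround of bright
  features below the global mode, so a global reference would bias the
  widths). The width is then corrected through the exact model of a disk
  observed under isotropic Gaussian blur: the scale-invariant observable
  `FWHM · slope / peak` determines `r/σ` without knowing the blur, and the
  model inverts the measured width to the true diameter. On rasterized
  cylinder oracles (radii 1.5–5 voxels, blur 0–1.5 voxels) this estimator
  is unbiased to well under half a voxel except below the resolution limit
  (`r < σ`), where no estimator can do better. A distance-transform
  read-out at the skeleton voxel — the obvious alternative — is biased low
  by the skeleton's sub-voxel lattice offset and was rejected on the same
  oracles.
* **Spacing**: within each plane, crossings are ordered along the lamella
  and consecutive crossings (height difference ≤ 5 nm) are paired —
  pairing each crossing with its neighbor on *each* side avoids the
  downward selection bias of keeping only the nearer one. Pairs whose
  center distance exceeds 1.8× the plane's median (or 45 nm) are rejected
  as spans across a missed fibril, as are pairs whose connecting profile
  shows an intervening density peak. The edge gap is measured along the
  center line between the two local half-maximum surfaces, with the same
  blur-drift correction per side.
* **Cross-link length** uses the same profile estimator between the two
  attachment centerlines; when the bridge is as dense as its fibrils and
  the profile carries no surface information (sharp synthetic fixtures),
  the geometric chord minus the two anchor radii is used instead.
* The sensitivity offset δ (SD units) shifts every measured surface by its
  first-order response `δ/slope`, exactly as re-picking the threshold
  would; diameters are therefore monotone non-increasing in δ by
  construction, small offsets (|δ| ≤ 0.05) move means by well under half
  a voxel, and the large offsets (±0.15) reproduce the ~1 nm shifts such
  re-thresholding produces on real data.

`analyze_roi()` chains all stages deterministically (one seed drives plane
sampling; the generator's seed drives the phantom), records per-stage
counts and the resolved threshold in a provenance attribute, and
propagates stage names in error messages.

## Statistics

`boxplot_stats()` uses linear interpolation between order statistics at
positions `1 + (n−1)p` (the mainstream numerics default — a convention had
to be fixed and is verified against a brute-force oracle), whiskers at the
extreme data within 1.5·IQR, and the notch formula above.
`notch_overlap_test()` declares significance by notch disjointness only —
no additional hypothesis test is layered on, by design fidelity to the
inference rule the boxplots encode. `threshold_sensitivity()` re-runs the
analysis across a δ grid and reports per-offset means and shifts.

## Problem sizes and reproducibility

The bundled tests and the acceptance script run the full recovery at
256×256×64 voxels per preset (three ROIs along the fibril axis, pooling
well over 60 measurements per preset), the two-group comparison and
extraction control at 144³/128³-scale volumes over 20 seeds each, and the
sensitivity and route-equivalence checks at similar sizes — the sizes at
which the suite characterizes the pipeline. All stochastic stages take
explicit seeds; rerunning any stage with the same seed is bit-identical.

## Known limitations

* **Cross-link detection operates at the physical detection limit.** A
  3-nm bridge, after the PSF, the missing wedge (which also removes the
  lamella-periodic mean density, lowering everything within a lamella
  plane), and noise at the study's SNR, retains a per-voxel contrast
  comparable to the residual background fluctuation. Bridge-like
  structures are recovered and their length scale is plausible, but
  one-to-one correspondence with individual true bridges is not achieved
  at low SNR, and recovered cross-link counts are conservative (the
  validation gates favor precision — an extraction-control phantom yields
  zero cross-links — over recall). Diameters and spacings, carried by much
  larger coherent structures, recover accurately under the same
  conditions.
* The pair identity `g_c = g_e + (d_i + d_j)/2` holds to about a voxel in
  the median but individual pairs can deviate by 2–3 voxels when wedge
  elongation distorts a cross-section anisotropically (the diameter is
  measured along the in-plane width, the gap along the center line).
* Per-volume mean diameters carry a geometry-dependent systematic wobble
  of roughly ±0.3 nm: the missing wedge's negative lobes depend on how
  that volume's lamellae happen to lie, and shift the local background
  reference. Comparisons between conditions should pool several volumes
  per group, as is standard practice, to average this out.
* Lamella assignment assumes walls roughly parallel to the section plane;
  strongly tilted walls would need a preliminary rotation.
* The generator's fibrils are straight (up to orientation jitter) and span
  the full ROI; real microfibrils undulate and terminate, which mainly
  adds variance the recovery tests do not see.
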