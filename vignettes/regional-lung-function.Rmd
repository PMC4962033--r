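---
title: "Regional pulmonary function testing from 4D lung imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional pulmonary function testing from 4D lung imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lungflow4d)
```

## The measurement problem

Spirometry and forced-oscillation testing summarise the whole lung in a
single number, so patchy disease — regions of high airway resistance or
frank mucus obstruction surrounded by normally or even super-normally
ventilating tissue — is invisible until it is widespread. Time-resolved 3D
imaging of the breathing lung contains far more information: lung tissue
moves as air enters and leaves it, and the local motion field is a direct
mechanical signature of regional ventilation. `lungflow4d` turns a 4D image
series (here, 16 reconstructed volumes per respiratory cycle of a
pressure-controlled ventilated subject at 12/2 cmH₂O and 133 breaths per
minute: a 0.45 s cycle, 0.15 s inspiration, 0.30 s expiration) into
time-resolved airflow in every segment of the airway tree and per-region
function measures.

The processing chain is:

1. **Volumetric velocimetry** — windowed 3D cross-correlation between
   successive frames yields a displacement field of the lung tissue.
2. **Expansion mapping** — the determinant of the local deformation
   gradient converts displacement into fractional volume change, the
   surrogate for regional ventilation.
3. **Airway tree** — the airway lumen is segmented by flood fill from a
   tracheal seed at the peak-expiration frame and skeletonized into a
   rooted tree; *endpoints* are segments with a parent and no daughters.
4. **Tissue linking** — every masked grid point is assigned to its nearest
   endpoint; summing expansion over a region gives the regional volume
   change per frame interval, hence the airflow through the supplying
   airway; continuity (parent flow = sum of daughter flows) propagates
   airflow up to the trachea.
5. **Function metrics** — per endpoint: tidal volume (TV), peak expiratory
   flow (PEF), and the expiratory time constant τ_exp, the time after
   expiration onset at which the expelled volume reaches 1 − 1/e (≈ 63.2%)
   of tidal volume. For a region emptying exponentially with time constant
   τ = RC this estimator returns exactly τ.
6. **Cohort analyses** — a polynomial reference of normalized PEF
   (PEF/TV) against normalized TV (TV/V_ee) fitted to pooled healthy
   endpoints with a pointwise 99% prediction band; the Lung Disease Index
   (LDI), the percentage of total lung volume supplied by endpoints below
   the lower band limit; per-subject τ_exp distribution statistics; and
   k-means phenotype clustering (k = 4) in the (median τ, sd τ) plane with
   angles measured from the population-mean point P.

## The synthetic phantom and what it emulates

No public 4D data sets accompany this class of experiment, so the package
ships a first-class phantom whose every stage has closed-form ground
truth. A subject is a set of single-compartment regions, one per terminal
airway: volume obeys dV/dt = (P_aw(t) − V/C)/R with a square-wave airway
pressure between PIP and PEEP. The periodic steady state is solved in
closed form (piecewise exponentials matched over one cycle); a fine-step
numerical integration is used as an independent oracle in the tests. Time
constants are drawn from configurable normal distributions — healthy
subjects homogeneous (mean 0.12 s, sd 0.022 s), diseased subjects a
two-mode mixture (0.13/0.038 and 0.22/0.037 s) — and full obstructions
(zero flow) emulate mucus plugging.

The image model: a band-limited speckle texture fills the block; each
region is a spherical *core* that dilates uniformly so that its volume
change equals the region's ODE volume change, continued outside the core
by the volume-preserving radial map ρ³ = r³ + (s³−1)r₁³. All of a region's
volume change is therefore carried by its core, the displacement field is
continuous (as in real parenchyma), and both the displacement and the
Jacobian of the warp are analytic. The airway lumen is rasterized into the
texture at a distinct low intensity and warped with the tissue. Every
frame — including the reference — is sampled from a 2× supersampled master
texture through the same trilinear interpolation, so all frames share one
effective point-spread function, as reconstructed CT frames do; rendering
the reference directly from the raw texture would give it an artificially
sharper response and bias motion estimates of the first frame pair by tens
of percent.

Phantom defaults define the study conditions: 16 compartments in a 128³
grid at 15.3 μm voxels, cores of radius 13 voxels packed by a seeded
max-min repulsion so that cores stay disjoint at peak inflation, and a
regional tidal fraction of ≈ 5% (compliance 0.0075 μL/cmH₂O per μL of
resting volume, log-normal jitter sd 0.15 so normalized tidal volume
varies between endpoints). The tidal fraction is set by the core-packing
geometry: 16 disjoint cores with peak-inflation linear scale below 1.3
must fit the grid with margins. Real mice ventilated at 12/2 cmH₂O
breathe considerably deeper relative to FRC; the phantom is a scaled-down
validation object, not an anatomical claim — tissue regions are balls,
airway walls have no thickness, and there is no image noise,
reconstruction artifact or cardiac motion. Passing tests demonstrate that
the *measurement chain* is correct and well-calibrated on ideal data, not
that it is robust to every artifact of real acquisitions.

## Velocimetry choices

Interrogation regions default to 64³ voxels with 16-voxel centre spacing,
the standard setting for this class of lung data. The correlation
estimator is zero-normalized circular cross-correlation by FFT, followed
by a *discrete window offset* second pass: the second window is re-read at
the integer displacement and re-correlated, so at the true shift both
windows hold identical content and the correlation map is exactly
symmetric about its peak. This makes integer-shift recovery exact and
removes window-truncation bias; it is not a window-deformation multi-pass
scheme. Sub-voxel refinement is a separable three-point Gaussian fit
(exact for Gaussian correlation peaks), with a parabolic fallback (flagged)
when a log is undefined. Outliers are treated by the normalized-median
test over the 26-neighbourhood (threshold 2, noise floor 0.1 voxel) and
replaced by the neighbour median.

Two defaults differ from what one might first guess:

* **Speckle correlation length 1.5 voxels.** With very smooth speckle
  (correlation length ≈ 4) the correlation peak is so flat that the
  three-point fit amplifies tiny window asymmetries about sixfold and
  sub-voxel errors exceed 0.2 voxels; a 1.5-voxel correlation length
  keeps hundreds of independent speckle cells in even a 16³ window while
  keeping the peak sharp.
* **Hann apodization for small windows.** Uniform weighting is the
  default, matching common practice at 64³; the phantom pipeline preset
  (window 16, spacing 8) enables Hann weighting, which suppresses the
  residual truncation bias that dominates at small windows.

## Expansion and flow linking

Expansion is det(I + ∇u) − 1 with ∇u estimated by central differences on
the window grid (one-sided at mask borders, flagged when no stencil
exists); the small-strain divergence is available as an option but the
determinant is exact for the phantom's uniform core dilations. Regional
volume change is the sum of expansion over a region's grid points times
the grid-cell volume, rescaled by the region's reference volume over its
assigned cell volume; grid points with missing expansion contribute zero,
which is also the truth away from the cores since the radial tails are
volume-preserving. Flow at each interval midpoint is ΔV/Δt with
inspiration positive; air compressibility is neglected (tissue volume
change equals air volume moved), and continuity then fixes every internal
segment's waveform as the sum of its daughters'. Tissue is assigned to the
endpoint with the nearest distal node (Euclidean distance, ties to the
smaller endpoint id); a geodesic-in-mask assignment would respect lobar
boundaries better but is not identifiable on the phantom, where the
nearest-tip rule is exact by construction.

## Airway segmentation

The lumen is segmented by 26-connected flood fill within an intensity
window from a tracheal seed, on the peak-expiration (minimum-content)
frame. Skeletonization is a geodesic centreline extraction: Dijkstra
costs over the mask's voxel graph are penalized away from the
distance-transform ridge so paths run along tube centres; the farthest
uncovered voxel is traced back to the existing skeleton, the branch
added, and voxels within twice the local radius (+3) of the branch marked
covered, until the mask is covered. Chains are split into segments at
junctions and leaf segments shorter than `prune_factor` (default 2) times
the local radius at their attachment (+2 voxels) are pruned. Radius is the
chessboard distance-transform value. The endpoint set is therefore a
resolution-dependent property of the image — the same lung segmented at
coarser resolution yields fewer, larger endpoints — which is why all
cohort metrics are volume-weighted or normalized per endpoint.

## Numerical and statistical choices

* τ_exp threshold: the exact 1 − 1/e rather than a rounded 63%, so the
  estimator is unbiased for exponentials; the threshold is a parameter.
* Expiration onset is the volume-waveform maximum, not the nominal valve
  time, tolerating phase lag in diseased regions; non-emptying regions are
  censored at t_exp = 0.3 s and flagged.
* The τ_exp estimator is downward-biased when a region does not finish
  emptying within the expiration window, because the measured tidal volume
  then under-represents the full excursion: a region with true RC = 0.22 s
  measures ≈ 0.14 s under this protocol. Rank order is preserved (the
  map is monotone), which is what the phenotype analyses rely on; the
  drawn time-constant population, not the biased estimates, is the
  reference for distribution-recovery checks.
* The 99% band of the healthy reference is a *pointwise prediction
  interval* (t-quantile), not a confidence band for the mean response: it
  classifies individual endpoints, and a mean-response band would flag
  half of all healthy endpoints at large n.
* Within the single-R, single-C compartment family the normalized PEF has
  a hard floor near 1/t_exp as τ grows, and τ-only disease moves endpoints
  *along* the healthy curve rather than below it. The phantom therefore
  realizes "functioning below healthy" through obstruction: fully blocked
  (zero-flow) endpoints, which the LDI counts as below-bound — a blocked
  region is maximally dysfunctional. Real lungs also produce sub-band PEF
  through expiratory flow limitation, which a linear one-compartment model
  cannot; this is a stated limitation, not an omission.
* k-means uses `stats::kmeans` with 20 seeded restarts (k = 4 by default);
  angles from point P are computed on raw (s, s) axes without
  standardization. Group comparisons are unpaired two-tailed t-tests
  (pooled variance by default, Welch optional) with no multiple-comparison
  correction, reported as raw p-values against the conventional 0.05.

## Problem sizes

The shipped analyses run at: study phantom 128³ × 16 frames with 16
compartments (velocimetry window 16, spacing 8 — 3375 vectors per frame
pair); pipeline demonstration 64³ with 8 compartments; cohorts of 7
healthy plus diseased subjects at 230 endpoints each (about 1600 pooled
healthy endpoints for the reference fit). These sizes keep every check
closed-loop against analytic ground truth while exercising the same code
paths a full-resolution study would use.

## Known limitations

Single-pass velocimetry (no window deformation) limits accuracy where the
displacement varies strongly within one window; the phantom's gentle
tidal fraction keeps per-interval core strains near 20%, at the edge of
this regime. The skeletonizer assumes a tree (it cannot represent
anastomoses) and its endpoint granularity follows image resolution. The
compartment model has no gas compressibility, no airway resistance
coupling between regions (no interdependence or pendelluft), and no
cardiac or chest-wall motion. The LDI depends on the healthy reference
cohort; it is a relative, volume-weighted index, not an absolute measure
of disease burden.
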