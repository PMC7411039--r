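---
title: "Models and methods behind xenotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xenotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

xenotrack simulates and quantifies the dissemination of human tumor cells
injected into the circulation of 2-dpf zebrafish embryos, as observed in
long-term light-sheet time-lapse recordings: roughly 150-200 cells per
embryo, imaged for about 30 h at one frame per 10 min, in a maximum-intensity
projection whose axes are anterior-posterior (x) and dorsal-ventral (y).
This vignette explains the models, their assumptions, the tunable
parameters, and what the shipped defaults do and do not establish.

## The embryo atlas

`build_atlas()` draws a deliberately stylized 2D embryo: a dorsal aorta
(DA) and a cardinal/caudal vein (CV) joined by semicircular caps at the
head (heart / duct of Cuvier) and the tail tip, so that the vasculature
forms a closed loop through which advected material recirculates; a dorsal
longitudinal anastomotic vessel fed by jittered intersegmental vessels; a
widened caudal hematopoietic tissue (CHT) plexus on the posterior vein;
avascular fin folds below the CHT and at the caudal fin; and the yolk.
The default canvas is 400 x 1500 px at 2 µm/px (a ~0.8 x 3 mm embryo);
the recordings behind the study give the magnification but not a pixel
size, so this calibration is a package convention exposed in the
configuration.

Blood flow is a per-pixel velocity field: 300 µm/s along the axial
vessels, linearly tapered in the intersegmental vessels, 30% speed in the
CHT plexus, and a tangential field with a weak centering component in the
caps (the centering keeps forward-Euler streamlines inside the lumen; no
hemodynamics are intended). Head/trunk/tail regions are cut at fixed
fractions 0.25 and 0.55 of the body length. The source recordings never
state where these cuts were drawn for regional counting; the fractions are
a declared convention of this package, not a reconstruction.

Coordinates are 0-based and pixel-centered; a point is assigned to the
pixel obtained by rounding half-down. Frames are 1-based.

## Cell kinematics: effective displacements per sampling interval

Blood in the axial vessels moves at hundreds of µm/s, so over one 10-min
sampling interval a fully entrained cell would complete many circuits of
the vascular loop — individual intervals of true advection are not
resolvable at this frame rate, and the tracked displacements in such
recordings are far smaller than literal transport. The simulator therefore
models *effective per-interval displacements*:

* **Redistribution.** One frame after injection, each cell jumps to a
  random vessel pixel (CHT pixels weighted by `cht_weight`), standing in
  for the fast dissemination through the circulation during the first
  sampling interval. This jump is intentionally far beyond the tracking
  gate: the automated linker starts tracks only after cells settle, which
  mirrors how tracking of such recordings effectively begins once cells
  slow down. With flow off (silent-heart morphants) or zero
  `advection_coupling`, no redistribution happens.
* **Drift.** Each interval, an intravascular cell is displaced by
  `advection_coupling x flow(x, y) x frame_interval`, integrated in two
  vessel-confined substeps. `advection_coupling` is therefore the small
  fraction of the local flow displacement retained as net drift per
  interval — an effective parameter, calibrated, not a physical coupling.
* **Active walk.** On top of the drift, a persistent random walk: speed
  drawn from a truncated normal (µm/min), heading decorrelated by a
  wrapped-normal turn with `sd = sqrt(-2 log(persistence))`. A step into
  the vessel wall slides along it (preserving heading, as cells crawling
  in a lumen do); a fully blocked cell reverses.
* **Volume exclusion.** Cell bodies cannot stack below optical
  resolution: pairs of intravascular/adherent cells closer than
  `exclusion_radius_um` (default 18 µm, about one cell diameter plus the
  resolution limit) are relaxed apart each frame. The injected bolus
  still waiting at the injection site is exempt. Without this, settled
  cells pile into unresolvable clumps, the detector merges them, and the
  tracker then follows wandering cluster centroids whose path lengths are
  artifacts; with it, the detector's per-frame recall on the default
  scenario is ~0.95 and per-embryo metric means stabilize.
* **Adherent micro-motility.** Arrested cells are not perfectly static:
  `adherent_wiggle_um_per_min` (default 0.05 µm/min for the breast
  profiles) adds an unpersistent sub-cellular jitter to adherent cells.
  It contributes path length (total distance) without materially moving
  the maximum or net distance, which is exactly how arrested cells behave
  in tracked recordings.

Fates are per-interval hazards (converted as `1 - exp(-rate x dt)`):
adhesion (allowed only after `adhesion_onset_h`, default 5 h, boosted by
`cht_homing_factor` inside the CHT), extravasation of adherent cells (the
cell is moved to the nearest extravascular tissue pixel), invasion of
extravasated cells with probability `invasion_prob` (the cell moves to the
nearest avascular caudal pixel, the operational definition of an invading
cell), death, and macrophage engulfment. Engulfment requires a macrophage
within `engulf_contact_um` for `engulf_dwell_frames` consecutive frames
(default 36 frames = 6 h, matching the observed duration of host-tumor
contact before enclosure) and only arrested (adherent, extravasated or
invaded) cells are eligible — cells in circulation outrun macrophages.
Macrophages themselves perform a persistent walk through the body with a
mild bias toward the nearest tumor cell.

No proliferation is modeled, so the live count is non-increasing after
the injection window; the quantified biology at these time scales is
decline, not growth.

## Calibration of the shipped profiles

The shipped profiles are calibrated so that the *full pipeline* — simulate,
render, segment, link, measure — reproduces the published cohort means
under the study conditions (3 embryos x 175 cells, 181 frames at 600 s for
the tracking scenarios; 80 embryos for the 4-dpi cohorts). Death hazards
come directly from printed survival percentages: 76.15% of leukemic cells
surviving 0-12 h gives 0.0227/h; the Fasudil arm's 45.92% gives a death
multiplier of 2.86; 53.78% and 16.24% at 4 dpi give 0.0064/h and 0.0194/h
for metastatic and epithelial breast cells. Motility parameters
(`advection_coupling`, active speed, persistence, adhesion rate) were fit
once against the printed distance means — 459.0/353.5/566.2 µm (maximum /
net / total) for leukemic cells and 91.44/71/232.1 µm for breast cells —
and then frozen; the acceptance suite re-measures them through the full
pipeline at the printed SEM tolerances.

Two systematic effects matter when interpreting these numbers. First,
metrics are computed from *tracked* cells, so detection gaps and track
fragmentation shorten tracks; the calibration absorbs this because it is
performed through the same pipeline. Second, stationary (adherent) cells
still accumulate path length from centroid localization noise — a few
tenths of a pixel per frame, roughly 50-60 µm over a 30-h track at the
default noise levels. This is visible in the breast profile's total
distance being much larger than its maximum distance, a pattern the
published cohort shows as well.

## Detection and tracking

Segmentation is Gaussian blur (σ = 1 px) → per-frame global threshold
(256-bin Otsu by default; mean + k·SD as an alternative) → 8-connected
components → area gate [5, 500] px → intensity-weighted centroids. The
segmentation parameters of the original semi-automated workflow were never
published; these defaults are conventions chosen to be robust for the
renderer's spot model, and a per-frame threshold that claims more than
25% of the frame as foreground is treated as a failure (no foreground),
which makes blank or pure-noise frames return cleanly empty results.
Touching cells are deliberately not declumped: the original workflow
resolved clusters manually, and the programmatic analogue here is the
track-edit log, not a watershed.

Linking solves, per consecutive frame pair, the minimum-total-cost
one-to-one assignment under squared-distance cost with a hard gate
(`max_disp_um`, default 400 µm/frame — generous because circulating cells
can jump far between 10-min frames), via a Jonker-Volgenant shortest
augmenting-path solver; unmatched detections open new tracks. Track ends
are then joined to later track starts across at most `max_gap_frames`
missing frames (gate scaled by the gap), and tracks shorter than 3 points
are dropped. All of the gate, gap horizon and minimum length are package
conventions — none are stated in the original workflow — and are exposed
in the configuration. Edits (SPLIT/MERGE/DELETE/REASSIGN) are a replayable
CSV log; a manual join may exceed the automatic gate and is flagged rather
than rejected.

Rigid drift correction (integer-pixel cross-correlation of the
vasculature channel against the first frame) is available for real input
movies and off by default for synthetic ones, which are rendered
drift-free.

## Metrics, phenotypes, statistics

The four dissemination characteristics are computed in the projected
plane: maximum distance (largest pairwise distance over the path), net
distance (first to last position), total distance (path length; gap
segments contribute their straight-line chord — the minimal assumption for
unobserved frames), and mean speed (total distance over elapsed time).
Mean speed is path-length/elapsed-time rather than the mean of
instantaneous speeds; the per-step series is exported separately for
inspection. Two biases are worth knowing: sampling at a finite interval
underestimates the speed of any curved path, and wall sliding inside a
narrow lumen shortens realized steps, so confined cells move slower than
their programmed active speed (the parameter-recovery test therefore runs
in an open arena). Speeds carry explicit units (µm/s, µm/min, µm/h). The
published speed figures for this assay print in µm/s with magnitudes that
are not reconcilable with a 10-min sampling interval and the printed total
distances, so no speed calibration is attempted; distances are the
calibrated quantities.

Phenotypes per embryo: invasion (a cell outside the vessel mask and
inside the avascular caudal mask, scored at the endpoint frame, matching
scoring on fixed embryos), colocalization (either ≥25% mask overlap of a
tumor object with a macrophage object, or a centroid distance within the
sum of equivalent radii; the 25% threshold is a declared convention since
the published definition of "double positive" is qualitative; counted per
embryo), survival (live count at a timepoint over the post-injection
baseline, excluding yolk-located cells from both counts, matching the
manual counting rule), and head/trunk/tail regional counts with yolk and
out-of-body cells reported separately so the tallies conserve the total.

The statistics battery mirrors the study's: Kruskal-Wallis with
tie-corrected H and Dunn's post hoc z-tests (Holm-adjusted by default; the
source names Dunn's method without specifying an adjustment) for tracking
measurements, two-tailed Mann-Whitney U (exact by exhaustive enumeration
of label arrangements for min(n) ≤ 8, normal approximation with tie and
continuity corrections otherwise), one-way ANOVA with Dunnett's
many-to-one comparisons, and Welch's t. Stars follow the published coding
(`*` < 0.05 to `****` < 0.0001) with boundary p-values mapped to the
weaker code, since strict inequalities leave boundaries undefined. Group
comparisons are reported both pooling all cells and on per-embryo means,
because it is not published which aggregation the original cell-level
tests used.

## What the synthetic data does and does not establish

The generator reproduces the *statistical signatures* the quantification
pipeline consumes: cell-type-specific dissemination ranges, CHT homing,
survival decline, treatment effects, rising macrophage colocalization,
and embryo-level invasion. It does not attempt vascular anatomy beyond a
loop with the right landmarks, 3D lumen geometry, cell shape (amoeboid
protrusions render as isotropic spots), cluster or stream co-migration
(proximity only), vessel remodeling, or proliferation. Passing the
acceptance suite therefore demonstrates that the measurement pipeline
recovers known ground truth under realistic density, noise and motion
regimes — not that the simulator is a faithful digital embryo.

Problem sizes in the shipped tests were chosen to exercise the study
conditions at full scale where the claims demand it (3 x 175 cells x 181
frames for the distance calibrations; cohorts of 30-80 embryos for
survival) and reduced scales elsewhere.

## Numerical and degenerate-input choices

* Seeds: every stochastic stage takes an explicit seed; per-embryo seeds
  derive from the master seed by a counter scheme (`derive_seed`), so
  growing a cohort never reshuffles earlier embryos. Rendering noise uses
  a seed stream separate from the simulation.
* The assignment solver requires finite costs; gating uses a large finite
  penalty, and unmatched-row/column (birth/death) entries cost `gate^2`,
  which makes any within-gate link preferable to leaving both endpoints
  unmatched.
* Empty inputs: empty detection tables, zero-cell embryos and header-only
  CSVs flow through every stage as empty tables rather than errors; a
  zero baseline count makes survival undefined (`NA`) at the embryo level
  and an error at the `survival_fraction` level, where it indicates an
  uninjected embryo.
* Boundary pixels: masks are looked up after rounding half-down;
  out-of-bounds points are OUTSIDE for regions and FALSE for masks.
* The 16-bit TIFF writer stores intensities relative to a recorded scale;
  flow fields are stored as 32-bit float pages normalized by 2.5x the
  axial speed (caps carry a radial component above the axial speed).

## Known limitations

* The effective-kinematics abstraction means `advection_coupling` has no
  physical interpretation as a drag coefficient; only the calibrated
  displacement statistics are meaningful.
* Detection has no declumping, so dense clusters (e.g. an over-weighted
  CHT) degrade counts; the volume-exclusion default keeps the shipped
  scenarios in a regime where this is a ~5% effect.
* Drift correction is integer-pixel and rigid, suitable for the synthetic
  movies and modest real drift, not for elastic deformation.
* Engulfment is contact + dwell + removal; no phagocytosis imagery is
  rendered, so colocalization counting from images and engulfment events
  in ground truth are related but distinct readouts.
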