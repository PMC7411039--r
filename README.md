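# xenotrack

Quantifying how human tumor cells disseminate inside embryonic zebrafish
xenografts, from long-term light-sheet time-lapse movies — and simulating
such movies with known ground truth so that every stage of the
quantification can be validated.

In the embryonic zebrafish xenograft model (eZXM), ~150–200 labeled tumor
cells are injected into the duct of Cuvier of a 2-dpf embryo and imaged
for ~30 h at one frame per 10 min in maximum-intensity projection.
Leukemic cells (OCI-AML3-like) circulate rapidly through the vasculature;
metastatic breast cancer cells (MDA-MB231-like) arrest and adhere,
preferentially in the caudal hematopoietic tissue (CHT), extravasate and
can invade the avascular tail fin folds; non-malignant epithelial cells
(MCF10A-like) fail to engraft. `xenotrack` implements the full analysis
workflow for such recordings, plus an agent-based generator of synthetic
recordings for validation and calibration.

## What it computes

For each tracked cell the four dissemination characteristics, computed in
the projected anterior–posterior × dorsal–ventral plane:

* **maximum distance** — the largest Euclidean distance between any two
  time points of the migratory path, `max_{i<j} ||x_i - x_j||`;
* **net distance** — distance between first (origin) and last (final)
  positions, `||x_n - x_1||`;
* **total distance** — the path length `Σ ||x_{i+1} - x_i||` (gap
  segments contribute their straight-line chord);
* **mean speed** — total distance over elapsed time, in explicit units.

Per embryo it scores invasion (a cell outside the vasculature inside the
avascular caudal fin folds), tumor–macrophage colocalization (mask
overlap ≥ 25% or centroid criterion), survival (live count normalized to
the post-injection baseline, yolk excluded) and head/trunk/tail regional
counts. Group comparisons use the study's battery: Kruskal–Wallis +
Dunn's post hoc for tracking measurements, two-tailed Mann–Whitney U
(exact by enumeration for small n), one-way ANOVA + Dunnett, Welch's t,
with `*`/`**`/`***`/`****` star coding.

The pipeline stages are: **atlas** (stylized 2D embryo: vascular loop
with DA/CV, caps, DLAV/ISVs, CHT plexus, fin folds, yolk, flow field) →
**simulate** (agent-based cells with calibrated motility/fate profiles) →
**render** (Gaussian-spot movie, Poisson + read noise) → **segment**
(blur → Otsu → 8-connected components → area gate) → **track** (gated
Hungarian frame-pair assignment + gap closing + replayable edit log) →
**metrics / phenotypes / statistics**.

## Worked example

Simulate one leukemic embryo under the study conditions, push it through
the full pipeline, and summarize:

```r
library(xenotrack)

atlas <- build_atlas(seed = 7)                    # 400 x 1500 px, 2 um/px
cfg   <- simulation_config(n_cells = 175, n_frames = 181,
                           frame_interval_s = 600, seed = 1)
res   <- measure_embryo(atlas, leukemic_profile(), config = cfg, seed = 1)

nrow(res$metrics)                                  # tracked cells
summarize_metrics(res$metrics, rep("OCI", nrow(res$metrics)),
                  columns = c("max_um", "net_um", "total_um"))
```

```
#>   group   metric     mean      sem   n sem_undefined
#> 1   OCI   max_um 435.3801 28.08344 170         FALSE
#> 2   OCI   net_um 397.7438 27.61042 170         FALSE
#> 3   OCI total_um 610.9162 29.00335 170         FALSE
```

170 of the 175 injected cells are recovered as tracks; this embryo's
cells covered on average ~435 µm maximum distance, ~398 µm net and
~611 µm total path over up to 30 h — the rapid, far-ranging intravascular
pattern characteristic of leukemic xenografts (cohort means across
embryos land near the published 459/353.5/566 µm). Running the same with
`breast_metastatic_profile()` yields short-range adherent behavior
(~93/68/225 µm), and comparing the two metric tables with
`compare_metric_groups()` reports Kruskal–Wallis/Dunn p-values < 1e-4
with `****` stars.

Cohort-level survival, e.g. the 12-h ROCK1-inhibition (Fasudil)
experiment:

```r
run_survival_scenario("leukemic", "control", hours = 12,
                      frame_interval_s = 600, n_embryos = 8, seed = 1)$mean
#> [1] 76.11623
run_survival_scenario("leukemic", "fasudil", hours = 12,
                      frame_interval_s = 600, n_embryos = 8, seed = 2)$mean
#> [1] 46.60661
```

i.e. ~76% of leukemic cells survive 0→12 h untreated versus ~47% under
Fasudil co-injection.

## Command line

A thin CLI over the same functions ships in `inst/cli/xenotrack.R`
(subcommands `simulate | segment | track | edit | metrics | phenotype |
compare`, operating on the documented TIFF/JSON/CSV formats):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/xenotrack.R", package="xenotrack"))')" \
    track --detections detections.csv --out tracks.csv --pixel-size 2
```

## File formats

* movies: multi-page TIFF (frame-major, then channel) + JSON sidecar
  (pixel size, frame interval, intensity scale, channel names);
* atlas: 16-bit mask/region TIFF + 32-bit float flow TIFF + JSON sidecar;
* ground truth: CSV `cell_id, frame, x_px, y_px, compartment, kind`;
* detections: CSV `frame, detection_id, x_px, y_px, area_px,
  mean_intensity`;
* tracks: CSV `track_id, frame, x_px, y_px, detection_id, gap_flag`;
* edits: CSV `order, verb, track_id, track_id2, frame`, applied in order;
* run archive: every stage's output plus `manifest.json`, from which
  `read_manifest_config()` reproduces the run bit-for-bit.

Pixel coordinates are 0-based and pixel-centered; frames are 1-based.

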