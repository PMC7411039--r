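# Orchestration: reproducible simulate -> render -> segment -> track ->
# quantify -> compare runs, plus the shipped study scenarios used for
# calibration against the published cohort statistics.

resolve_profile <- function(x) {
  if (inherits(x, "motility_profile")) return(x)
  switch(x,
         leukemic = leukemic_profile(),
         breast_metastatic = breast_metastatic_profile(),
         breast_epithelial = breast_epithelial_profile(),
         stop_config("unknown profile: ", x))
}

resolve_treatment <- function(x) {
  if (inherits(x, "treatment_effect")) return(x)
  switch(x,
         control = treatment_control(),
         fasudil = treatment_fasudil(),
         no_flow = treatment_no_flow(),
         stop_config("unknown treatment: ", x))
}

#' Full run configuration
#'
#' Bundles every stage's parameters into one serializable object; a run is
#' reproducible from this record alone.
#'
#' @param profile profile name or a `motility_profile`
#' @param treatment treatment name or a `treatment_effect`
#' @param atlas_params list passed to [build_atlas()]
#' @param sim a `simulation_config`
#' @param detection a `detection_params`
#' @param linking a `linking_params`
#' @param noise a `noise_params`
#' @param speed_unit unit for the speed metric
#' @param seed master seed (overrides `sim$seed`)
#' @return a list of class `run_config`
#' @export
run_config <- function(profile = "leukemic", treatment = "control",
                       atlas_params = list(), sim = simulation_config(),
                       detection = detection_params(),
                       linking = linking_params(), noise = noise_params(),
                       speed_unit = "um_per_min", seed = sim$seed) {
  sim$seed <- as.integer(seed)
  structure(list(profile = profile, treatment = treatment,
                 atlas_params = atlas_params, sim = sim,
                 detection = detection, linking = linking, noise = noise,
                 speed_unit = speed_unit, seed = as.integer(seed)),
            class = "run_config")
}

#' Simulate and measure one embryo through the full pipeline
#'
#' Simulates ground truth, renders the tumor channel frame by frame
#' (streaming, so long movies never materialize in memory), segments each
#' frame, links detections into tracks and computes the dissemination
#' metrics.
#'
#' @param atlas an `embryo_atlas`
#' @param profile a `motility_profile`
#' @param treatment a `treatment_effect`
#' @param config a `simulation_config`
#' @param det_params a `detection_params`
#' @param link_params a `linking_params`
#' @param noise a `noise_params`
#' @param seed embryo seed
#' @param speed_unit unit for the speed metric
#' @return list with `ground_truth`, `detections`, `trackset`, `metrics`
#' @export
measure_embryo <- function(atlas, profile, treatment = treatment_control(),
                           config = simulation_config(),
                           det_params = detection_params(),
                           link_params = linking_params(),
                           noise = noise_params(), seed = config$seed,
                           speed_unit = "um_per_min") {
  gt <- simulate_embryo(atlas, profile, treatment, config, seed = seed)
  live <- gt[gt$kind == "TUMOR" &
               !(gt$compartment %in% c("DEAD", "ENGULFED")), ]
  sigma <- profile$radius_um / atlas$pixel_size_um
  H <- atlas$height_px; W <- atlas$width_px
  dets <- with_seed(derive_seed(seed, 104729L), {
    out <- vector("list", config$n_frames)
    for (f in seq_len(config$n_frames)) {
      tf <- live[live$frame == f, ]
      img <- apply_noise(render_channel(cbind(tf$x_px, tf$y_px), sigma, H, W,
                                        noise), noise)
      det <- segment_frame(img, det_params)
      attr(det, "labels") <- NULL
      out[[f]] <- if (nrow(det)) cbind(frame = f, det) else NULL
    }
    res <- do.call(rbind, out)
    if (is.null(res))
      res <- data.frame(frame = integer(0), detection_id = integer(0),
                        x_px = numeric(0), y_px = numeric(0),
                        area_px = integer(0), mean_intensity = numeric(0))
    res
  })
  ts <- link_frames(dets, link_params, atlas$pixel_size_um)
  met <- if (nrow(ts)) track_metrics(ts, atlas$pixel_size_um,
                                     config$frame_interval_s, speed_unit)
  else data.frame(track_id = integer(0), max_um = numeric(0),
                  net_um = numeric(0), total_um = numeric(0),
                  speed = numeric(0), n_points = integer(0),
                  duration_s = numeric(0))
  list(ground_truth = gt, detections = dets, trackset = ts, metrics = met)
}

#' Shipped dissemination calibration scenario
#'
#' The default tracking experiment: `n_embryos` embryos x 175 cells imaged
#' for 30 h at one frame per 10 min, pushed through the full
#' simulate->segment->track->metrics pipeline. Used to compare leukemic and
#' breast-metastatic dissemination distances against the published cohort
#' means.
#'
#' @param cell_type `"leukemic"` or `"breast_metastatic"`
#' @param seed master seed; embryo k uses `derive_seed(seed, k)`
#' @param n_embryos embryos in the cohort
#' @param atlas optional prebuilt atlas (built once and shared otherwise)
#' @return list with pooled `metrics` (extra column `embryo_id`) and the
#'   per-embryo results in `embryos`
#' @export
run_dissemination_scenario <- function(cell_type = c("leukemic", "breast_metastatic"),
                                       seed = 1L, n_embryos = 3L,
                                       atlas = NULL) {
  cell_type <- match.arg(cell_type)
  atlas <- atlas %||% build_atlas(seed = 7L)
  profile <- resolve_profile(cell_type)
  config <- simulation_config(n_embryos = n_embryos, seed = seed)
  res <- lapply(seq_len(n_embryos), function(k)
    measure_embryo(atlas, profile, treatment_control(), config,
                   seed = derive_seed(seed, k)))
  pooled <- do.call(rbind, lapply(seq_len(n_embryos), function(k) {
    m <- res[[k]]$metrics
    if (nrow(m)) cbind(embryo_id = k, m) else NULL
  }))
  list(metrics = pooled, embryos = res, atlas = atlas, profile = profile)
}

#' Shipped survival scenarios
#'
#' `run_survival_scenario` simulates a cohort on ground truth only (no
#' imaging) and reports per-embryo survival percentages: live cells
#' (yolk-located cells excluded) at the final frame normalized to the
#' post-injection baseline (frame 3).
#'
#' `hours = 96, frame_interval_s = 3600` reproduces the 4-dpi endpoint
#' counting protocol at coarse time-steps (engulfment dwell rescaled to
#' keep its ~6 h duration); `hours = 12, frame_interval_s = 600` is the
#' 12-h time-lapse protocol of the treatment experiment.
#'
#' @param profile profile name or `motility_profile`
#' @param treatment treatment name or `treatment_effect`
#' @param hours simulated duration
#' @param frame_interval_s sampling interval
#' @param n_embryos cohort size
#' @param n_cells injected cells per embryo
#' @param seed master seed
#' @param atlas optional prebuilt atlas
#' @return list with `survival` (vector, one % per embryo) and `mean`
#' @export
run_survival_scenario <- function(profile, treatment = "control", hours = 96,
                                  frame_interval_s = 3600, n_embryos = 20L,
                                  n_cells = 175L, seed = 1L, atlas = NULL) {
  atlas <- atlas %||% build_atlas(seed = 7L)
  profile <- resolve_profile(profile)
  treatment <- resolve_treatment(treatment)
  n_frames <- as.integer(round(hours * 3600 / frame_interval_s)) + 1L
  dwell <- max(1L, as.integer(round(6 * 3600 / frame_interval_s)))
  config <- simulation_config(n_embryos = n_embryos, n_cells = n_cells,
                              n_frames = n_frames,
                              frame_interval_s = frame_interval_s,
                              seed = seed, engulf_dwell_frames = dwell)
  surv <- vapply(seq_len(n_embryos), function(k) {
    gt <- simulate_embryo(atlas, profile, treatment, config,
                          seed = derive_seed(seed, k))
    ph <- phenotype_counts(gt, atlas)
    ph$survival_percent[length(ph$survival_percent)]
  }, numeric(1))
  list(survival = surv, mean = mean(surv))
}

#' Silent-heart (no-flow) migration scenario
#'
#' Simulates breast-metastatic cells without blood flow and reports the
#' pooled percentage of cells whose final recorded position lies in the
#' TAIL region.
#'
#' @param n_embryos,n_cells cohort shape (default 4 embryos x 200 cells)
#' @param seed master seed
#' @param atlas optional prebuilt atlas
#' @return list with `percent_tail` and the per-cell final regions
#' @export
run_noflow_scenario <- function(n_embryos = 4L, n_cells = 200L, seed = 1L,
                                atlas = NULL) {
  atlas <- atlas %||% build_atlas(seed = 7L)
  profile <- breast_metastatic_profile()
  config <- simulation_config(n_embryos = n_embryos, n_cells = n_cells,
                              seed = seed)
  regions <- unlist(lapply(seq_len(n_embryos), function(k) {
    gt <- simulate_embryo(atlas, profile, treatment_no_flow(), config,
                          seed = derive_seed(seed, k))
    tum <- gt[gt$kind == "TUMOR", ]
    fin <- tum[!duplicated(tum$cell_id, fromLast = TRUE), ]
    region_of(atlas, cbind(fin$x_px, fin$y_px))
  }))
  list(percent_tail = 100 * mean(regions == "TAIL"), regions = regions)
}

#' Compare metric tables between groups
#'
#' Runs the tracking-measurement battery (Kruskal-Wallis + Dunn) on each
#' dissemination metric, both pooling all cells and on per-embryo means
#' (reported side by side, since either aggregation is defensible).
#'
#' @param metrics_by_group named list of metric data frames (each with an
#'   `embryo_id` column for the per-embryo aggregation)
#' @param columns metric columns to compare
#' @return data frame of test results (one block per metric x aggregation)
#' @export
compare_metric_groups <- function(metrics_by_group,
                                  columns = c("max_um", "net_um", "total_um")) {
  out <- list()
  for (cl in columns) {
    pooled <- lapply(metrics_by_group, function(m) m[[cl]])
    kw <- kruskal_wallis_dunn(pooled)
    out[[length(out) + 1L]] <- cbind(metric = cl, aggregation = "pooled_cells",
                                     rbind(kw$overall, kw$pairwise))
    if (all(vapply(metrics_by_group, function(m) !is.null(m$embryo_id), TRUE))) {
      per_embryo <- lapply(metrics_by_group, function(m)
        tapply(m[[cl]], m$embryo_id, mean))
      if (all(lengths(per_embryo) >= 1)) {
        kw2 <- kruskal_wallis_dunn(lapply(per_embryo, as.numeric))
        out[[length(out) + 1L]] <- cbind(metric = cl,
                                         aggregation = "per_embryo_means",
                                         rbind(kw2$overall, kw2$pairwise))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full pipeline and archive every stage
#'
#' Writes, under `out_dir`: the atlas, and per embryo the ground truth
#' (CSV), rendered movie (TIFF + sidecar), detections, tracks and metrics
#' (CSV); then per-embryo phenotypes, a cohort metric summary, and a
#' manifest (config, seed, package version, config checksum) from which
#' the run can be reproduced bit-for-bit.
#'
#' @param config a `run_config`
#' @param out_dir output directory (created; must not exist or be empty)
#' @return invisibly, the manifest as a list
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)))
    stop_config("output directory exists and is not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- do.call(build_atlas, config$atlas_params)
  write_atlas(atlas, file.path(out_dir, "atlas"))
  profile <- resolve_profile(config$profile)
  treatment <- resolve_treatment(config$treatment)
  sim <- config$sim
  log <- list()
  all_metrics <- list()
  for (k in seq_len(sim$n_embryos)) {
    tag <- sprintf("embryo%02d", k)
    res <- measure_embryo(atlas, profile, treatment, sim,
                          config$detection, config$linking, config$noise,
                          seed = derive_seed(config$seed, k),
                          speed_unit = config$speed_unit)
    write_ground_truth(res$ground_truth,
                       file.path(out_dir, paste0(tag, "_ground_truth.csv")))
    mov <- render_movie(res$ground_truth, atlas, sim, config$noise,
                        seed = derive_seed(config$seed, k + 10000L))
    write_movie(mov, file.path(out_dir, paste0(tag, "_movie")))
    write.csv(res$detections, file.path(out_dir, paste0(tag, "_detections.csv")),
              row.names = FALSE)
    write_tracks(res$trackset, file.path(out_dir, paste0(tag, "_tracks.csv")))
    write.csv(res$metrics, file.path(out_dir, paste0(tag, "_metrics.csv")),
              row.names = FALSE)
    ph <- phenotype_counts(res$ground_truth, atlas, embryo_id = k)
    write.csv(data.frame(embryo_id = k,
                         baseline = ph$live[1],
                         final = ph$live[length(ph$live)],
                         survival_percent = ph$survival_percent[length(ph$survival_percent)],
                         ph$region,
                         n_invading_cells = ph$n_invading_cells,
                         invasion_positive = ph$invasion_positive),
              file.path(out_dir, paste0(tag, "_phenotype.csv")),
              row.names = FALSE)
    all_metrics[[k]] <- if (nrow(res$metrics))
      cbind(embryo_id = k, res$metrics) else NULL
    log[[k]] <- data.frame(embryo = k, n_cells = sim$n_cells,
                           n_detections = nrow(res$detections %||% data.frame()),
                           n_tracks = length(unique(res$trackset$track_id)))
  }
  pooled <- do.call(rbind, all_metrics)
  if (!is.null(pooled) && nrow(pooled)) {
    summ <- summarize_metrics(pooled, rep(profile$cell_type, nrow(pooled)))
    write.csv(summ, file.path(out_dir, "metrics_summary.csv"), row.names = FALSE)
  } else {
    write.csv(data.frame(), file.path(out_dir, "metrics_summary.csv"),
              row.names = FALSE)
  }
  write.csv(do.call(rbind, log), file.path(out_dir, "stage_log.csv"),
            row.names = FALSE)
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "xenotrack",
                   version = as.character(utils::packageVersion("xenotrack")),
                   seed = config$seed,
                   config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
                   config_checksum = sum(utf8ToInt(as.character(cfg_json))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# strip S3 classes recursively so jsonlite serializes plain lists
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Rebuild a run configuration from an archived manifest
#' @param path path to a `manifest.json` written by [run_pipeline()]
#' @return a `run_config`
#' @export
read_manifest_config <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- man$config
  run_config(profile = if (is.character(cf$profile)) cf$profile else
    do.call(motility_profile, cf$profile),
    treatment = if (is.character(cf$treatment)) cf$treatment else
      do.call(treatment_effect, cf$treatment),
    atlas_params = as.list(cf$atlas_params),
    sim = do.call(simulation_config, as.list(cf$sim)),
    detection = do.call(detection_params, cf$detection),
    linking = do.call(linking_params, cf$linking),
    noise = do.call(noise_params, cf$noise),
    speed_unit = cf$speed_unit, seed = cf$seed)
}
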