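# Per-embryo phenotype scoring: invasion of the avascular caudal fin
# folds, tumor-macrophage colocalization, survival normalized to baseline,
# and head/trunk/tail regional distribution.

#' Classify invading cells
#'
#' A cell is invading iff its position is outside the vessel mask AND
#' inside the avascular caudal mask (fin folds below the CHT and the caudal
#' fin fold). The embryo is invasion-positive if any cell invades.
#'
#' @param positions data frame with `x_px`, `y_px` (one row per cell;
#'   typically endpoint detections or final track positions)
#' @param atlas an `embryo_atlas`
#' @return list with `invading` (logical per cell), `n_invading_cells`,
#'   `invasion_positive`
#' @export
classify_invasion <- function(positions, atlas) {
  if (nrow(positions) == 0L)
    return(list(invading = logical(0), n_invading_cells = 0L,
                invasion_positive = FALSE))
  inv <- !atlas_lookup(atlas$vessel_mask, positions$x_px, positions$y_px) &
    atlas_lookup(atlas$avascular_caudal_mask, positions$x_px, positions$y_px)
  list(invading = inv, n_invading_cells = sum(inv), invasion_positive = any(inv))
}

#' Count tumor cells colocalized with macrophages
#'
#' Counts "double positive" events in one frame. Under the `"overlap"`
#' criterion, a tumor object counts if at least 25% (configurable) of its
#' segmented mask overlaps any macrophage mask; `tumor` and `macrophage`
#' must then be integer label matrices (e.g. the `"labels"` attribute of
#' [segment_frame()]). Under the `"centroid"` criterion they are detection
#' tables and a tumor cell counts if its centroid lies within the sum of
#' the two equivalent radii (`sqrt(area_px / pi)`) of some macrophage. Each
#' tumor cell is counted at most once.
#'
#' @param tumor tumor-channel label matrix or detection data frame
#' @param macrophage macrophage-channel label matrix or detection data frame
#' @param criterion `"overlap"` or `"centroid"`
#' @param min_overlap_frac overlap fraction threshold (overlap criterion)
#' @return integer count of colocalized tumor cells
#' @export
count_colocalized <- function(tumor, macrophage,
                              criterion = c("overlap", "centroid"),
                              min_overlap_frac = 0.25) {
  if (length(criterion) == 1L && !criterion %in% c("overlap", "centroid"))
    stop_config("unknown colocalization criterion: ", criterion)
  criterion <- match.arg(criterion)
  if (criterion == "overlap") {
    stopifnot(is.matrix(tumor), is.matrix(macrophage),
              all(dim(tumor) == dim(macrophage)))
    ids <- setdiff(unique(as.integer(tumor)), 0L)
    if (!length(ids)) return(0L)
    hit <- macrophage > 0
    n <- 0L
    for (id in ids) {
      sel <- tumor == id
      if (sum(hit[sel]) >= min_overlap_frac * sum(sel)) n <- n + 1L
    }
    n
  } else {
    if (!nrow(tumor) || !nrow(macrophage)) return(0L)
    rt <- sqrt(tumor$area_px / pi)
    rm_ <- sqrt(macrophage$area_px / pi)
    d <- sqrt(outer(tumor$x_px, macrophage$x_px, "-")^2 +
                outer(tumor$y_px, macrophage$y_px, "-")^2)
    sum(apply(d <= outer(rt, rm_, "+"), 1, any))
  }
}

#' Survival percentage relative to baseline
#'
#' @param counts_t live count at the timepoint (yolk-located cells excluded
#'   upstream)
#' @param counts_baseline live count at baseline
#' @return percentage, `100 * counts_t / counts_baseline`
#' @export
survival_fraction <- function(counts_t, counts_baseline) {
  if (any(counts_baseline <= 0))
    stop("baseline count is 0 (uninjected embryo?)")
  100 * counts_t / counts_baseline
}

#' Regional cell counts (head / trunk / tail)
#'
#' Tallies positions by [region_of()]; cells located in the yolk are
#' excluded from the regional tallies and reported separately, as are
#' out-of-body cells, so that `head + trunk + tail + outside + yolk`
#' equals the number of input positions.
#'
#' @param positions data frame with `x_px`, `y_px`
#' @param atlas an `embryo_atlas`
#' @return data frame with columns `head`, `trunk`, `tail`, `outside`, `yolk`
#' @export
region_counts <- function(positions, atlas) {
  if (nrow(positions) == 0L)
    return(data.frame(head = 0L, trunk = 0L, tail = 0L, outside = 0L, yolk = 0L))
  in_yolk <- atlas_lookup(atlas$yolk_mask, positions$x_px, positions$y_px)
  reg <- region_of(atlas, cbind(positions$x_px, positions$y_px))
  reg[in_yolk] <- "YOLK"
  tab <- table(factor(reg, levels = c("HEAD", "TRUNK", "TAIL", "OUTSIDE", "YOLK")))
  data.frame(head = as.integer(tab["HEAD"]), trunk = as.integer(tab["TRUNK"]),
             tail = as.integer(tab["TAIL"]), outside = as.integer(tab["OUTSIDE"]),
             yolk = as.integer(tab["YOLK"]))
}

#' Phenotype counts for one simulated embryo
#'
#' Builds the per-embryo phenotype record from ground truth: live tumor
#' counts (yolk excluded) and survival percentages at the requested
#' timepoints, endpoint regional counts, and endpoint invasion.
#'
#' @param gt a `ground_truth` data frame
#' @param atlas an `embryo_atlas`
#' @param baseline_frame frame used as the 100% baseline (default: first
#'   frame at which all cells have been injected)
#' @param timepoint_frames frames to report (default: baseline and final)
#' @param embryo_id identifier carried into the output
#' @return list of class `phenotype_counts`
#' @export
phenotype_counts <- function(gt, atlas, baseline_frame = NULL,
                             timepoint_frames = NULL, embryo_id = 1L) {
  nf <- max(gt$frame)
  baseline_frame <- baseline_frame %||% min(3L, nf)
  timepoint_frames <- timepoint_frames %||% unique(c(baseline_frame, nf))
  lc <- live_counts(gt, atlas)
  base <- lc$n_live[lc$frame == baseline_frame]
  surv <- if (length(base) && base > 0)
    survival_fraction(lc$n_live[match(timepoint_frames, lc$frame)], base)
  else rep(NA_real_, length(timepoint_frames))   # uninjected embryo
  fin <- gt[gt$kind == "TUMOR" & gt$frame == nf &
              !(gt$compartment %in% c("DEAD", "ENGULFED")), ]
  inv <- classify_invasion(fin, atlas)
  structure(list(embryo_id = embryo_id,
                 timepoint_frames = timepoint_frames,
                 live = lc$n_live[match(timepoint_frames, lc$frame)],
                 survival_percent = surv,
                 region = region_counts(fin, atlas),
                 n_invading_cells = inv$n_invading_cells,
                 invasion_positive = inv$invasion_positive),
            class = "phenotype_counts")
}
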