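# The four dissemination characteristics of a tracked cell, computed in
# the projected anterior-posterior x dorsal-ventral plane:
#   maximum distance  - largest distance between any two time points of the
#                       migratory path;
#   net distance      - distance separating the first (origin) and last
#                       (final) positions;
#   total distance    - length of the path from origin to final position
#                       (gap segments contribute their straight-line chord);
#   mean speed        - total distance / elapsed time, in explicit units.

as_track_xy <- function(track) {
  if (is.matrix(track)) return(track[, 1:2, drop = FALSE])
  stopifnot(all(c("x_px", "y_px") %in% names(track)))
  if (!is.null(track$frame)) track <- track[order(track$frame), ]
  cbind(track$x_px, track$y_px)
}

#' Maximum pairwise distance of a track (um)
#'
#' Largest Euclidean distance between any two time points of the path.
#'
#' @param track n x 2 matrix of positions in px, or a data frame with
#'   `x_px`, `y_px` (and optionally `frame`) columns
#' @param pixel_size_um pixel size
#' @return distance in micrometers
#' @export
max_distance <- function(track, pixel_size_um = 1) {
  xy <- as_track_xy(track)
  if (nrow(xy) == 0L) stop("empty track")
  if (nrow(xy) == 1L) return(0)
  max(stats::dist(xy)) * pixel_size_um
}

#' Net (first-to-last) distance of a track (um)
#' @inheritParams max_distance
#' @export
net_distance <- function(track, pixel_size_um = 1) {
  xy <- as_track_xy(track)
  if (nrow(xy) == 0L) stop("empty track")
  sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2)) * pixel_size_um
}

#' Total path length of a track (um)
#' @inheritParams max_distance
#' @export
total_distance <- function(track, pixel_size_um = 1) {
  xy <- as_track_xy(track)
  if (nrow(xy) == 0L) stop("empty track")
  sum(step_lengths(xy)) * pixel_size_um
}

#' Mean speed of a track
#'
#' Total path length divided by elapsed time between the first and last
#' frame. A track with fewer than two points has undefined speed, reported
#' as 0 with attribute `undefined = TRUE`.
#'
#' @inheritParams max_distance
#' @param frame_interval_s sampling interval (seconds)
#' @param unit output unit: `"um_per_s"`, `"um_per_min"` or `"um_per_h"`
#' @export
mean_speed <- function(track, pixel_size_um = 1, frame_interval_s = 600,
                       unit = c("um_per_s", "um_per_min", "um_per_h")) {
  unit <- match.arg(unit)
  xy <- as_track_xy(track)
  frames <- if (is.data.frame(track) && !is.null(track$frame))
    sort(track$frame) else seq_len(nrow(xy))
  if (nrow(xy) < 2L) return(structure(0, undefined = TRUE))
  elapsed_s <- (frames[length(frames)] - frames[1]) * frame_interval_s
  v <- total_distance(track, pixel_size_um) / elapsed_s
  v * switch(unit, um_per_s = 1, um_per_min = 60, um_per_h = 3600)
}

#' Instantaneous speed series of a track
#'
#' Per-step speeds (um per chosen unit), exported for inspection alongside
#' the path-length-based mean speed.
#' @inheritParams mean_speed
#' @export
instant_speeds <- function(track, pixel_size_um = 1, frame_interval_s = 600,
                           unit = c("um_per_s", "um_per_min", "um_per_h")) {
  unit <- match.arg(unit)
  xy <- as_track_xy(track)
  frames <- if (is.data.frame(track) && !is.null(track$frame))
    sort(track$frame) else seq_len(nrow(xy))
  if (nrow(xy) < 2L) return(numeric(0))
  v <- step_lengths(xy) * pixel_size_um / (diff(frames) * frame_interval_s)
  v * switch(unit, um_per_s = 1, um_per_min = 60, um_per_h = 3600)
}

#' Per-track dissemination metrics table
#'
#' @param trackset a `track_set` (or ground-truth tumor tracks coerced to
#'   the same columns)
#' @param pixel_size_um pixel size; defaults to the track set's calibration
#' @param frame_interval_s sampling interval
#' @param speed_unit unit for the speed column
#' @return data frame: `track_id`, `max_um`, `net_um`, `total_um`, `speed`,
#'   `n_points`, `duration_s`
#' @export
track_metrics <- function(trackset,
                          pixel_size_um = attr(trackset, "pixel_size_um") %||% 1,
                          frame_interval_s = 600,
                          speed_unit = "um_per_min") {
  ts <- as.data.frame(trackset)
  ids <- unique(ts$track_id)
  rows <- lapply(ids, function(id) {
    tr <- ts[ts$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    data.frame(track_id = id,
               max_um = max_distance(tr, pixel_size_um),
               net_um = net_distance(tr, pixel_size_um),
               total_um = total_distance(tr, pixel_size_um),
               speed = as.numeric(mean_speed(tr, pixel_size_um,
                                             frame_interval_s, speed_unit)),
               n_points = nrow(tr),
               duration_s = (max(tr$frame) - min(tr$frame)) * frame_interval_s)
  })
  out <- do.call(rbind, rows)
  attr(out, "speed_unit") <- speed_unit
  out
}

#' Summarize metrics per group (mean +/- SEM)
#'
#' @param metrics data frame from [track_metrics()] (optionally with extra
#'   grouping columns bound on)
#' @param grouping vector of group labels, one per row of `metrics`
#' @param columns metric columns to summarize
#' @return data frame: `group`, `metric`, `mean`, `sem`, `n`,
#'   `sem_undefined` (TRUE when n = 1). Empty groups are dropped with a
#'   warning record in `attr(, "warnings")`.
#' @export
summarize_metrics <- function(metrics, grouping,
                              columns = c("max_um", "net_um", "total_um", "speed")) {
  stopifnot(length(grouping) == nrow(metrics))
  warns <- character(0)
  levels <- unique(grouping)
  out <- list()
  for (g in levels) {
    sel <- metrics[grouping == g, , drop = FALSE]
    if (!nrow(sel)) { warns <- c(warns, paste("group", g, "empty: omitted")); next }
    for (cl in columns) {
      v <- sel[[cl]]
      n <- sum(!is.na(v))
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = cl, mean = mean(v, na.rm = TRUE),
        sem = if (n > 1) sd(v, na.rm = TRUE) / sqrt(n) else 0,
        n = n, sem_undefined = n <= 1)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "warnings") <- warns
  res
}

#' 2D tracking-map export
#'
#' Polyline per track with a distinct color index, as plotted in tracking
#' maps where each color is an individual cell.
#'
#' @param trackset a `track_set`
#' @return data frame: `track_id`, `frame`, `x_px`, `y_px`, `color_index`
#' @export
tracking_map <- function(trackset) {
  ts <- as.data.frame(trackset)[, c("track_id", "frame", "x_px", "y_px")]
  ts$color_index <- match(ts$track_id, unique(ts$track_id))
  ts
}
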