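# Frame-to-frame Hungarian linking with a hard displacement gate, followed
# by gap closing of track ends onto later track starts, re-implementing the
# automated pre-tracking stage as an algorithm with a scriptable correction
# surface (see apply_edits).

#' Linking parameters
#'
#' @param max_disp_um gating radius per frame interval (um). The default is
#'   generous because circulating leukemic cells can jump hundreds of um
#'   between 10-min frames.
#' @param max_gap_frames gap-closing horizon: a track end may be joined to
#'   a track start up to this many missing frames later, with the gate
#'   scaled by the frame gap
#' @param min_track_len_frames tracks with fewer points are discarded
#' @return a list of class `linking_params`
#' @export
linking_params <- function(max_disp_um = 400, max_gap_frames = 2L,
                           min_track_len_frames = 3L) {
  if (max_disp_um <= 0) stop_config("max_disp_um must be > 0")
  if (max_gap_frames < 0) stop_config("max_gap_frames must be >= 0")
  structure(list(max_disp_um = max_disp_um,
                 max_gap_frames = as.integer(max_gap_frames),
                 min_track_len_frames = as.integer(min_track_len_frames)),
            class = "linking_params")
}

#' Minimum-cost one-to-one assignment
#'
#' Solves the square linear assignment problem (Hungarian algorithm with
#' shortest augmenting paths). Exposed for validation; the linker uses it
#' internally with gate-padded cost matrices.
#'
#' @param cost square numeric cost matrix (use large finite values, not
#'   `Inf`, for forbidden pairings)
#' @return integer vector: assigned column for each row
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  lap_solve(cost)
}

# gated minimum-cost one-to-one matching between two point sets (px).
# Returns an integer vector: for each row of a, the matched row of b or NA.
gated_match <- function(ax, ay, bx, by, gate_px) {
  na <- length(ax); nb <- length(bx)
  if (na == 0L || nb == 0L) return(rep(NA_integer_, na))
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  g2 <- gate_px^2
  n <- na + nb
  big <- (2 * n + 10) * max(g2, 1)
  C <- matrix(big, n, n)
  C[seq_len(na), seq_len(nb)] <- ifelse(d2 <= g2, d2, big)
  C[cbind(seq_len(na), nb + seq_len(na))] <- g2        # unmatched a (death)
  C[cbind(na + seq_len(nb), seq_len(nb))] <- g2        # unmatched b (birth)
  C[na + seq_len(nb), nb + seq_len(na)] <- 0
  asg <- lap_solve(C)
  m <- rep(NA_integer_, na)
  for (i in seq_len(na)) {
    j <- asg[i]
    if (j <= nb && d2[i, j] <= g2) m[i] <- j
  }
  m
}

#' Link per-frame detections into tracks
#'
#' For each consecutive frame pair, solves the minimum-total-cost
#' one-to-one assignment with cost = squared centroid distance, forbidding
#' links beyond `max_disp_um`; unmatched detections start new tracks. Track
#' ends are then joined to later track starts (gap closing) over at most
#' `max_gap_frames` missing frames, with the gate scaled by the frame gap.
#' Tracks shorter than `min_track_len_frames` points are discarded.
#'
#' @param detections data frame from [segment_movie()] (columns `frame`,
#'   `detection_id`, `x_px`, `y_px`), sorted by frame
#' @param params a `linking_params`
#' @param pixel_size_um pixel size used to calibrate the gate
#' @return a `track_set` data frame: `track_id`, `frame`, `x_px`, `y_px`,
#'   `detection_id`, `gap_flag`
#' @export
link_frames <- function(detections, params = linking_params(),
                        pixel_size_um = 1) {
  empty <- structure(
    data.frame(track_id = integer(0), frame = integer(0), x_px = numeric(0),
               y_px = numeric(0), detection_id = integer(0),
               gap_flag = logical(0)),
    class = c("track_set", "data.frame"), pixel_size_um = pixel_size_um,
    params = params)
  if (is.null(detections) || nrow(detections) == 0L) return(empty)
  det <- detections[order(detections$frame, detections$detection_id), ]
  gate_px <- params$max_disp_um / pixel_size_um
  frames <- sort(unique(det$frame))
  by_frame <- split(seq_len(nrow(det)), det$frame)

  tid <- integer(nrow(det))
  next_id <- 1L
  first <- by_frame[[as.character(frames[1])]]
  tid[first] <- seq_len(length(first))
  next_id <- length(first) + 1L

  for (k in seq_len(length(frames) - 1L)) {
    f <- frames[k]
    if (frames[k + 1L] != f + 1L) {
      nxt <- by_frame[[as.character(frames[k + 1L])]]
      tid[nxt] <- next_id + seq_along(nxt) - 1L
      next_id <- next_id + length(nxt)
      next
    }
    a <- by_frame[[as.character(f)]]
    b <- by_frame[[as.character(f + 1L)]]
    m <- gated_match(det$x_px[a], det$y_px[a], det$x_px[b], det$y_px[b], gate_px)
    linked_b <- rep(FALSE, length(b))
    for (i in seq_along(a)) {
      if (!is.na(m[i])) { tid[b[m[i]]] <- tid[a[i]]; linked_b[m[i]] <- TRUE }
    }
    new_b <- b[!linked_b]
    if (length(new_b)) {
      tid[new_b] <- next_id + seq_along(new_b) - 1L
      next_id <- next_id + length(new_b)
    }
  }

  ts <- data.frame(track_id = tid, frame = det$frame, x_px = det$x_px,
                   y_px = det$y_px, detection_id = det$detection_id,
                   gap_flag = FALSE)
  ts <- close_gaps(ts, params, gate_px)
  len <- table(ts$track_id)
  keep <- names(len)[len >= params$min_track_len_frames]
  ts <- ts[ts$track_id %in% as.integer(keep), ]
  ts$track_id <- match(ts$track_id, sort(unique(ts$track_id)))
  ts <- ts[order(ts$track_id, ts$frame), ]
  rownames(ts) <- NULL
  structure(ts, class = c("track_set", "data.frame"),
            pixel_size_um = pixel_size_um, params = params)
}

# join track ends to later track starts (one-to-one, minimum cost, gate
# scaled by the frame gap)
close_gaps <- function(ts, params, gate_px) {
  if (params$max_gap_frames < 1L) return(ts)
  ts <- ts[order(ts$track_id, ts$frame), ]
  ids <- unique(ts$track_id)
  if (length(ids) < 2L) return(ts)
  firsts <- ts[!duplicated(ts$track_id), ]
  lasts <- ts[!duplicated(ts$track_id, fromLast = TRUE), ]
  firsts <- firsts[match(ids, firsts$track_id), ]
  lasts <- lasts[match(ids, lasts$track_id), ]
  ne <- length(ids)
  df <- outer(firsts$frame, lasts$frame, "-")   # [start s, end e]
  d <- sqrt(outer(firsts$x_px, lasts$x_px, "-")^2 +
              outer(firsts$y_px, lasts$y_px, "-")^2)
  cand <- df >= 2L & df <= params$max_gap_frames + 1L & d <= gate_px * df
  if (!any(cand)) return(ts)
  maxg2 <- (gate_px * (params$max_gap_frames + 1L))^2
  n <- 2L * ne
  big <- (2 * n + 10) * max(maxg2, 1)
  C <- matrix(big, n, n)                        # rows = ends, cols = starts
  C[seq_len(ne), seq_len(ne)] <- ifelse(t(cand), t(d)^2, big)
  C[cbind(seq_len(ne), ne + seq_len(ne))] <- maxg2
  C[cbind(ne + seq_len(ne), seq_len(ne))] <- maxg2
  C[ne + seq_len(ne), ne + seq_len(ne)] <- 0
  asg <- lap_solve(C)
  # merge matched (end e -> start s) pairs, resolving chains
  newid <- stats::setNames(ids, ids)
  resolve <- function(i) { while (newid[[as.character(i)]] != i) i <- newid[[as.character(i)]]; i }
  gap_rows <- integer(0)
  for (e in seq_len(ne)) {
    s <- asg[e]
    if (s > ne || !cand[s, e]) next
    root <- resolve(ids[e])
    newid[[as.character(ids[s])]] <- root
    gap_rows <- c(gap_rows,
                  which(ts$track_id == ids[s] & ts$frame == firsts$frame[s]))
  }
  ts$track_id <- as.integer(vapply(ts$track_id,
                                   function(i) as.numeric(resolve(i)),
                                   numeric(1)))
  ts$gap_flag[gap_rows] <- TRUE
  ts[order(ts$track_id, ts$frame), ]
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks, %d points, frames %s-%s\n",
              length(unique(x$track_id)), nrow(x),
              if (nrow(x)) min(x$frame) else NA, if (nrow(x)) max(x$frame) else NA))
  invisible(x)
}

#' Write / read a track set as CSV
#' @param ts a `track_set`
#' @param path CSV path
#' @param pixel_size_um calibration recorded on the object when reading
#' @return `read_tracks`: a `track_set`
#' @export
write_tracks <- function(ts, path) {
  write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, pixel_size_um = 1) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_px", "y_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed tracks CSV: missing columns ", paste(miss, collapse = ", "))
  if (is.null(df$detection_id)) df$detection_id <- NA_integer_
  if (is.null(df$gap_flag)) df$gap_flag <- FALSE
  structure(df[order(df$track_id, df$frame), ],
            class = c("track_set", "data.frame"),
            pixel_size_um = pixel_size_um, params = NULL)
}
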