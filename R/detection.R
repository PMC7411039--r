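# Per-frame fluorescent-cell segmentation: Gaussian blur -> global
# threshold -> 8-connected components -> area gate -> intensity-weighted
# centroids. Touching cells are not declumped; cluster resolution is
# delegated to the track-edit stage, mirroring manual correction.

#' Segmentation parameters
#'
#' @param channel 1-based channel index to segment (2 = tumor)
#' @param blur_sigma_px Gaussian pre-blur sigma in pixels (0 = none)
#' @param threshold_method `"OTSU"` (per-frame Otsu on the blurred image) or
#'   `"MEAN_K_SD"` (mean + k standard deviations)
#' @param k SD multiplier for `MEAN_K_SD`
#' @param min_area_px,max_area_px inclusive component area gate
#' @return a list of class `detection_params`
#' @export
detection_params <- function(channel = 2L, blur_sigma_px = 1,
                             threshold_method = c("OTSU", "MEAN_K_SD"),
                             k = 4, min_area_px = 5L, max_area_px = 500L) {
  threshold_method <- match.arg(threshold_method)
  if (!(min_area_px > 0 && min_area_px < max_area_px))
    stop_config("need 0 < min_area_px < max_area_px")
  if (blur_sigma_px < 0) stop_config("blur_sigma_px must be >= 0")
  structure(list(channel = as.integer(channel), blur_sigma_px = blur_sigma_px,
                 threshold_method = threshold_method, k = k,
                 min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px)),
            class = "detection_params")
}

# per-frame Otsu threshold (256-bin between-class variance maximization)
otsu_threshold <- function(v, levels = 256L) {
  rng <- range(v)
  if (diff(rng) <= 0) return(NA_real_)
  bin <- pmin(levels, floor((v - rng[1]) / diff(rng) * levels) + 1L)
  h <- tabulate(bin, levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  sb <- (mu[levels] * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  rng[1] + which.max(sb) / levels * diff(rng)
}

#' Segment one frame
#'
#' @param image_2d non-negative 2D intensity matrix (rows = y, cols = x)
#' @param params a `detection_params`
#' @return data frame with one row per detection: `detection_id`, `x_px`,
#'   `y_px` (0-based intensity-weighted centroids), `area_px`,
#'   `mean_intensity`, sorted by (y, x). The integer label matrix is
#'   attached as attribute `"labels"` (for mask-overlap colocalization).
#' @export
segment_frame <- function(image_2d, params = detection_params()) {
  stopifnot(is.matrix(image_2d), all(image_2d >= 0))
  img <- image_2d
  blur <- if (params$blur_sigma_px > 0)
    gauss_blur(img, params$blur_sigma_px) else img
  rng <- range(blur)
  empty <- data.frame(detection_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px = integer(0),
                      mean_intensity = numeric(0))
  attr(empty, "labels") <- matrix(0L, nrow(img), ncol(img))
  if (params$threshold_method == "OTSU") {
    if (diff(rng) <= 0) return(empty)   # constant image: no foreground
    thr <- otsu_threshold(blur)
    mask <- blur > thr
    # a fluorescent-spot frame is sparse; if the global threshold claims a
    # large foreground fraction it failed to separate (e.g. pure noise)
    if (mean(mask) > 0.25) return(empty)
  } else {
    thr <- mean(blur) + params$k * sd(blur)
    mask <- blur > thr
  }
  if (!any(mask)) return(empty)
  lab <- label_components_8(mask)
  idx <- which(lab > 0L)
  li <- lab[idx]
  w <- img[idx]
  ys <- (idx - 1L) %% nrow(img)          # 0-based
  xs <- (idx - 1L) %/% nrow(img)
  agg <- rowsum(cbind(1, w, w * xs, w * ys), li)
  area <- agg[, 1]; wsum <- agg[, 2]
  keep <- area >= params$min_area_px & area <= params$max_area_px
  if (!any(keep)) return(empty)
  cx <- agg[keep, 3] / wsum[keep]
  cy <- agg[keep, 4] / wsum[keep]
  ord <- order(cy, cx)
  out <- data.frame(detection_id = seq_along(cx),
                    x_px = cx[ord], y_px = cy[ord],
                    area_px = as.integer(area[keep][ord]),
                    mean_intensity = (wsum[keep] / area[keep])[ord])
  kept_labels <- as.integer(rownames(agg))[keep][ord]
  relab <- integer(max(lab))
  relab[kept_labels] <- seq_along(kept_labels)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  attr(out, "labels") <- lab
  out
}

#' Segment every frame of a movie
#'
#' Applies [segment_frame()] to the configured channel of each frame,
#' optionally after rigid drift correction against frame 1.
#'
#' @param movie a `zfx_movie`
#' @param params a `detection_params`
#' @param drift_correct apply [estimate_drift()]-based integer-pixel
#'   registration of the vasculature channel before segmenting
#' @return data frame with columns `frame`, `detection_id`, `x_px`, `y_px`,
#'   `area_px`, `mean_intensity`
#' @export
segment_movie <- function(movie, params = detection_params(),
                          drift_correct = FALSE) {
  d <- dim(movie$data)
  if (params$channel < 1L || params$channel > d[2])
    stop_config("channel index ", params$channel, " out of range (movie has ",
                d[2], " channels)")
  shifts <- if (drift_correct) estimate_drift(movie) else
    matrix(0L, d[1], 2)
  out <- vector("list", d[1])
  for (f in seq_len(d[1])) {
    img <- movie$data[f, params$channel, , ]
    if (any(shifts[f, ] != 0L)) img <- shift_image(img, shifts[f, ])
    det <- segment_frame(img, params)
    attr(det, "labels") <- NULL
    out[[f]] <- if (nrow(det)) cbind(frame = f, det) else
      data.frame(frame = integer(0), detection_id = integer(0),
                 x_px = numeric(0), y_px = numeric(0), area_px = integer(0),
                 mean_intensity = numeric(0))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rigid integer-pixel drift estimation
#'
#' Cross-correlates the vasculature channel of each frame against frame 1
#' (FFT phase of plain cross-correlation) and returns the integer (dx, dy)
#' shift that best aligns each frame to the reference.
#'
#' @param movie a `zfx_movie`
#' @param channel reference channel (default 1, the vasculature)
#' @return n_frames x 2 integer matrix of (dx, dy) shifts to apply
#' @export
estimate_drift <- function(movie, channel = 1L) {
  d <- dim(movie$data)
  ref <- movie$data[1, channel, , ]
  H <- d[3]; W <- d[4]
  Fr <- stats::fft(ref - mean(ref))
  shifts <- matrix(0L, d[1], 2)
  for (f in 2:d[1]) {
    img <- movie$data[f, channel, , ]
    cc <- Re(stats::fft(Fr * Conj(stats::fft(img - mean(img))), inverse = TRUE))
    k <- which.max(cc)
    dy <- (k - 1L) %% H; dx <- (k - 1L) %/% H
    if (dy > H / 2) dy <- dy - H
    if (dx > W / 2) dx <- dx - W
    shifts[f, ] <- c(dx, dy)
  }
  shifts
}

# integer-pixel translate; exposed margins are filled with the image median
# (background estimate) so global thresholding is not skewed
shift_image <- function(img, s) {
  dx <- s[1]; dy <- s[2]
  H <- nrow(img); W <- ncol(img)
  out <- matrix(stats::median(img), H, W)
  src_r <- max(1, 1 - dy):min(H, H - dy)
  src_c <- max(1, 1 - dx):min(W, W - dx)
  out[src_r + dy, src_c + dx] <- img[src_r, src_c]
  out
}
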