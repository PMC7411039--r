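# Synthetic movie rendering: live cells as isotropic Gaussian spots on
# their channel, the vasculature raster on channel 1, Poisson shot noise
# plus Gaussian read noise, emulating light-sheet acquisition of the
# maximum-intensity projection.

#' Noise model parameters for the renderer
#'
#' @param background mean background level (counts)
#' @param peak peak spot amplitude above background (counts)
#' @param read_sd Gaussian read-noise standard deviation (counts)
#' @param poisson apply Poisson shot noise
#' @return a list of class `noise_params`
#' @export
noise_params <- function(background = 100, peak = 1000, read_sd = 5,
                         poisson = TRUE) {
  stopifnot(background >= 0, peak >= 0, read_sd >= 0)
  structure(list(background = background, peak = peak, read_sd = read_sd,
                 poisson = isTRUE(poisson)), class = "noise_params")
}

# add Gaussian spots (sigma in px) to an intensity matrix; positions 0-based
add_spots <- function(img, xs, ys, sigma_px, peak) {
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(3 * sigma_px)
  off <- -r:r
  g <- exp(-(off^2) / (2 * sigma_px^2))
  patch <- peak * outer(g, g)          # [dy, dx]
  for (i in seq_along(xs)) {
    cx <- px_index(xs[i]) + 1L; cy <- px_index(ys[i]) + 1L
    rows <- (cy - r):(cy + r); cols <- (cx - r):(cx + r)
    ok_r <- rows >= 1L & rows <= H; ok_c <- cols >= 1L & cols <= W
    if (!any(ok_r) || !any(ok_c)) next
    img[rows[ok_r], cols[ok_c]] <- img[rows[ok_r], cols[ok_c]] +
      patch[ok_r, ok_c, drop = FALSE]
  }
  img
}

apply_noise <- function(img, noise) {
  if (noise$poisson) img <- matrix(rpois(length(img), img), nrow(img), ncol(img))
  if (noise$read_sd > 0) img <- img + rnorm(length(img), 0, noise$read_sd)
  pmax(img, 0)
}

# expected (noise-free) frame for one channel given 0-based positions
render_channel <- function(xy, sigma_px, H, W, noise) {
  img <- matrix(noise$background, H, W)
  if (nrow(xy)) img <- add_spots(img, xy[, 1], xy[, 2], sigma_px, noise$peak)
  img
}

#' Render a multi-channel time-lapse movie from ground-truth tracks
#'
#' Channel 1 carries the vasculature raster, channel 2 the tumor cells and
#' channel 3 the macrophages. Each live (non-dead, non-engulfed) cell is an
#' isotropic Gaussian spot of sigma `radius_um / pixel_size_um`.
#' Deterministic for a fixed seed.
#'
#' @param tracks a `ground_truth` data frame from [simulate_embryo()]
#' @param atlas the `embryo_atlas` the tracks were simulated on
#' @param config the `simulation_config` used
#' @param noise a `noise_params`
#' @param seed noise seed
#' @return object of class `zfx_movie`: list with `data` (T x C x Y x X
#'   array), `pixel_size_um`, `frame_interval_s`, `channels`
#' @export
render_movie <- function(tracks, atlas, config, noise = noise_params(),
                         seed = config$seed) {
  profile <- attr(tracks, "profile")
  sigma_t <- (if (is.null(profile)) 5 else profile$radius_um) / atlas$pixel_size_um
  sigma_m <- 7 / atlas$pixel_size_um
  H <- atlas$height_px; W <- atlas$width_px
  nf <- config$n_frames
  arr <- array(0, dim = c(nf, 3L, H, W))
  vessel_img <- matrix(0, H, W)
  vessel_img[atlas$vessel_mask] <- 0.6 * noise$peak
  live <- tracks[!(tracks$compartment %in% c("DEAD", "ENGULFED")), ]
  with_seed(seed, for (f in seq_len(nf)) {
    tf <- live[live$frame == f & live$kind == "TUMOR", ]
    mf <- live[live$frame == f & live$kind == "MACROPHAGE", ]
    arr[f, 1, , ] <- apply_noise(vessel_img + noise$background, noise)
    arr[f, 2, , ] <- apply_noise(
      render_channel(cbind(tf$x_px, tf$y_px), sigma_t, H, W, noise), noise)
    arr[f, 3, , ] <- apply_noise(
      render_channel(cbind(mf$x_px, mf$y_px), sigma_m, H, W, noise), noise)
  })
  structure(list(data = arr, pixel_size_um = atlas$pixel_size_um,
                 frame_interval_s = config$frame_interval_s,
                 channels = c("vasculature", "tumor", "macrophage")),
            class = "zfx_movie")
}

#' @export
print.zfx_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("zfx_movie: %d frames x %d channels x %d x %d px (%.2f um/px, %.0f s/frame)\n",
              d[1], d[2], d[3], d[4], x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Write / read a movie as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered frame-major then channel (T, C); intensities are
#' stored as 16-bit with a recorded scale.
#'
#' @param movie a `zfx_movie`
#' @param prefix output path prefix (writes `<prefix>.tif`, `<prefix>.json`)
#' @return `read_movie`: a `zfx_movie`
#' @export
write_movie <- function(movie, prefix) {
  d <- dim(movie$data)
  scale <- max(movie$data, 1)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (f in seq_len(d[1])) for (c in seq_len(d[2])) {
    pages[[k]] <- movie$data[f, c, , ] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 16,
                  compression = "none")
  jsonlite::write_json(
    list(n_frames = d[1], n_channels = d[2], height_px = d[3], width_px = d[4],
         intensity_scale = scale, pixel_size_um = movie$pixel_size_um,
         frame_interval_s = movie$frame_interval_s, channels = movie$channels,
         tif = paste0(basename(prefix), ".tif")),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_movie
#' @export
read_movie <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dirname(prefix), side$tif), all = TRUE)
  arr <- array(0, dim = c(side$n_frames, side$n_channels,
                          side$height_px, side$width_px))
  k <- 1L
  for (f in seq_len(side$n_frames)) for (c in seq_len(side$n_channels)) {
    arr[f, c, , ] <- round(pages[[k]] * 65535) / 65535 * side$intensity_scale
    k <- k + 1L
  }
  structure(list(data = arr, pixel_size_um = side$pixel_size_um,
                 frame_interval_s = side$frame_interval_s,
                 channels = side$channels), class = "zfx_movie")
}
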