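# Stylized 2D embryonic zebrafish atlas: vasculature, anatomical regions and
# a per-pixel flow field. The geometry abstracts the 2-dpf embryo as seen in
# a maximum-intensity projection: a dorsal aorta (DA) running
# anterior->posterior, the cardinal/caudal vein (CV) returning below it, the
# two joined by semicircular caps at head (heart/duct of Cuvier) and tail
# tip so that advected cells recirculate; a dorsal longitudinal anastomotic
# vessel (DLAV) fed by intersegmental vessels (ISVs); a widened caudal
# hematopoietic tissue (CHT) plexus on the posterior vein; avascular fin
# folds below the CHT and at the caudal fin; and the yolk ball. x increases
# anterior->posterior, y dorsal->ventral.

ATLAS_REGIONS <- c("OUTSIDE", "HEAD", "TRUNK", "TAIL")

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Build the stylized embryo atlas
#'
#' Constructs the labeled 2D map of the embryonic zebrafish in which the
#' simulator moves cells and against which phenotypes are scored: boolean
#' rasters for the vasculature, yolk, CHT and avascular caudal fin folds, a
#' head/trunk/tail region raster, a per-pixel blood-flow velocity field
#' (um/s, zero outside vessels) and the injection site at the duct of
#' Cuvier. Deterministic for a fixed seed (the seed jitters ISV placement).
#'
#' @param height_px,width_px canvas size in pixels (>= 64 x 256)
#' @param pixel_size_um physical pixel size in micrometers
#' @param seed integer seed for the (small) random component of the geometry
#' @param axial_flow_um_s peak flow speed in the axial vessels (um/s)
#' @return an object of class `embryo_atlas`
#' @export
build_atlas <- function(height_px = 400L, width_px = 1500L, pixel_size_um = 2.0,
                        seed = 1L, axial_flow_um_s = 300) {
  if (height_px < 64L || width_px < 256L)
    stop_config("atlas canvas too small: need at least 64 x 256 px, got ",
                height_px, " x ", width_px)
  if (pixel_size_um <= 0) stop_config("pixel_size_um must be > 0")
  H <- as.integer(height_px); W <- as.integer(width_px)

  rows <- function(yc, hw) max(1L, px_index(yc) - hw + 1L):min(H, px_index(yc) + hw + 1L)
  zero <- matrix(FALSE, H, W)

  # -- anatomical frame ------------------------------------------------------
  body_x <- c(round(0.02 * W), round(0.98 * W))        # 0-based pixel range
  body_y <- c(round(0.25 * H), round(0.83 * H))
  xa0 <- round(0.10 * W); xa1 <- round(0.90 * W)       # axial loop extent
  yc_da <- 0.47 * H; yc_cv <- 0.55 * H
  hw_ax <- max(2L, as.integer(round(0.011 * H)))
  ymid <- (yc_da + yc_cv) / 2
  rc <- (yc_cv - yc_da) / 2                            # cap centerline radius

  vx <- matrix(0, H, W); vy <- matrix(0, H, W)
  S <- axial_flow_um_s

  # DLAV
  hw_dlav <- max(1L, as.integer(round(0.0075 * H)))
  dlav <- zero
  dlav_rows <- rows(0.30 * H, hw_dlav)
  dlav_cols <- (round(0.20 * W):round(0.85 * W)) + 1L
  dlav[dlav_rows, dlav_cols] <- TRUE
  vx[dlav_rows, dlav_cols] <- 0.15 * S

  # ISVs (seeded jitter on their anterior-posterior placement)
  isv <- zero
  isv_x0 <- seq(0.22 * W, 0.84 * W, by = 0.04 * W)
  jitter <- with_seed(seed, runif(length(isv_x0), -0.004 * W, 0.004 * W))
  isv_xc <- isv_x0 + jitter
  hw_isv <- max(1L, as.integer(round(0.0015 * W)))
  y_dlav <- 0.30 * H
  isv_rows <- (px_index(y_dlav) + 1L):(px_index(yc_da) + 1L)
  isv_taper <- 0.2 * S * (seq_along(isv_rows) - 1) / max(1L, length(isv_rows) - 1L)
  for (xc in isv_xc) {
    cols <- max(1L, px_index(xc) - hw_isv + 1L):min(W, px_index(xc) + hw_isv + 1L)
    isv[isv_rows, cols] <- TRUE
    vy[isv_rows, cols] <- -isv_taper   # DA -> DLAV, tapering to zero dorsally
  }

  # CHT plexus (widened posterior vein), assigned before DA/CV so the axial
  # bands keep their own flow where they overlap it
  cht <- zero
  cht_x <- (round(0.66 * W):xa1) + 1L
  cht_top <- px_index(yc_cv) - hw_ax
  cht_bot <- cht_top + max(10L, as.integer(round(0.075 * H)))
  cht_rows <- (cht_top:min(H - 1L, cht_bot)) + 1L
  cht[cht_rows, cht_x] <- TRUE
  vx[cht_rows, cht_x] <- -0.3 * S

  # axial vessels
  da <- zero; cv <- zero
  ax_cols <- (xa0:xa1) + 1L
  da_rows <- rows(yc_da, hw_ax); cv_rows <- rows(yc_cv, hw_ax)
  da[da_rows, ax_cols] <- TRUE
  cv[cv_rows, ax_cols] <- TRUE
  vx[da_rows, ax_cols] <- S
  vx[cv_rows, ax_cols] <- -S
  vy[da_rows, ax_cols] <- 0
  vy[cv_rows, ax_cols] <- 0

  # circulatory caps joining DA and CV at head and tail
  cap <- zero
  yy <- matrix(0:(H - 1), H, W)
  xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  for (xc in c(xa0, xa1)) {
    dx <- xx - xc; dy <- yy - ymid
    r <- sqrt(dx^2 + dy^2)
    side <- if (xc == xa0) dx <= 0 else dx >= 0
    in_cap <- side & r >= (rc - hw_ax) & r <= (rc + hw_ax)
    cap <- cap | in_cap
    phi <- atan2(dy[in_cap], dx[in_cap])
    # tangential (clockwise) flow plus a weak radial component toward the
    # lumen centerline so advected tracers stay centered around the turn
    ctr <- 0.3 * (rc - r[in_cap]) / hw_ax
    vx[in_cap] <- (-sin(phi) + ctr * cos(phi)) * S
    vy[in_cap] <- (cos(phi) + ctr * sin(phi)) * S
  }

  vessel <- da | cv | cap | dlav | isv | cht
  vx[!vessel] <- 0; vy[!vessel] <- 0

  # yolk ball (anterior-ventral, below the cardinal vein)
  yolk <- ((xx - 0.17 * W) / (0.09 * W))^2 + ((yy - 0.70 * H) / (0.11 * H))^2 <= 1
  yolk <- yolk & !vessel

  # avascular caudal masks: ventral fin fold below the CHT + caudal fin fold
  avascular <- zero
  ff_rows <- ((cht_bot + 3L):round(0.80 * H)) + 1L
  avascular[ff_rows, cht_x] <- TRUE
  caud_cols <- (round(0.93 * W):round(0.98 * W)) + 1L
  caud_rows <- (round(0.35 * H):round(0.75 * H)) + 1L
  avascular[caud_rows, caud_cols] <- TRUE
  avascular <- avascular & !vessel

  # region raster over the embryo body
  region <- matrix(1L, H, W)   # OUTSIDE
  in_body <- xx >= body_x[1] & xx <= body_x[2] & yy >= body_y[1] & yy <= body_y[2]
  in_body <- in_body | vessel | avascular | yolk
  len <- body_x[2] - body_x[1]
  fx <- (xx - body_x[1]) / len
  region[in_body & fx < 0.25] <- 2L                       # HEAD
  region[in_body & fx >= 0.25 & fx < 0.55] <- 3L          # TRUNK
  region[in_body & fx >= 0.55] <- 4L                      # TAIL

  injection <- c(x = round(0.13 * W), y = px_index(yc_cv))
  stopifnot(vessel[injection["y"] + 1L, injection["x"] + 1L])

  structure(list(
    height_px = H, width_px = W, pixel_size_um = pixel_size_um,
    vessel_mask = vessel, yolk_mask = yolk,
    avascular_caudal_mask = avascular, cht_mask = cht,
    region_raster = region, flow_vx = vx, flow_vy = vy,
    injection_site_px = injection, seed = as.integer(seed),
    axial_flow_um_s = axial_flow_um_s,
    body_x = body_x, body_y = body_y
  ), class = "embryo_atlas")
}

#' @export
print.embryo_atlas <- function(x, ...) {
  cat(sprintf("embryo_atlas %d x %d px (%.2f um/px), %d vessel px, seed %d\n",
              x$height_px, x$width_px, x$pixel_size_um,
              sum(x$vessel_mask), x$seed))
  invisible(x)
}

#' Anatomical region at a point
#'
#' Looks up the head/trunk/tail region raster at the pixel containing each
#' point (0-based pixel-centered coordinates, rounded half-down).
#' Out-of-bounds points return `"OUTSIDE"`.
#'
#' @param atlas an `embryo_atlas`
#' @param point_px numeric `c(x, y)` or an n x 2 matrix of points
#' @return character vector of region labels
#' @export
region_of <- function(atlas, point_px) {
  p <- if (is.matrix(point_px)) point_px else matrix(point_px, ncol = 2)
  ix <- px_index(p[, 1]); iy <- px_index(p[, 2])
  ok <- ix >= 0 & ix < atlas$width_px & iy >= 0 & iy < atlas$height_px
  out <- rep("OUTSIDE", nrow(p))
  if (any(ok))
    out[ok] <- ATLAS_REGIONS[atlas$region_raster[cbind(iy[ok] + 1L, ix[ok] + 1L)]]
  out
}

# value of a mask / field at 0-based (x, y) positions (vectors)
atlas_lookup <- function(m, x, y) {
  H <- nrow(m); W <- ncol(m)
  ix <- px_index(x); iy <- px_index(y)
  ok <- ix >= 0 & ix < W & iy >= 0 & iy < H
  out <- rep(if (is.logical(m)) FALSE else 0, length(x))
  if (any(ok)) out[ok] <- m[cbind(iy[ok] + 1L, ix[ok] + 1L)]
  out
}

#' Advect a massless tracer along the flow field
#'
#' Follows the flow-field streamline from a start point with fixed-length
#' steps (unit-speed advection). Used to verify that the vascular loop is
#' closed: a tracer released at the injection site recirculates without
#' leaving the vessel mask.
#'
#' @param atlas an `embryo_atlas`
#' @param start `c(x, y)` start point; defaults to the injection site
#' @param n_steps number of advection steps
#' @param step_px step length in pixels
#' @return n x 2 matrix of visited positions (0-based px)
#' @export
advect_tracer <- function(atlas, start = NULL, n_steps = 1000L, step_px = 1) {
  p <- as.numeric(start %||% atlas$injection_site_px)
  out <- matrix(NA_real_, n_steps, 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(n_steps)) {
    v <- c(atlas_lookup(atlas$flow_vx, p[1], p[2]),
           atlas_lookup(atlas$flow_vy, p[1], p[2]))
    nv <- sqrt(sum(v^2))
    if (nv > 0) p <- p + step_px * v / nv
    out[i, ] <- p
  }
  out
}

#' Serialize an atlas to TIFF rasters plus a JSON sidecar
#'
#' Writes `<prefix>_masks.tif` (pages: vessel, yolk, avascular caudal, CHT,
#' region raster; 16-bit), `<prefix>_flow.tif` (2-page 32-bit float, vx/vy
#' normalized by the recorded flow scale) and `<prefix>.json` (pixel size,
#' landmarks, flow scale, seed).
#'
#' @param atlas an `embryo_atlas`
#' @param prefix output path prefix
#' @return invisibly, the sidecar path
#' @export
write_atlas <- function(atlas, prefix) {
  pages <- lapply(list(atlas$vessel_mask, atlas$yolk_mask,
                       atlas$avascular_caudal_mask, atlas$cht_mask,
                       atlas$region_raster),
                  function(m) matrix(as.numeric(m) / 65535, nrow(m), ncol(m)))
  tiff::writeTIFF(pages, paste0(prefix, "_masks.tif"), bits.per.sample = 16,
                  compression = "none")
  # margin over the axial speed: cap flow carries an extra radial component
  scale <- 2.5 * atlas$axial_flow_um_s
  flow <- lapply(list(atlas$flow_vx, atlas$flow_vy),
                 function(m) m / scale + 0.5)
  tiff::writeTIFF(flow, paste0(prefix, "_flow.tif"), bits.per.sample = 32,
                  compression = "none")
  side <- list(height_px = atlas$height_px, width_px = atlas$width_px,
               pixel_size_um = atlas$pixel_size_um,
               injection_site_px = as.list(atlas$injection_site_px),
               flow_scale_um_s = scale, seed = atlas$seed,
               axial_flow_um_s = atlas$axial_flow_um_s,
               body_x = atlas$body_x, body_y = atlas$body_y,
               masks = paste0(basename(prefix), "_masks.tif"),
               flow = paste0(basename(prefix), "_flow.tif"))
  path <- paste0(prefix, ".json")
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an atlas written by [write_atlas()]
#' @param prefix path prefix used when writing
#' @return an `embryo_atlas`
#' @export
read_atlas <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dir <- dirname(prefix)
  masks <- tiff::readTIFF(file.path(dir, side$masks), all = TRUE)
  flow <- tiff::readTIFF(file.path(dir, side$flow), all = TRUE)
  as_int <- function(m) matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  scale <- side$flow_scale_um_s
  inj <- c(x = side$injection_site_px$x, y = side$injection_site_px$y)
  structure(list(
    height_px = side$height_px, width_px = side$width_px,
    pixel_size_um = side$pixel_size_um,
    vessel_mask = as_int(masks[[1]]) > 0, yolk_mask = as_int(masks[[2]]) > 0,
    avascular_caudal_mask = as_int(masks[[3]]) > 0,
    cht_mask = as_int(masks[[4]]) > 0, region_raster = as_int(masks[[5]]),
    flow_vx = (flow[[1]] - 0.5) * scale, flow_vy = (flow[[2]] - 0.5) * scale,
    injection_site_px = inj, seed = side$seed,
    axial_flow_um_s = side$axial_flow_um_s,
    body_x = side$body_x, body_y = side$body_y
  ), class = "embryo_atlas")
}
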