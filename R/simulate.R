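# Agent-based simulation of xenografted tumor cells (and host macrophages)
# in the embryo atlas, with per-frame ground truth.

COMP_INTRA <- 1L; COMP_ADHER <- 2L; COMP_EXTRA <- 3L; COMP_INVAD <- 4L
COMP_ENGULF <- 5L; COMP_DEAD <- 6L; COMP_MACRO <- 7L

turn_sd_from_persistence <- function(p) if (p <= 0) Inf else sqrt(-2 * log(p))

# one confined step: accept the proposal if the target pixel is inside
# `mask`, otherwise slide along x or y, otherwise stay
confined_step <- function(mask, x, y, dx, dy) {
  nx <- x + dx; ny <- y + dy
  ok <- atlas_lookup(mask, nx, ny)
  x2 <- ifelse(ok, nx, x); y2 <- ifelse(ok, ny, y)
  rem <- !ok
  if (any(rem)) {
    okx <- rem & atlas_lookup(mask, nx, y)
    x2[okx] <- nx[okx]
    oky <- rem & !okx & atlas_lookup(mask, x, ny)
    y2[oky] <- ny[oky]
  }
  list(x = x2, y = y2)
}

# spiral-search the nearest pixel of `mask` within `max_r` px of (x, y);
# returns c(x, y) or NULL
nearest_mask_pixel <- function(mask, x, y, max_r) {
  H <- nrow(mask); W <- ncol(mask)
  cx <- px_index(x); cy <- px_index(y)
  for (r in 0:max_r) {
    dxs <- -r:r
    cand <- unique(rbind(cbind(cx + dxs, cy - r), cbind(cx + dxs, cy + r),
                         cbind(cx - r, cy + dxs), cbind(cx + r, cy + dxs)))
    ok <- cand[, 1] >= 0 & cand[, 1] < W & cand[, 2] >= 0 & cand[, 2] < H
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    hit <- mask[cbind(cand[, 2] + 1L, cand[, 1] + 1L)]
    if (any(hit)) {
      cand <- cand[hit, , drop = FALSE]
      d2 <- (cand[, 1] - x)^2 + (cand[, 2] - y)^2
      return(as.numeric(cand[which.min(d2), ]))
    }
  }
  NULL
}

#' Simulate one xenografted embryo
#'
#' Runs the agent-based model: tumor cells appear at the injection site
#' (duct of Cuvier) within the first 3 frames, are redistributed along the
#' vasculature by the circulation (if flow is on), then move by effective
#' advective drift plus an active persistent random walk confined to the
#' vessel lumen. Cells can become adherent (hazard boosted in the CHT after
#' the adhesion onset), extravasate, invade the avascular caudal fin folds,
#' die, or be engulfed by a macrophage after sustained contact. Host
#' macrophages perform a tumor-biased walk through the embryo body.
#'
#' @param atlas an `embryo_atlas`
#' @param profile a `motility_profile`
#' @param treatment a `treatment_effect`
#' @param config a `simulation_config`
#' @param seed seed for this embryo (defaults to `config$seed`)
#' @return a `ground_truth` data frame with columns `cell_id`, `frame`,
#'   `x_px`, `y_px`, `compartment`, `kind`; a cell's final row carries its
#'   terminal compartment (`DEAD`/`ENGULFED`) and no rows follow it
#' @export
simulate_embryo <- function(atlas, profile, treatment = treatment_control(),
                            config = simulation_config(),
                            seed = config$seed) {
  stopifnot(inherits(atlas, "embryo_atlas"), inherits(profile, "motility_profile"),
            inherits(treatment, "treatment_effect"),
            inherits(config, "simulation_config"))
  if (!treatment$flow_on && profile$advection_coupling > 0 &&
      profile$active_speed_um_per_min[1] == 0)
    warning("flow disabled with an advection-only profile: cells will stay near the injection site")
  with_seed(seed, simulate_embryo_impl(atlas, profile, treatment, config))
}

simulate_embryo_impl <- function(atlas, profile, treatment, config) {
  n <- config$n_cells
  nm <- if (config$macrophages_enabled) config$n_macrophages else 0L
  nf <- config$n_frames
  px <- atlas$pixel_size_um
  dt_h <- config$frame_interval_s / 3600
  dt_min <- config$frame_interval_s / 60
  vessel <- atlas$vessel_mask
  in_body <- atlas$region_raster > 1L
  tissue <- in_body & !vessel & !atlas$yolk_mask

  inj <- as.numeric(atlas$injection_site_px)
  birth <- if (n > 0) ((seq_len(n) - 1L) %% min(3L, nf)) + 1L else integer(0)

  # redistribution destinations (fast circulation during the first interval)
  do_jump <- profile$redistribute && profile$advection_coupling > 0 &&
    treatment$flow_on && n > 0
  if (do_jump) {
    vp <- which(vessel, arr.ind = TRUE)           # row = y+1, col = x+1
    w <- ifelse(atlas$cht_mask[vp], profile$cht_weight, 1)
    pick <- sample.int(nrow(vp), n, replace = TRUE, prob = w)
    dest_x <- vp[pick, 2] - 1L + runif(n, -0.4, 0.4)
    dest_y <- vp[pick, 1] - 1L + runif(n, -0.4, 0.4)
  }

  x <- rep(inj[1], n); y <- rep(inj[2], n)
  heading <- runif(n, 0, 2 * pi)
  comp <- rep(COMP_INTRA, n)
  terminal <- rep(NA_integer_, n)   # frame at which a terminal row was written
  streak <- integer(n)

  # macrophages
  if (nm > 0) {
    tp <- which(in_body, arr.ind = TRUE)
    mp <- sample.int(nrow(tp), nm, replace = TRUE)
    mx <- tp[mp, 2] - 1L + runif(nm, -0.4, 0.4)
    my <- tp[mp, 1] - 1L + runif(nm, -0.4, 0.4)
    mhead <- runif(nm, 0, 2 * pi)
  }

  death_h <- profile$death_hazard_per_h * treatment$death_multiplier
  p_death <- 1 - exp(-death_h * dt_h)
  turn_sd <- turn_sd_from_persistence(profile$persistence)
  sp_mean <- profile$active_speed_um_per_min[1]
  sp_sd <- profile$active_speed_um_per_min[2]

  rec <- vector("list", nf)
  for (f in seq_len(nf)) {
    born <- birth <= f
    live <- born & comp < COMP_ENGULF
    mover <- live & comp == COMP_INTRA & birth < f
    if (do_jump) {
      jump <- mover & birth == (f - 1L)
      x[jump] <- dest_x[jump]; y[jump] <- dest_y[jump]
      mover <- mover & !jump
    }
    idx <- which(mover)
    if (length(idx)) {
      # advective drift (two confined substeps)
      if (treatment$flow_on && profile$advection_coupling > 0) {
        for (s in 1:2) {
          vx <- atlas_lookup(atlas$flow_vx, x[idx], y[idx])
          vy <- atlas_lookup(atlas$flow_vy, x[idx], y[idx])
          fac <- profile$advection_coupling * config$frame_interval_s / (2 * px)
          st <- confined_step(vessel, x[idx], y[idx], vx * fac, vy * fac)
          x[idx] <- st$x; y[idx] <- st$y
        }
      }
      # active persistent walk; a step into the wall slides along it
      # (preserving heading, as a cell crawling inside a vessel lumen),
      # and a fully blocked cell turns around
      if (sp_mean > 0 || sp_sd > 0) {
        sp <- pmax(0, rnorm(length(idx), sp_mean, sp_sd)) *
          treatment$motility_multiplier * dt_min / px
        h <- if (is.finite(turn_sd)) heading[idx] + rnorm(length(idx), 0, turn_sd)
             else runif(length(idx), 0, 2 * pi)
        st <- confined_step(vessel, x[idx], y[idx], sp * cos(h), sp * sin(h))
        moved <- st$x != x[idx] | st$y != y[idx] | sp < 1e-9
        x[idx] <- st$x; y[idx] <- st$y
        heading[idx] <- ifelse(moved, h, h + pi)
      }
    }

    # soft volume exclusion: intravascular/adherent cell bodies cannot
    # stack below optical resolution (motile profiles only)
    motile <- sp_mean > 0 || sp_sd > 0 || profile$advection_coupling > 0
    excl <- profile$exclusion_radius_um / px
    # the injected bolus (cells still waiting at the injection site) is
    # allowed to overlap; exclusion starts once a cell is in the tissue
    ex <- which(born & comp <= COMP_ADHER & birth < f)
    if (motile && excl > 0 && length(ex) > 1L) {
      for (it in 1:4) {
        d2 <- outer(x[ex], x[ex], "-")^2 + outer(y[ex], y[ex], "-")^2
        pr <- which(upper.tri(d2) & d2 < excl^2, arr.ind = TRUE)
        if (!nrow(pr)) break
        for (rr in seq_len(nrow(pr))) {
          i <- ex[pr[rr, 1]]; j <- ex[pr[rr, 2]]
          ddx <- x[j] - x[i]; ddy <- y[j] - y[i]
          d <- sqrt(ddx^2 + ddy^2)
          if (d < 1e-6) {
            ang <- 2 * pi * ((i + j) %% 7) / 7
            ddx <- cos(ang); ddy <- sin(ang); d <- 1
          }
          push <- (excl - d) / 2
          ux <- ddx / d; uy <- ddy / d
          st <- confined_step(vessel, x[i], y[i], -push * ux, -push * uy)
          x[i] <- st$x; y[i] <- st$y
          st <- confined_step(vessel, x[j], y[j], push * ux, push * uy)
          x[j] <- st$x; y[j] <- st$y
        }
      }
    }

    # adherent cells keep a residual sub-cellular jitter
    wig <- profile$adherent_wiggle_um_per_min %||% 0
    if (wig > 0) {
      adh <- which(born & comp == COMP_ADHER)
      if (length(adh)) {
        wsp <- abs(rnorm(length(adh), 0, wig)) * dt_min / px
        wh <- runif(length(adh), 0, 2 * pi)
        st <- confined_step(vessel, x[adh], y[adh], wsp * cos(wh), wsp * sin(wh))
        x[adh] <- st$x; y[adh] <- st$y
      }
    }

    # fate transitions ------------------------------------------------------
    age_h <- (f - birth) * dt_h
    if (profile$adhesion_rate_per_h > 0) {
      eligible <- which(live & comp == COMP_INTRA & age_h >= profile$adhesion_onset_h)
      if (length(eligible)) {
        rate <- profile$adhesion_rate_per_h *
          ifelse(atlas_lookup(atlas$cht_mask, x[eligible], y[eligible]),
                 profile$cht_homing_factor, 1)
        hit <- runif(length(eligible)) < 1 - exp(-rate * dt_h)
        comp[eligible[hit]] <- COMP_ADHER
      }
    }
    if (profile$extravasation_prob_per_h > 0) {
      adh <- which(live & comp == COMP_ADHER)
      if (length(adh)) {
        hit <- adh[runif(length(adh)) <
                     1 - exp(-profile$extravasation_prob_per_h * dt_h)]
        for (i in hit) {
          p <- nearest_mask_pixel(tissue, x[i], y[i], 15L)
          if (is.null(p)) next
          comp[i] <- COMP_EXTRA; x[i] <- p[1]; y[i] <- p[2]
          if (runif(1) < profile$invasion_prob) {
            q <- nearest_mask_pixel(atlas$avascular_caudal_mask, x[i], y[i], 80L)
            if (!is.null(q)) { comp[i] <- COMP_INVAD; x[i] <- q[1]; y[i] <- q[2] }
          }
        }
      }
    }
    if (p_death > 0) {
      lv <- which(live)
      comp[lv[runif(length(lv)) < p_death]] <- COMP_DEAD
    }

    # macrophages: persistent walk with a bias toward the nearest tumor cell
    if (nm > 0) {
      tgt <- which(born & comp < COMP_ENGULF)
      msp <- pmax(0, rnorm(nm, 1.0, 0.4)) * dt_min / px
      mhead <- mhead + rnorm(nm, 0, turn_sd_from_persistence(0.5))
      ddx <- cos(mhead); ddy <- sin(mhead)
      if (length(tgt)) {
        for (m in seq_len(nm)) {
          d2 <- (x[tgt] - mx[m])^2 + (y[tgt] - my[m])^2
          j <- which.min(d2)
          if (d2[j] < (150 / px)^2) {
            dn <- sqrt(d2[j])
            if (dn > 1e-9) {
              ddx[m] <- 0.5 * ddx[m] + 0.5 * (x[tgt[j]] - mx[m]) / dn
              ddy[m] <- 0.5 * ddy[m] + 0.5 * (y[tgt[j]] - my[m]) / dn
            }
          }
        }
      }
      st <- confined_step(in_body, mx, my, msp * ddx, msp * ddy)
      mx <- st$x; my <- st$y
      mhead <- atan2(ddy, ddx)
      # engulfment: sustained contact for engulf_dwell_frames; only
      # arrested cells (adherent/extravasated/invaded) can be engulfed --
      # cells in circulation outrun the macrophage
      liv <- which(born & comp >= COMP_ADHER & comp < COMP_ENGULF)
      if (length(liv)) {
        cd <- config$engulf_contact_um / px
        mind <- sapply(liv, function(i) min((mx - x[i])^2 + (my - y[i])^2))
        streak[liv] <- ifelse(mind <= cd^2, streak[liv] + 1L, 0L)
        gone <- liv[streak[liv] >= config$engulf_dwell_frames]
        comp[gone] <- COMP_ENGULF
      }
    }

    # record ---------------------------------------------------------------
    show <- which(born & (comp < COMP_ENGULF |
                            (comp >= COMP_ENGULF & is.na(terminal))))
    terminal[show[comp[show] >= COMP_ENGULF]] <- f
    parts <- list(data.frame(cell_id = show, frame = rep(f, length(show)),
                             x_px = x[show], y_px = y[show],
                             compartment = comp[show],
                             kind = rep("TUMOR", length(show))))
    if (nm > 0)
      parts[[2]] <- data.frame(cell_id = n + seq_len(nm), frame = f,
                               x_px = mx, y_px = my,
                               compartment = COMP_MACRO, kind = "MACROPHAGE")
    rec[[f]] <- do.call(rbind, parts)
  }

  out <- do.call(rbind, rec)
  out <- out[order(out$cell_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out$compartment <- COMPARTMENTS[out$compartment]
  structure(out, class = c("ground_truth", "data.frame"),
            pixel_size_um = px, frame_interval_s = config$frame_interval_s,
            profile = profile, treatment = treatment, config = config)
}

#' Per-frame live tumor cell count
#'
#' Counts tumor cells that are neither dead nor engulfed at each frame,
#' optionally excluding cells located in the yolk.
#'
#' @param gt a `ground_truth` data frame
#' @param atlas pass the atlas to exclude yolk-located cells (the manual
#'   counting rule); `NULL` to count everywhere
#' @return data frame with columns `frame`, `n_live`
#' @export
live_counts <- function(gt, atlas = NULL) {
  g <- gt[gt$kind == "TUMOR" & !(gt$compartment %in% c("DEAD", "ENGULFED")), ]
  if (!is.null(atlas) && nrow(g))
    g <- g[!atlas_lookup(atlas$yolk_mask, g$x_px, g$y_px), ]
  frames <- seq_len(max(gt$frame))
  tab <- table(factor(g$frame, levels = frames))
  data.frame(frame = frames, n_live = as.integer(tab))
}

#' Write / read ground-truth tracks as CSV
#'
#' Lossless round trip of the simulated per-frame positions and
#' compartments. `read_ground_truth` validates the schema and rejects
#' files in which a cell's frames are not strictly increasing.
#'
#' @param gt a `ground_truth` data frame
#' @param path CSV path
#' @return `read_ground_truth`: a `ground_truth` data frame
#' @export
write_ground_truth <- function(gt, path) {
  write.csv(as.data.frame(gt)[, c("cell_id", "frame", "x_px", "y_px",
                                  "compartment", "kind")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "x_px", "y_px", "compartment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed ground-truth CSV: missing columns ", paste(miss, collapse = ", "))
  if (is.null(df$kind)) df$kind <- "TUMOR"
  bad <- !df$compartment %in% COMPARTMENTS
  if (any(bad))
    stop("malformed ground-truth CSV at line ", which(bad)[1] + 1L,
         ": unknown compartment '", df$compartment[which(bad)[1]], "'")
  if (nrow(df) > 1) {
    same <- df$cell_id[-1] == df$cell_id[-nrow(df)]
    nonmono <- same & diff(df$frame) <= 0
    if (any(nonmono))
      stop("malformed ground-truth CSV at line ", which(nonmono)[1] + 2L,
           ": frames not strictly increasing for cell_id ",
           df$cell_id[which(nonmono)[1] + 1L])
  }
  structure(df, class = c("ground_truth", "data.frame"))
}
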