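# Motility profiles, treatment effects and simulation configuration.
#
# A note on kinematics: blood in the axial vessels moves at hundreds of
# um/s, so over one 10-min sampling interval a fully entrained cell would
# complete many circuits of the vascular loop. The simulator therefore
# works on *effective per-interval displacements*: a one-off redistribution
# jump along the vasculature at entry into circulation (standing in for the
# fast dissemination phase right after injection) followed by slow
# kinematics in which `advection_coupling` is the small fraction of the
# local flow velocity retained as net drift per interval, plus an active
# persistent random walk. Shipped defaults are calibrated so that the full
# simulate->segment->track->metric pipeline reproduces the cohort means
# reported for leukemic (OCI-AML3) and breast (MDA-MB231, MCF10A) xenografts.

COMPARTMENTS <- c("INTRAVASCULAR", "ADHERENT", "EXTRAVASATED", "INVADED",
                  "ENGULFED", "DEAD", "MACROPHAGE")

#' Construct a motility profile
#'
#' Describes the cell-type-specific kinematics and fate hazards of a tumor
#' cell population.
#'
#' @param cell_type one of `"LEUKEMIC"`, `"BREAST_METASTATIC"`,
#'   `"BREAST_EPITHELIAL"` (or a custom tag)
#' @param advection_coupling fraction in \[0, 1\] of the local flow velocity
#'   applied as drift per frame (effective, see file header)
#' @param active_speed_um_per_min `c(mean, sd)` of the active-step speed
#' @param persistence directional correlation of the active walk in \[0, 1)
#' @param adhesion_rate_per_h hazard of becoming adherent, multiplied by
#'   `cht_homing_factor` inside the CHT
#' @param cht_homing_factor multiplier on the adhesion hazard inside the CHT
#' @param adhesion_onset_h hours after injection before adhesion can begin
#' @param extravasation_prob_per_h hazard of leaving the vessel once adherent
#' @param invasion_prob per-cell probability that an extravasated cell
#'   migrates on into the avascular caudal fin folds
#' @param death_hazard_per_h baseline clearance hazard
#' @param radius_um rendered spot radius (Gaussian sigma)
#' @param exclusion_radius_um soft volume-exclusion distance between cell
#'   centers (cell bodies cannot stack below optical resolution); applied
#'   only to motile profiles
#' @param adherent_wiggle_um_per_min residual micro-motility of adherent
#'   cells (unpersistent sub-cellular jitter; arrested cells are not
#'   perfectly static)
#' @param redistribute logical; draw a post-injection redistribution jump
#'   along the vasculature (disabled automatically when
#'   `advection_coupling == 0` or flow is off)
#' @param cht_weight relative weight of CHT pixels in the redistribution
#'   destination draw (models CHT homing of disseminating cells)
#' @return object of class `motility_profile`
#' @export
motility_profile <- function(cell_type,
                             advection_coupling,
                             active_speed_um_per_min,
                             persistence,
                             adhesion_rate_per_h = 0,
                             cht_homing_factor = 1,
                             adhesion_onset_h = 5,
                             extravasation_prob_per_h = 0,
                             invasion_prob = 0,
                             death_hazard_per_h = 0,
                             radius_um = 5,
                             exclusion_radius_um = 18,
                             adherent_wiggle_um_per_min = 0,
                             redistribute = TRUE,
                             cht_weight = 1) {
  stopifnot(advection_coupling >= 0, advection_coupling <= 1,
            length(active_speed_um_per_min) == 2,
            active_speed_um_per_min[1] >= 0,
            persistence >= 0, persistence < 1,
            adhesion_rate_per_h >= 0, extravasation_prob_per_h >= 0,
            invasion_prob >= 0, invasion_prob <= 1,
            death_hazard_per_h >= 0, radius_um > 0, cht_weight >= 0)
  structure(list(cell_type = cell_type,
                 advection_coupling = advection_coupling,
                 active_speed_um_per_min = as.numeric(active_speed_um_per_min),
                 persistence = persistence,
                 adhesion_rate_per_h = adhesion_rate_per_h,
                 cht_homing_factor = cht_homing_factor,
                 adhesion_onset_h = adhesion_onset_h,
                 extravasation_prob_per_h = extravasation_prob_per_h,
                 invasion_prob = invasion_prob,
                 death_hazard_per_h = death_hazard_per_h,
                 radius_um = radius_um,
                 exclusion_radius_um = exclusion_radius_um,
                 adherent_wiggle_um_per_min = adherent_wiggle_um_per_min,
                 redistribute = isTRUE(redistribute),
                 cht_weight = cht_weight),
            class = "motility_profile")
}

#' Shipped motility profiles
#'
#' Calibrated defaults for the three xenografted populations: fast
#' circulating leukemic cells (OCI-AML3-like), short-range adhering
#' metastatic breast cells (MDA-MB231-like) and non-engrafting breast
#' epithelial cells (MCF10A-like). Death hazards follow the printed
#' survival percentages (76.15% of leukemic cells over 12 h; 53.78% and
#' 16.24% at 4 dpi for metastatic and epithelial cells); motility
#' parameters are calibrated so the full pipeline reproduces the printed
#' per-cell distance means.
#'
#' @return a `motility_profile`
#' @export
leukemic_profile <- function() {
  motility_profile(
    cell_type = "LEUKEMIC",
    advection_coupling = 3.45e-5,
    active_speed_um_per_min = c(0.27, 0.21),
    persistence = 0.30,
    adhesion_rate_per_h = 0.002,
    cht_homing_factor = 2,
    adhesion_onset_h = 5,
    death_hazard_per_h = 0.0227,
    radius_um = 2,
    cht_weight = 1)
}

#' @rdname leukemic_profile
#' @export
breast_metastatic_profile <- function() {
  motility_profile(
    cell_type = "BREAST_METASTATIC",
    advection_coupling = 1.5e-6,
    active_speed_um_per_min = c(0.45, 0.29),
    persistence = 0.90,
    adhesion_rate_per_h = 0.12,
    cht_homing_factor = 3,
    adhesion_onset_h = 5,
    extravasation_prob_per_h = 0.002,
    invasion_prob = 0.02,
    death_hazard_per_h = 0.0064,
    radius_um = 2.5,
    adherent_wiggle_um_per_min = 0.03,
    cht_weight = 3)
}

#' @rdname leukemic_profile
#' @export
breast_epithelial_profile <- function() {
  p <- breast_metastatic_profile()
  p$cell_type <- "BREAST_EPITHELIAL"
  p$death_hazard_per_h <- 0.0194
  p$extravasation_prob_per_h <- 0
  p$invasion_prob <- 0
  p
}

#' Construct a treatment effect
#'
#' @param name tag for reports
#' @param motility_multiplier factor >= 0 applied to the active speed
#' @param death_multiplier factor >= 1 applied to the death hazard
#' @param flow_on logical; `FALSE` models silent-heart morphants (no blood
#'   flow, so no advection and no post-injection redistribution)
#' @return object of class `treatment_effect`
#' @export
treatment_effect <- function(name = "control", motility_multiplier = 1,
                             death_multiplier = 1, flow_on = TRUE) {
  stopifnot(is.finite(motility_multiplier), motility_multiplier >= 0,
            is.finite(death_multiplier), death_multiplier >= 1)
  structure(list(name = name, motility_multiplier = motility_multiplier,
                 death_multiplier = death_multiplier, flow_on = isTRUE(flow_on)),
            class = "treatment_effect")
}

#' Shipped treatment effects
#'
#' `treatment_control()` is the identity treatment. `treatment_fasudil()`
#' models ROCK1 inhibition as a death-hazard and motility multiplier,
#' calibrated so ~46% of leukemic cells survive 0->12 h versus ~76%
#' untreated. `treatment_no_flow()` models silent-heart morphants.
#' @return a `treatment_effect`
#' @export
treatment_control <- function() treatment_effect("control")

#' @rdname treatment_control
#' @export
treatment_fasudil <- function()
  treatment_effect("fasudil", motility_multiplier = 0.5, death_multiplier = 2.86)

#' @rdname treatment_control
#' @export
treatment_no_flow <- function() treatment_effect("no_flow", flow_on = FALSE)

#' Simulation configuration
#'
#' Defaults emulate the study conditions: ~175 injected cells per embryo,
#' 30 h of imaging at one frame per 10 min (181 frames).
#'
#' @param n_embryos number of embryos in a cohort run
#' @param n_cells injected tumor cells per embryo
#' @param n_macrophages host macrophage agents per embryo
#' @param n_frames frames per movie (>= 2)
#' @param frame_interval_s sampling interval in seconds
#' @param seed master seed; per-embryo seeds are derived via [derive_seed()]
#' @param engulf_contact_um tumor-macrophage contact distance for engulfment
#' @param engulf_dwell_frames consecutive contact frames before engulfment
#'   (default 36 frames = 6 h at the default interval)
#' @param macrophages_enabled `FALSE` models macrophage ablation
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_embryos = 3L, n_cells = 175L,
                              n_macrophages = 10L, n_frames = 181L,
                              frame_interval_s = 600, seed = 1L,
                              engulf_contact_um = 20,
                              engulf_dwell_frames = 36L,
                              macrophages_enabled = TRUE) {
  if (n_frames < 2L) stop_config("n_frames must be >= 2")
  if (frame_interval_s <= 0) stop_config("frame_interval_s must be > 0")
  stopifnot(n_cells >= 0, n_macrophages >= 0)
  structure(list(n_embryos = as.integer(n_embryos),
                 n_cells = as.integer(n_cells),
                 n_macrophages = as.integer(n_macrophages),
                 n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s, seed = as.integer(seed),
                 engulf_contact_um = engulf_contact_um,
                 engulf_dwell_frames = as.integer(engulf_dwell_frames),
                 macrophages_enabled = isTRUE(macrophages_enabled)),
            class = "simulation_config")
}
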