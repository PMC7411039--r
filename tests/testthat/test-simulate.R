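test_that("identical seeds give identical tracks", {
  a <- small_atlas()
  cfg <- simulation_config(n_cells = 30L, n_frames = 25L, seed = 5L)
  g1 <- simulate_embryo(a, leukemic_profile(), config = cfg, seed = 5L)
  g2 <- simulate_embryo(a, leukemic_profile(), config = cfg, seed = 5L)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  g3 <- simulate_embryo(a, leukemic_profile(), config = cfg, seed = 6L)
  expect_false(identical(as.data.frame(g1), as.data.frame(g3)))
})

test_that("cells appear at the injection site within the first 3 frames", {
  a <- small_atlas()
  cfg <- simulation_config(n_cells = 40L, n_frames = 12L, seed = 2L)
  gt <- simulate_embryo(a, breast_metastatic_profile(), config = cfg)
  tum <- gt[gt$kind == "TUMOR", ]
  first <- tum[!duplicated(tum$cell_id), ]
  expect_true(all(first$frame <= 3L))
  inj <- a$injection_site_px
  expect_true(all(first$x_px == inj["x"] & first$y_px == inj["y"]))
})

test_that("null-motility cells stay at the injection site", {
  a <- small_atlas()
  p <- motility_profile("CUSTOM", advection_coupling = 0,
                        active_speed_um_per_min = c(0, 0), persistence = 0.5)
  cfg <- simulation_config(n_cells = 10L, n_frames = 15L, n_macrophages = 0L,
                           seed = 1L)
  gt <- simulate_embryo(a, p, config = cfg)
  inj <- a$injection_site_px
  expect_true(all(gt$x_px == inj["x"] & gt$y_px == inj["y"]))
  expect_true(all(gt$compartment == "INTRAVASCULAR"))
})

test_that("compartment transitions follow the fate DAG", {
  a <- small_atlas()
  # high rates to exercise every transition
  p <- motility_profile("CUSTOM", advection_coupling = 1e-5,
                        active_speed_um_per_min = c(0.3, 0.1),
                        persistence = 0.6, adhesion_rate_per_h = 2,
                        cht_homing_factor = 2, adhesion_onset_h = 0.5,
                        extravasation_prob_per_h = 1, invasion_prob = 0.5,
                        death_hazard_per_h = 0.08, cht_weight = 4)
  cfg <- simulation_config(n_cells = 250L, n_frames = 90L, seed = 9L)
  gt <- simulate_embryo(a, p, config = cfg)
  tum <- gt[gt$kind == "TUMOR", ]
  expect_gt(nrow(tum), 1e4)  # enough cell-frames to be a meaningful check
  rank_of <- c(INTRAVASCULAR = 1, ADHERENT = 2, EXTRAVASATED = 3, INVADED = 4,
               ENGULFED = 9, DEAD = 9)
  for (tr in split(tum, tum$cell_id)) {
    expect_true(all(diff(tr$frame) == 1L))           # contiguous until the end
    r <- rank_of[tr$compartment]
    expect_true(all(diff(r) >= 0))                   # no backward transition
    expect_true(all(r[-length(r)] < 9))              # terminal states end the track
  }
  expect_true(any(tum$compartment == "ADHERENT"))
  expect_true(any(tum$compartment == "EXTRAVASATED"))
  expect_true(any(tum$compartment == "INVADED"))
  expect_true(any(tum$compartment == "DEAD"))
  # invaded cells sit inside the avascular caudal mask
  inv <- tum[tum$compartment == "INVADED", ]
  ok <- a$avascular_caudal_mask[cbind(ceiling(inv$y_px - 0.5) + 1L,
                                      ceiling(inv$x_px - 0.5) + 1L)]
  expect_true(all(ok))
})

test_that("intravascular cells stay inside the vessel mask", {
  a <- small_atlas()
  cfg <- simulation_config(n_cells = 60L, n_frames = 30L, seed = 4L)
  gt <- simulate_embryo(a, leukemic_profile(), config = cfg)
  iv <- gt[gt$compartment == "INTRAVASCULAR", ]
  ok <- a$vessel_mask[cbind(ceiling(iv$y_px - 0.5) + 1L,
                            ceiling(iv$x_px - 0.5) + 1L)]
  expect_true(all(ok))
})

test_that("leukemic cells overwhelmingly remain in circulation", {
  a <- default_atlas()
  cfg <- simulation_config(n_frames = 30L, seed = 2L)
  gt <- simulate_embryo(a, leukemic_profile(), config = cfg)
  tum <- gt[gt$kind == "TUMOR", ]
  expect_gte(mean(tum$compartment == "INTRAVASCULAR"), 0.9)
})

test_that("live tumor count never increases after the injection window", {
  a <- small_atlas()
  cfg <- simulation_config(n_cells = 80L, n_frames = 60L, seed = 8L)
  gt <- simulate_embryo(a, breast_epithelial_profile(), config = cfg)
  lc <- live_counts(gt)
  expect_true(all(diff(lc$n_live[3:nrow(lc)]) <= 0))
})

test_that("flow-off advection-only profiles warn but still simulate", {
  a <- small_atlas()
  p <- motility_profile("CUSTOM", advection_coupling = 0.5,
                        active_speed_um_per_min = c(0, 0), persistence = 0.5)
  cfg <- simulation_config(n_cells = 5L, n_frames = 10L, seed = 1L)
  expect_warning(gt <- simulate_embryo(a, p, treatment_no_flow(), cfg),
                 "injection site")
  inj <- a$injection_site_px
  # no advective transport: cells remain near the injection site (volume
  # exclusion can nudge them apart by a few cell radii)
  d <- sqrt((gt$x_px[gt$kind == "TUMOR"] - inj["x"])^2 +
              (gt$y_px[gt$kind == "TUMOR"] - inj["y"])^2)
  expect_true(all(d < 30))
})

test_that("macrophage engulfment needs sustained contact and removes the cell", {
  a <- small_atlas()
  # cells adhere immediately (only arrested cells can be engulfed),
  # macrophages walk nearby, short dwell
  p <- motility_profile("CUSTOM", advection_coupling = 0,
                        active_speed_um_per_min = c(0, 0), persistence = 0.5,
                        adhesion_rate_per_h = 50, adhesion_onset_h = 0)
  cfg <- simulation_config(n_cells = 3L, n_macrophages = 25L, n_frames = 60L,
                           engulf_contact_um = 120, engulf_dwell_frames = 5L,
                           seed = 3L)
  gt <- simulate_embryo(a, p, config = cfg)
  tum <- gt[gt$kind == "TUMOR", ]
  eng <- tum[tum$compartment == "ENGULFED", ]
  expect_gt(nrow(eng), 0)
  # engulfed on-frame is the cell's last row and came after >= dwell frames
  for (i in eng$cell_id) {
    tr <- tum[tum$cell_id == i, ]
    expect_identical(tr$compartment[nrow(tr)], "ENGULFED")
    expect_gte(nrow(tr), 5L)
  }
  # ablated macrophages (macrophages_enabled = FALSE) never engulf
  cfg2 <- simulation_config(n_cells = 3L, n_macrophages = 25L, n_frames = 60L,
                            engulf_contact_um = 120, engulf_dwell_frames = 5L,
                            seed = 3L, macrophages_enabled = FALSE)
  gt2 <- simulate_embryo(a, p, config = cfg2)
  expect_false(any(gt2$compartment == "ENGULFED"))
})

test_that("ground-truth CSV round-trips losslessly", {
  a <- small_atlas()
  cfg <- simulation_config(n_cells = 10L, n_frames = 12L, seed = 6L)
  gt <- simulate_embryo(a, leukemic_profile(), config = cfg)
  path <- tempfile(fileext = ".csv")
  write_ground_truth(gt, path)
  rt <- read_ground_truth(path)
  expect_equal(as.data.frame(gt)[, names(rt)], as.data.frame(rt),
               tolerance = 1e-12)
})

test_that("empty track list writes a header-only CSV", {
  gt <- structure(data.frame(cell_id = integer(0), frame = integer(0),
                             x_px = numeric(0), y_px = numeric(0),
                             compartment = character(0), kind = character(0)),
                  class = c("ground_truth", "data.frame"))
  path <- tempfile(fileext = ".csv")
  write_ground_truth(gt, path)
  expect_identical(nrow(read_ground_truth(path)), 0L)
  expect_match(readLines(path)[1], "cell_id")
})

test_that("non-monotone frames in a ground-truth CSV are a parse error", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("cell_id,frame,x_px,y_px,compartment",
               "1,1,0,0,INTRAVASCULAR",
               "1,3,0,0,INTRAVASCULAR",
               "1,2,0,0,INTRAVASCULAR"), path)
  expect_error(read_ground_truth(path), "line 4")
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("cell_id,frame,x_px", "1,1,0"), path2)
  expect_error(read_ground_truth(path2), "missing columns")
})
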