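gauss_spot <- function(img, x0, y0, sigma, peak) {
  H <- nrow(img); W <- ncol(img)
  yy <- matrix(0:(H - 1), H, W); xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  img + peak * exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * sigma^2))
}

test_that("blank and constant images give no detections", {
  expect_identical(nrow(segment_frame(matrix(0, 60, 80))), 0L)
  expect_identical(nrow(segment_frame(matrix(7, 60, 80))), 0L)  # constant, OTSU
  set.seed(1)
  noise <- matrix(abs(rnorm(60 * 80, 100, 5)), 60, 80)          # pure noise
  expect_identical(nrow(segment_frame(noise)), 0L)
})

test_that("two spots 50 px apart are found within 1 px at SNR 10", {
  set.seed(2)
  img <- matrix(rnorm(120 * 160, 100, 10), 120, 160)
  img <- gauss_spot(img, 40, 60, 2, 1000)
  img <- gauss_spot(img, 90, 60, 2, 1000)
  det <- segment_frame(pmax(img, 0), detection_params())
  expect_identical(nrow(det), 2L)
  expect_lt(abs(det$x_px[1] - 40), 1); expect_lt(abs(det$y_px[1] - 60), 1)
  expect_lt(abs(det$x_px[2] - 90), 1); expect_lt(abs(det$y_px[2] - 60), 1)
})

test_that("the area gate removes specks and caps blob size", {
  img <- matrix(0, 50, 50)
  img[20, 20] <- 1000; img[20, 21] <- 1000          # 2-px speck
  det <- segment_frame(img, detection_params(blur_sigma_px = 0, min_area_px = 5))
  expect_identical(nrow(det), 0L)
  img2 <- matrix(0, 50, 50); img2[10:40, 10:40] <- 1000   # 961-px slab
  det2 <- segment_frame(img2, detection_params(blur_sigma_px = 0,
                                               max_area_px = 500))
  expect_identical(nrow(det2), 0L)
})

test_that("raising min_area_px never increases the detection count", {
  set.seed(3)
  img <- matrix(rnorm(150 * 150, 100, 8), 150, 150)
  for (k in 1:12)
    img <- gauss_spot(img, runif(1, 15, 135), runif(1, 15, 135),
                      runif(1, 1, 3), 900)
  img <- pmax(img, 0)
  prev <- Inf
  for (ma in c(1, 5, 10, 20, 40, 80)) {
    n <- nrow(segment_frame(img, detection_params(min_area_px = ma)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("MEAN_K_SD thresholding works and parameters validate", {
  img <- matrix(100, 80, 80)
  img <- gauss_spot(img, 40, 40, 2, 1000)
  det <- segment_frame(img, detection_params(threshold_method = "MEAN_K_SD", k = 4))
  expect_identical(nrow(det), 1L)
  expect_error(detection_params(min_area_px = 10, max_area_px = 5),
               class = "xenotrack_config_error")
  expect_error(detection_params(blur_sigma_px = -1),
               class = "xenotrack_config_error")
})

test_that("segment_movie tracks the configured channel framewise", {
  a <- small_atlas()
  inj <- a$injection_site_px
  gt <- make_gt(matrix(c(inj["x"], inj["y"]), 1), n_frames = 20L)
  attr(gt, "profile") <- leukemic_profile()
  cfg <- simulation_config(n_cells = 1L, n_frames = 20L, seed = 1L)
  mov <- render_movie(gt, a, cfg)
  det <- segment_movie(mov, detection_params())
  expect_identical(nrow(det), 20L)
  expect_identical(sort(unique(det$frame)), 1:20)
  expect_error(segment_movie(mov, detection_params(channel = 9L)),
               class = "xenotrack_config_error")
})

test_that("an empty movie yields an empty detection table with the schema", {
  a <- small_atlas()
  gt <- structure(data.frame(cell_id = integer(0), frame = integer(0),
                             x_px = numeric(0), y_px = numeric(0),
                             compartment = character(0), kind = character(0)),
                  class = c("ground_truth", "data.frame"))
  cfg <- simulation_config(n_cells = 0L, n_frames = 2L, seed = 1L)
  mov <- render_movie(gt, a, cfg)
  det <- segment_movie(mov, detection_params())
  expect_identical(nrow(det), 0L)
  expect_true(all(c("frame", "detection_id", "x_px", "y_px", "area_px",
                    "mean_intensity") %in% names(det)))
})

test_that("per-frame detection counts track the live ground-truth count", {
  a <- default_atlas()
  cfg <- simulation_config(n_frames = 20L, seed = 6L)
  res <- measure_embryo(a, leukemic_profile(), config = cfg, seed = 6L)
  gt <- res$ground_truth
  live <- live_counts(gt)
  det_per_frame <- table(factor(res$detections$frame, levels = 1:20))
  for (f in 4:20) {   # after the injection window
    expect_lt(abs(as.integer(det_per_frame[f]) - live$n_live[f]),
              0.1 * live$n_live[f] + 1)
  }
})

test_that("rigid drift is estimated and undone before segmentation", {
  a <- small_atlas()
  inj <- a$injection_site_px
  gt <- make_gt(matrix(c(inj["x"], inj["y"]), 1), n_frames = 3L)
  attr(gt, "profile") <- leukemic_profile()
  cfg <- simulation_config(n_cells = 1L, n_frames = 3L, seed = 1L)
  mov <- render_movie(gt, a, cfg, noise_params(read_sd = 0, poisson = FALSE))
  # impose a known drift on frames 2 and 3 (all channels)
  sh <- list(c(0L, 0L), c(5L, -3L), c(-7L, 4L))
  for (f in 2:3) for (ch in 1:3)
    mov$data[f, ch, , ] <- xenotrack:::shift_image(mov$data[f, ch, , ], sh[[f]])
  est <- estimate_drift(mov)
  expect_identical(est[2, ], -sh[[2]])
  expect_identical(est[3, ], -sh[[3]])
  det <- segment_movie(mov, detection_params(), drift_correct = TRUE)
  expect_identical(nrow(det), 3L)
  expect_true(all(abs(det$x_px - inj["x"]) < 1))
  expect_true(all(abs(det$y_px - inj["y"]) < 1))
})
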