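# Frozen oracle values for the worked path
# (0,0) -> (10,0) -> (10,10) -> (0,10) -> (2,2):
#   max  = |(0,0)-(10,10)|            = sqrt(200)        = 14.1421356...
#   net  = |(0,0)-(2,2)|              = sqrt(8)          = 2.8284271...
#   total= 10 + 10 + 10 + |(0,10)-(2,2)| = 30 + sqrt(68) = 38.2462113...
worked_path <- cbind(c(0, 10, 10, 0, 2), c(0, 0, 10, 10, 2))

test_that("distance metrics reproduce hand-computed values", {
  expect_equal(max_distance(worked_path, 1), sqrt(200))
  expect_equal(net_distance(worked_path, 1), sqrt(8))
  expect_equal(total_distance(worked_path, 1), 30 + sqrt(68))
  p <- cbind(c(0, 3), c(0, 4))
  expect_equal(max_distance(p, 1), 5)
  expect_equal(net_distance(p, 1), 5)
  expect_equal(total_distance(p, 1), 5)
  expect_equal(max_distance(p, 2.5), 12.5)     # calibration scales linearly
  loop <- cbind(c(0, 5, 5, 0, 0), c(0, 0, 5, 5, 0))
  expect_equal(net_distance(loop, 1), 0)
  single <- matrix(c(3, 4), 1)
  expect_equal(max_distance(single, 1), 0)
  expect_equal(net_distance(single, 1), 0)
  expect_equal(total_distance(single, 1), 0)
  expect_error(max_distance(matrix(numeric(0), 0, 2)), "empty")
  expect_error(net_distance(matrix(numeric(0), 0, 2)), "empty")
})

test_that("mean speed is path length over elapsed time in explicit units", {
  tr <- data.frame(frame = 1:5, x_px = worked_path[, 1], y_px = worked_path[, 2])
  v <- mean_speed(tr, 1, 600, "um_per_s")
  expect_equal(as.numeric(v), (30 + sqrt(68)) / 2400)   # 0.0159359...
  expect_equal(as.numeric(mean_speed(tr, 1, 600, "um_per_h")),
               (30 + sqrt(68)) / 2400 * 3600, tolerance = 1e-9)  # 57.369...
  stat <- data.frame(frame = 1:10, x_px = 5, y_px = 5)
  expect_equal(as.numeric(mean_speed(stat, 1, 600)), 0)
  one <- data.frame(frame = 1L, x_px = 0, y_px = 0)
  v1 <- mean_speed(one, 1, 600)
  expect_equal(as.numeric(v1), 0)
  expect_true(attr(v1, "undefined"))
  expect_length(instant_speeds(tr, 1, 600), 4L)
  expect_equal(instant_speeds(tr, 1, 600, "um_per_min")[1], 1)   # 10 px / 10 min
})

test_that("net <= max <= total on random tracks", {
  set.seed(21)
  for (i in 1:10000) {
    n <- sample(2:8, 1)
    xy <- cbind(cumsum(rnorm(n, 0, 3)), cumsum(rnorm(n, 0, 3)))
    mx <- max_distance(xy, 1); nt <- net_distance(xy, 1); tt <- total_distance(xy, 1)
    if (nt > mx + 1e-12 || mx > tt + 1e-12)
      fail(sprintf("ordering violated: net=%g max=%g total=%g", nt, mx, tt))
  }
  succeed()
})

test_that("distances are invariant under translation and rotation", {
  set.seed(22)
  for (i in 1:50) {
    xy <- cbind(cumsum(rnorm(6)), cumsum(rnorm(6)))
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    xy2 <- sweep(xy %*% R, 2, c(runif(1, -50, 50), runif(1, -50, 50)), "+")
    expect_equal(max_distance(xy2, 1), max_distance(xy, 1), tolerance = 1e-9)
    expect_equal(net_distance(xy2, 1), net_distance(xy, 1), tolerance = 1e-9)
    expect_equal(total_distance(xy2, 1), total_distance(xy, 1), tolerance = 1e-9)
  }
})

test_that("gap segments contribute straight-line chords to total distance", {
  tr <- data.frame(frame = c(1, 2, 5), x_px = c(0, 3, 9), y_px = 0)
  expect_equal(total_distance(tr, 1), 9)
  expect_equal(as.numeric(mean_speed(tr, 1, 100)), 9 / 400)
})

test_that("summaries report mean, SEM, n and degenerate flags", {
  m <- data.frame(max_um = c(1, 2, 3, 10), net_um = 1, total_um = 1, speed = 1)
  g <- c("a", "a", "a", "b")
  s <- summarize_metrics(m, g)
  row <- s[s$group == "a" & s$metric == "max_um", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sem, sd(1:3) / sqrt(3))     # 0.57735...
  expect_identical(row$n, 3L)
  rb <- s[s$group == "b" & s$metric == "max_um", ]
  expect_true(rb$sem_undefined)
  expect_equal(rb$sem, 0)
  # identical groups summarize identically
  m2 <- rbind(m[1:3, ], m[1:3, ])
  s2 <- summarize_metrics(m2, rep(c("x", "y"), each = 3))
  sx <- s2[s2$group == "x", -1]; sy <- s2[s2$group == "y", -1]
  rownames(sx) <- rownames(sy) <- NULL
  expect_equal(sx, sy)
})

test_that("track_metrics computes per-track rows from a track set", {
  det <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, detection_id = 1:2,
               x_px = c(f * 2, 100), y_px = c(0, 100 + f))))
  ts <- link_frames(det, linking_params(max_disp_um = 50), 1)
  tm <- track_metrics(ts, pixel_size_um = 2, frame_interval_s = 600)
  expect_identical(nrow(tm), 2L)
  expect_equal(sort(tm$total_um), c(4 * 1, 4 * 2) * 2)  # 1 and 2 px/frame, 2 um/px
  expect_equal(tm$duration_s, c(2400, 2400))
})

test_that("the tracking map assigns each track a distinct color", {
  det <- do.call(rbind, lapply(1:4, function(f)
    data.frame(frame = f, detection_id = 1:3,
               x_px = c(f, 50 + f, 100 + f), y_px = c(0, 50, 100))))
  ts <- link_frames(det, linking_params(max_disp_um = 10), 1)
  mp <- tracking_map(ts)
  expect_identical(length(unique(mp$color_index)),
                   length(unique(mp$track_id)))
})

test_that("programmed active speeds are recovered from ground-truth tracks", {
  # open arena (vessel everywhere) so the walk is unconfined: inside a
  # narrow lumen, wall sliding systematically shortens steps, which is a
  # property of confinement, not of the speed estimator
  a <- small_atlas()
  a$vessel_mask[] <- TRUE
  # 30-s sampling so even the fastest programmed walk stays local
  for (s in c(1, 5, 20)) {
    p <- motility_profile("CUSTOM", advection_coupling = 0,
                          active_speed_um_per_min = c(s, 0),
                          persistence = 0.9, exclusion_radius_um = 0,
                          redistribute = FALSE)
    cfg <- simulation_config(n_cells = 40L, n_frames = 40L,
                             frame_interval_s = 30, n_macrophages = 0L,
                             seed = 17L)
    gt <- simulate_embryo(a, p, config = cfg, seed = 17L)
    tum <- gt[gt$kind == "TUMOR", ]
    sp <- vapply(split(tum, tum$cell_id), function(tr)
      as.numeric(mean_speed(tr, a$pixel_size_um, 30, "um_per_min")),
      numeric(1))
    expect_lt(abs(mean(sp) - s) / s, 0.1)
  }
})
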