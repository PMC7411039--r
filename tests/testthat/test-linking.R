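drift_detections <- function(n_frames, x0 = 10, step = 2, y = 5) {
  do.call(rbind, lapply(seq_len(n_frames), function(f)
    data.frame(frame = f, detection_id = 1L, x_px = x0 + (f - 1) * step,
               y_px = y, area_px = 10L, mean_intensity = 500)))
}

test_that("a drifting cell yields exactly one track", {
  det <- drift_detections(10L)
  ts <- link_frames(det, linking_params(max_disp_um = 10), pixel_size_um = 1)
  expect_identical(length(unique(ts$track_id)), 1L)
  expect_identical(nrow(ts), 10L)
  expect_true(all(diff(ts$frame) == 1L))
})

test_that("linking matches the brute-force minimum-cost assignment", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    a <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    b <- a + matrix(rnorm(2 * n, 0, 4), n, 2)
    det <- rbind(data.frame(frame = 1L, detection_id = seq_len(n),
                            x_px = a[, 1], y_px = a[, 2]),
                 data.frame(frame = 2L, detection_id = seq_len(n),
                            x_px = b[, 1], y_px = b[, 2]))
    ts <- link_frames(det, linking_params(max_disp_um = 1e4,
                                          min_track_len_frames = 1L),
                      pixel_size_um = 1)
    expect_equal(linked_cost(ts, 1L, 2L),
                 brute_force_match_cost(a[, 1], a[, 2], b[, 1], b[, 2]),
                 tolerance = 1e-9)
  }
})

test_that("two crossing cells are assigned by minimum total cost", {
  # cells swap sides; min-cost keeps each on its own (straight) path
  det <- rbind(
    data.frame(frame = 1L, detection_id = 1:2, x_px = c(0, 30), y_px = c(0, 0)),
    data.frame(frame = 2L, detection_id = 1:2, x_px = c(14, 16), y_px = c(1, -1)),
    data.frame(frame = 3L, detection_id = 1:2, x_px = c(30, 0), y_px = c(2, -2)))
  ts <- link_frames(det, linking_params(max_disp_um = 100,
                                        min_track_len_frames = 1L), 1)
  expect_identical(length(unique(ts$track_id)), 2L)
  for (f in 1:2) {
    a <- det[det$frame == f, ]; b <- det[det$frame == f + 1L, ]
    expect_equal(linked_cost(ts, f, f + 1L),
                 brute_force_match_cost(a$x_px, a$y_px, b$x_px, b$y_px),
                 tolerance = 1e-9)
  }
})

test_that("the gate forbids long links and starts a new track instead", {
  det <- rbind(data.frame(frame = 1L, detection_id = 1L, x_px = 0, y_px = 0),
               data.frame(frame = 2L, detection_id = 1L, x_px = 50, y_px = 0),
               data.frame(frame = 3L, detection_id = 1L, x_px = 100, y_px = 0))
  ts <- link_frames(det, linking_params(max_disp_um = 10, max_gap_frames = 0L,
                                        min_track_len_frames = 1L),
                    pixel_size_um = 1)
  expect_identical(length(unique(ts$track_id)), 3L)
})

test_that("a single missing detection is bridged by gap closing", {
  det <- drift_detections(10L)
  det <- det[det$frame != 5L, ]
  ts <- link_frames(det, linking_params(max_disp_um = 10, max_gap_frames = 2L), 1)
  expect_identical(length(unique(ts$track_id)), 1L)
  expect_identical(nrow(ts), 9L)
  expect_true(ts$gap_flag[ts$frame == 6L])
  expect_identical(sum(ts$gap_flag), 1L)
  # gap-closing respects the scaled gate
  gap_step <- with(ts[ts$frame %in% c(4L, 6L), ], diff(x_px))
  expect_lte(abs(gap_step), 10 * 2)
})

test_that("gap closing beyond the horizon splits the track", {
  det <- drift_detections(12L)
  det <- det[!det$frame %in% 5:7, ]   # 3 missing frames > max_gap 2
  ts <- link_frames(det, linking_params(max_disp_um = 10, max_gap_frames = 2L), 1)
  expect_identical(length(unique(ts$track_id)), 2L)
})

test_that("short tracks are discarded by the length threshold", {
  det <- rbind(drift_detections(10L),
               data.frame(frame = 1:2, detection_id = 2L, x_px = 200,
                          y_px = 200, area_px = 10L, mean_intensity = 500))
  ts <- link_frames(det, linking_params(max_disp_um = 10,
                                        min_track_len_frames = 3L), 1)
  expect_identical(length(unique(ts$track_id)), 1L)
})

test_that("no detection belongs to two tracks and frames strictly increase", {
  set.seed(11)
  det <- do.call(rbind, lapply(1:15, function(f)
    data.frame(frame = f, detection_id = 1:8,
               x_px = runif(8, 0, 100), y_px = runif(8, 0, 100))))
  ts <- link_frames(det, linking_params(max_disp_um = 30,
                                        min_track_len_frames = 1L), 1)
  expect_identical(nrow(unique(ts[, c("frame", "detection_id")])), nrow(ts))
  for (tr in split(ts, ts$track_id)) expect_true(all(diff(tr$frame) > 0))
  # determinism
  ts2 <- link_frames(det, linking_params(max_disp_um = 30,
                                         min_track_len_frames = 1L), 1)
  expect_identical(as.data.frame(ts), as.data.frame(ts2))
})

test_that("empty detections give an empty track set", {
  ts <- link_frames(data.frame(frame = integer(0), detection_id = integer(0),
                               x_px = numeric(0), y_px = numeric(0)),
                    linking_params(), 1)
  expect_identical(nrow(ts), 0L)
  expect_s3_class(ts, "track_set")
})

test_that("the assignment solver matches exhaustive search on random costs", {
  set.seed(13)
  perms_of <- function(n) {
    if (n == 1) return(list(1L))
    out <- list()
    for (p in perms_of(n - 1L))
      for (i in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
    out
  }
  for (rep in 1:15) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n, 0, 10), n, n)
    asg <- solve_assignment(C)
    best <- min(vapply(perms_of(n),
                       function(p) sum(C[cbind(seq_len(n), p)]), numeric(1)))
    expect_equal(sum(C[cbind(seq_len(n), asg)]), best, tolerance = 1e-9)
  }
})
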