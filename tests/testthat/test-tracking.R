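test_that("feature selection respects the per-cell budget and quality floor", {
  # constant frame: no texture, no points
  expect_equal(nrow(select_features(matrix(128, 120, 160))), 0L)
  expect_error(select_features(matrix(numeric(0), 0, 0)), "empty")
  expect_error(select_features(matrix(1, 10, 10)), "smaller")

  # speckle frame: every cell fully inside the frame yields exactly 8 points
  fr <- speckle_frame(160, 120, seed = 2)
  fs <- select_features(fr)
  expect_equal(attr(fs, "capacity"), (160 %/% 40) * (120 %/% 40) * 8)
  counts <- table(fs$cell)
  expect_true(all(counts == 8))
  expect_equal(nrow(fs), attr(fs, "capacity"))
  # 0-based coordinates inside the frame
  expect_true(all(fs$x >= 0 & fs$x < 160 & fs$y >= 0 & fs$y < 120))
})

test_that("capacity bound holds for arbitrary frame sizes", {
  for (dims in list(c(120, 160), c(95, 130), c(40, 41))) {
    fr <- speckle_frame(dims[2], dims[1], seed = dims[1])
    fs <- select_features(fr)
    expect_lte(nrow(fs), (dims[2] %/% 40) * (dims[1] %/% 40) * 8)
  }
})

test_that("tracking static frames yields (near) zero displacement", {
  fr <- speckle_frame(160, 120, seed = 4)
  frames <- lapply(1:20, function(i) fr)
  traj <- track_window(frames, select_features(fr), fps = 30)
  expect_true(any(traj$valid))
  expect_lt(max(abs(traj$dx[, traj$valid]), abs(traj$dy[, traj$valid])), 0.1)
  expect_equal(unname(traj$dy[1, traj$valid]),
               rep(0, sum(traj$valid)))  # first-frame displacement is zero
})

test_that("tracking recovers a constructed 1 px/frame shift", {
  canvas <- speckle_frame(200, 180, seed = 5)
  n <- 12
  frames <- lapply(seq_len(n), function(i) canvas[i:(i + 119), 1:160])
  # scene content moves UP 1 px/frame in image coords (y decreases)
  traj <- track_window(frames, select_features(frames[[1]]), fps = 30)
  iv <- traj$valid
  expect_gt(sum(iv), 20)
  slopes <- apply(traj$dy[, iv], 2L, function(d) mean(diff(d)))
  expect_equal(unname(slopes), rep(-1, sum(iv)), tolerance = 0.05)
  expect_lt(max(abs(traj$dx[, iv])), 0.2)
})

test_that("tracked breathing motion carries the scene's frequency", {
  vid <- gen_video(small_scene(duration_s = 35, heart_rate = 0,
                               noise_sigma_px = 0, seed = 6))
  frames <- lapply(1:1050, function(i) vid$frames[, , i])
  traj <- track_window(frames, select_features(vid$frames[, , 1]), fps = 30)
  m <- rowMeans(traj$dy[, traj$valid, drop = FALSE])
  expect_equal(fft_peak_hz(m, 30), 0.25, tolerance = 30 / 1050 + 1e-9)
})

test_that("displacement percentile filter keeps the middle half", {
  mk_traj <- function(max_steps) {
    n_f <- 11L
    dx <- matrix(0, n_f, length(max_steps))
    # one big step per point, sized to order the points
    dy <- sapply(max_steps, function(m) c(0, cumsum(c(m, rep(0.01, n_f - 2)))))
    trajectory_matrix(dx, dy, fps = 30)
  }
  t100 <- filter_by_displacement(mk_traj(sample(1:100)))
  expect_equal(sum(t100$valid), 50L)

  t8 <- mk_traj(1:8)
  f8 <- filter_by_displacement(t8)
  expect_equal(which(f8$valid), 3:6)  # linear-interpolation percentiles

  tied <- filter_by_displacement(mk_traj(rep(2, 10)))
  expect_true(all(tied$valid))

  expect_warning(f3 <- filter_by_displacement(mk_traj(c(1, 2, 3))), "skipped")
  expect_true(attr(f3, "filter_skipped"))
})

test_that("percentile filter keeps 40-60 % of continuously distributed points", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(20:120, 1)
    dy <- rbind(0, sapply(runif(n, 0.1, 3), function(m) cumsum(rep(m / 10, 10))))
    traj <- trajectory_matrix(matrix(0, 11, n), dy, fps = 30)
    kept <- sum(filter_by_displacement(traj)$valid) / n
    expect_gte(kept, 0.4)
    expect_lte(kept, 0.6)
  }
})

test_that("movement detection flags spikes and respects the threshold", {
  clean <- gen_trajectories(small_scene(duration_s = 30, heart_rate = 0,
                                        noise_sigma_px = 0), 10)
  expect_false(detect_movement(clean$traj)$moving)

  ev <- gen_trajectories(small_scene(duration_s = 30, heart_rate = 0,
                                     noise_sigma_px = 0,
                                     movement_events = list(c(10, 0.2, 20))), 10)
  mv <- detect_movement(ev$traj)
  expect_true(mv$moving)
  expect_true(all(mv$spike_times_s >= 10 & mv$spike_times_s <= 10.3))
  expect_false(detect_movement(ev$traj, spike_px = Inf)$moving)
})

test_that("windows including and following a movement are labelled moving", {
  starts <- segment_windows(100)
  lab <- movement_labels(40.1, starts)
  expect_equal(starts[lab], 11:70)
})

test_that("window segmentation counts match the sliding-window contract", {
  expect_length(segment_windows(60), 31L)
  expect_equal(segment_windows(30), 0)
  expect_length(segment_windows(29), 0L)
  expect_equal(segment_windows(33.5), 0:3)
})

test_that("tracker re-selects features after a movement spike", {
  p <- small_scene(duration_s = 35, heart_rate = 0, noise_sigma_px = 0,
                   resp_amp_px = 0.5,
                   movement_events = list(c(5, 0.2, 11)), seed = 9)
  vid <- gen_video(p)
  tr <- track_recording(vid$frames, 30)
  expect_gt(length(tr$spike_times_s), 0)
  expect_gt(length(tr$segments), 1)
  expect_true(all(tr$spike_times_s >= 5 & tr$spike_times_s <= 5.4))
  # fresh feature set: later segment starts after the spike frame
  expect_gt(tr$segments[[length(tr$segments)]]$start_frame, 5 * 30)
  # a window straddling the spike has no spanning segment
  expect_null(window_trajectory(tr, 4, window_s = 2))
  w <- window_trajectory(tr, 0, window_s = 4)
  expect_s3_class(w, "trajectory_matrix")
  expect_equal(unname(w$dy[1, w$valid]), rep(0, sum(w$valid)))
})
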