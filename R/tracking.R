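#' Trajectory matrix for one analysis window
#'
#' Displacements of tracked feature points relative to their position in the
#' window's first frame, in pixels (x rightward, y downward, 0-based frame
#' coordinates).
#'
#' @param dx,dy numeric matrices `n_frames x n_points`.
#' @param fps frame rate.
#' @param window_start_s window start time, seconds.
#' @param valid per-point logical; points that failed tracking are `FALSE`.
#' @return Object of class `trajectory_matrix`.
#' @export
trajectory_matrix <- function(dx, dy, fps, window_start_s = 0,
                              valid = rep(TRUE, ncol(dx))) {
  stopifnot(all(dim(dx) == dim(dy)), length(valid) == ncol(dx))
  structure(list(dx = dx, dy = dy, fps = fps,
                 window_start_s = window_start_s, valid = as.logical(valid)),
            class = "trajectory_matrix")
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("<trajectory_matrix> %d points (%d valid), %d frames @ %g fps, t0 = %g s\n",
              ncol(x$dx), sum(x$valid), nrow(x$dx), x$fps, x$window_start_s))
  invisible(x)
}

# Coerce an H x W x n array or list of matrices to a list of matrices.
as_frame_list <- function(frames) {
  if (is.list(frames)) return(frames)
  if (is.array(frames) && length(dim(frames)) == 3L)
    return(lapply(seq_len(dim(frames)[3]), function(i) frames[, , i]))
  stopf("frames must be a list of matrices or an H x W x n array")
}

# 3x3 box sum of a matrix (replicate padded).
box3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0, H + 2L, W + 2L)
  p[2:(H + 1), 2:(W + 1)] <- m
  p[1, 2:(W + 1)] <- m[1, ]; p[H + 2, 2:(W + 1)] <- m[H, ]
  p[, 1] <- p[, 2]; p[, W + 2] <- p[, W + 1]
  p[1:H, 1:W] + p[1:H, 2:(W + 1)] + p[1:H, 3:(W + 2)] +
    p[2:(H + 1), 1:W] + p[2:(H + 1), 2:(W + 1)] + p[2:(H + 1), 3:(W + 2)] +
    p[3:(H + 2), 1:W] + p[3:(H + 2), 2:(W + 1)] + p[3:(H + 2), 3:(W + 2)]
}

# Shi-Tomasi minimum-eigenvalue corner response; zero on a 2 px border.
corner_response <- function(frame) {
  H <- nrow(frame); W <- ncol(frame)
  img <- matrix(as.numeric(frame), H, W)
  Ix <- matrix(0, H, W); Iy <- matrix(0, H, W)
  Ix[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  Iy[2:(H - 1), ] <- (img[3:H, ] - img[1:(H - 2), ]) / 2
  Sxx <- box3(Ix * Ix); Syy <- box3(Iy * Iy); Sxy <- box3(Ix * Iy)
  resp <- ((Sxx + Syy) - sqrt((Sxx - Syy)^2 + 4 * Sxy^2)) / 2
  resp[c(1:2, H - 1, H), ] <- 0
  resp[, c(1:2, W - 1, W)] <- 0
  resp
}

#' Select grid-based feature points
#'
#' Divides the frame into `cell_px` by `cell_px` squares and keeps, per cell,
#' the strongest `points_per_cell` minimum-eigenvalue corner responses above a
#' quality floor (a fraction of the frame's strongest response), with greedy
#' non-maximum suppression so selected points are at least `min_distance`
#' pixels apart. A 640 x 480 frame with 40 px cells and 8 points per cell can
#' yield at most (640/40) x (480/40) x 8 = 1536 points. Untextured cells
#' contribute no points.
#'
#' @param frame numeric/integer matrix (rows = y, cols = x), 8-bit monochrome.
#' @param cell_px grid cell size in pixels (default 40).
#' @param points_per_cell maximum points per cell (default 8).
#' @param quality_level corner quality floor relative to the frame maximum.
#' @param min_distance minimum spacing between selected points, pixels.
#' @return Object of class `feature_set`: data frame with 0-based `x`, `y`
#'   pixel coordinates, `cell` index and `response`; attributes `cell_px`,
#'   `points_per_cell`, `capacity`.
#' @export
select_features <- function(frame, cell_px = 40L, points_per_cell = 8L,
                            quality_level = 0.01, min_distance = 3) {
  if (is.null(dim(frame)) || nrow(frame) == 0L || ncol(frame) == 0L)
    stopf("empty frame")
  H <- nrow(frame); W <- ncol(frame)
  if (H < cell_px || W < cell_px)
    stopf("frame (%d x %d) smaller than one %d px grid cell", W, H, cell_px)
  resp <- corner_response(frame)
  floor_abs <- 1e-8
  thr <- max(quality_level * max(resp), floor_abs)
  nx <- W %/% cell_px; ny <- H %/% cell_px
  out <- vector("list", nx * ny)
  for (cy in seq_len(ny)) {
    rows <- ((cy - 1) * cell_px + 1):(cy * cell_px)
    for (cx in seq_len(nx)) {
      cols <- ((cx - 1) * cell_px + 1):(cx * cell_px)
      sub <- resp[rows, cols]
      cand <- which(sub >= thr, arr.ind = TRUE)
      if (!nrow(cand)) next
      vals <- sub[cand]
      ord <- order(vals, decreasing = TRUE)
      keep_x <- numeric(0); keep_y <- numeric(0); keep_v <- numeric(0)
      for (i in ord) {
        px <- cand[i, 2]; py <- cand[i, 1]
        if (length(keep_x) &&
            any((keep_x - px)^2 + (keep_y - py)^2 < min_distance^2)) next
        keep_x <- c(keep_x, px); keep_y <- c(keep_y, py)
        keep_v <- c(keep_v, vals[i])
        if (length(keep_x) >= points_per_cell) break
      }
      cell_id <- (cy - 1) * nx + cx
      out[[cell_id]] <- data.frame(
        x = (cx - 1) * cell_px + keep_x - 1,   # 0-based frame coords
        y = (cy - 1) * cell_px + keep_y - 1,
        cell = cell_id, response = keep_v
      )
    }
  }
  fs <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                         list(make.row.names = FALSE)))
  if (is.null(fs))
    fs <- data.frame(x = numeric(0), y = numeric(0), cell = integer(0),
                     response = numeric(0))
  structure(fs, class = c("feature_set", "data.frame"),
            cell_px = as.integer(cell_px),
            points_per_cell = as.integer(points_per_cell),
            capacity = nx * ny * as.integer(points_per_cell))
}

# Downsample an image by 2 (2x2 mean).
downsample2 <- function(img) {
  H2 <- nrow(img) %/% 2L; W2 <- ncol(img) %/% 2L
  a <- img[seq_len(2L * H2), seq_len(2L * W2)]
  (a[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)] +
     a[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)] +
     a[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)] +
     a[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)]) / 4
}

# Precomputed Lucas-Kanade template anchored at a reference frame: patches,
# gradients and structure tensors for every point, at the fine scale and at
# one coarse pyramid level.
lk_template <- function(ref, px, py, win_half) {
  H <- nrow(ref); W <- ncol(ref)
  off <- expand.grid(u = -win_half:win_half, v = -win_half:win_half)
  X <- outer(px, off$u, "+"); Y <- outer(py, off$v, "+")
  ok <- px - win_half >= 2 & px + win_half <= W - 1 &
    py - win_half >= 2 & py + win_half <= H - 1
  Tm <- matrix(bilinear_sample(ref, X, Y), nrow = length(px))
  Ix <- matrix(bilinear_sample(ref, X + 0.5, Y) -
                 bilinear_sample(ref, X - 0.5, Y), nrow = length(px))
  Iy <- matrix(bilinear_sample(ref, X, Y + 0.5) -
                 bilinear_sample(ref, X, Y - 0.5), nrow = length(px))
  Sxx <- rowSums(Ix * Ix); Syy <- rowSums(Iy * Iy); Sxy <- rowSums(Ix * Iy)
  det <- Sxx * Syy - Sxy^2
  ok <- ok & det > 1e-4
  list(X = X, Y = Y, T = Tm, Ix = Ix, Iy = Iy,
       Sxx = Sxx, Syy = Syy, Sxy = Sxy, det = det, ok = ok)
}

# One Gauss-Newton LK solve of frame `img` against template `tpl`, starting
# from displacements (dx, dy). Returns updated displacements and residual RMS.
lk_solve <- function(tpl, img, dx, dy, max_iter = 3L, eps = 0.01) {
  for (it in seq_len(max_iter)) {
    E <- matrix(bilinear_sample(img, tpl$X + dx, tpl$Y + dy),
                nrow = nrow(tpl$T)) - tpl$T
    bx <- rowSums(tpl$Ix * E); by <- rowSums(tpl$Iy * E)
    ddx <- -(tpl$Syy * bx - tpl$Sxy * by) / tpl$det
    ddy <- -(tpl$Sxx * by - tpl$Sxy * bx) / tpl$det
    ddx[!tpl$ok] <- 0; ddy[!tpl$ok] <- 0
    dx <- dx + ddx; dy <- dy + ddy
    if (max(abs(ddx), abs(ddy)) < eps) break
  }
  E <- matrix(bilinear_sample(img, tpl$X + dx, tpl$Y + dy),
              nrow = nrow(tpl$T)) - tpl$T
  list(dx = dx, dy = dy, rms = sqrt(rowMeans(E * E)))
}

#' Track feature points across a window of frames
#'
#' Pyramidal sparse Lucas-Kanade tracking anchored at the window's first
#' frame: each point's appearance template and gradient structure tensor are
#' taken from the first frame, and every later frame is registered against it
#' starting from the point's displacement in the previous frame. When the
#' previous frame-to-frame step exceeds ~0.5 px the solve is first run at a
#' half-resolution pyramid level. Points whose template is untextured, leaves
#' the frame, or whose residual exceeds `max_residual` are marked invalid.
#'
#' @param frames list of matrices or `H x W x n` array, 8-bit monochrome.
#' @param features a [select_features()] result.
#' @param fps frame rate.
#' @param window_start_s start time of the window, seconds.
#' @param win_half half-width of the tracking window (patch is
#'   `(2*win_half+1)^2` pixels).
#' @param max_residual tracking-failure threshold on patch residual RMS,
#'   intensity levels.
#' @param stop_on_spike_px optional spike threshold (px/frame) on the median
#'   step; when crossed, tracking stops and the returned trajectory is
#'   truncated at the spike frame, with attribute `spike_frame` set. Used by
#'   [track_recording()] to re-select features after large movements.
#' @return A [trajectory_matrix()]; all-invalid when every point is lost.
#' @export
track_window <- function(frames, features, fps, window_start_s = 0,
                         win_half = 5L, max_residual = 25,
                         stop_on_spike_px = NULL) {
  frames <- as_frame_list(frames)
  n_frames <- length(frames)
  if (n_frames < 2L) stopf("need at least 2 frames")
  if (!nrow(features)) stopf("feature set is empty")
  px <- features$x + 1; py <- features$y + 1   # to 1-based
  n <- length(px)
  ref <- matrix(as.numeric(frames[[1]]), nrow(frames[[1]]), ncol(frames[[1]]))
  tpl <- lk_template(ref, px, py, win_half)
  refc <- downsample2(ref)
  tplc <- lk_template(refc, (px + 1) / 2, (py + 1) / 2, win_half)
  dxm <- matrix(NA_real_, n_frames, n); dym <- matrix(NA_real_, n_frames, n)
  dxm[1, ] <- 0; dym[1, ] <- 0
  dx <- numeric(n); dy <- numeric(n)
  alive <- tpl$ok
  last_step <- 0
  for (i in 2:n_frames) {
    img <- matrix(as.numeric(frames[[i]]), nrow(ref), ncol(ref))
    if (last_step > 0.5) {
      cres <- lk_solve(tplc, downsample2(img), dx / 2, dy / 2,
                       max_iter = 3L, eps = 0.05)
      dx <- 2 * cres$dx; dy <- 2 * cres$dy
    }
    res <- lk_solve(tpl, img, dx, dy)
    prev_dx <- dx; prev_dy <- dy
    dx <- res$dx; dy <- res$dy
    oob <- px + dx - win_half < 2 | px + dx + win_half > ncol(ref) - 1 |
      py + dy - win_half < 2 | py + dy + win_half > nrow(ref) - 1
    n_before <- sum(alive)
    alive <- alive & !oob & res$rms <= max_residual & is.finite(dx) & is.finite(dy)
    lost_frac <- if (n_before) 1 - sum(alive) / n_before else 0
    dxm[i, alive] <- dx[alive]; dym[i, alive] <- dy[alive]
    steps <- sqrt((dx - prev_dx)^2 + (dy - prev_dy)^2)[alive]
    last_step <- if (length(steps)) median(steps) else 0
    # motion too fast to register also announces itself by mass template loss
    if (!is.null(stop_on_spike_px) &&
        (last_step > stop_on_spike_px || lost_frac > 0.5)) {
      dxm <- dxm[seq_len(i), , drop = FALSE]
      dym <- dym[seq_len(i), , drop = FALSE]
      valid <- alive & apply(is.finite(dxm), 2L, all)
      dxm[, !valid] <- NA_real_; dym[, !valid] <- NA_real_
      out <- trajectory_matrix(dxm, dym, fps, window_start_s, valid)
      attr(out, "spike_frame") <- i
      return(out)
    }
  }
  valid <- alive & apply(is.finite(dxm), 2L, all)
  dxm[, !valid] <- NA_real_; dym[, !valid] <- NA_real_
  trajectory_matrix(dxm, dym, fps, window_start_s, valid)
}

#' Sliding analysis windows
#'
#' Half-open windows `[k, k + window_s)` seconds stepped by `step_s`.
#' A 60 s recording at the defaults (30 s windows, 1 s step, i.e. 29 s
#' overlap) yields 31 windows.
#'
#' @param recording_length_s total recording length, seconds.
#' @param window_s window length, seconds.
#' @param step_s step between window starts, seconds.
#' @return numeric vector of window start times (empty when the recording is
#'   shorter than one window).
#' @export
segment_windows <- function(recording_length_s, window_s = 30, step_s = 1) {
  eps <- 1e-9   # absorb float error from sampling rates reconstructed off files
  if (recording_length_s < window_s - eps) return(numeric(0))
  n <- floor((recording_length_s - window_s) / step_s + eps) + 1
  (seq_len(n) - 1) * step_s
}

# Per-point maximum Euclidean frame-to-frame step, NA for invalid points.
max_step_per_point <- function(traj) {
  sx <- diff(traj$dx); sy <- diff(traj$dy)
  m <- sqrt(sx^2 + sy^2)
  out <- apply(m, 2L, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  out[!traj$valid] <- NA_real_
  out
}

#' Filter tracked points by frame-to-frame displacement percentile
#'
#' Computes each valid point's maximum frame-to-frame Euclidean step over the
#' window and invalidates points strictly below the 25th or strictly above
#' the 75th percentile (linear-interpolation percentiles), keeping the middle
#' half. With fewer than 4 valid points the filter is skipped and the result
#' carries attribute `filter_skipped = TRUE`.
#'
#' @param traj a [trajectory_matrix()].
#' @return A `trajectory_matrix` with the tail points' `valid` set `FALSE`.
#' @export
filter_by_displacement <- function(traj) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  m <- max_step_per_point(traj)
  iv <- which(traj$valid & is.finite(m))
  if (length(iv) < 4L) {
    warning("fewer than 4 valid points; displacement filter skipped")
    attr(traj, "filter_skipped") <- TRUE
    return(traj)
  }
  q <- quantile(m[iv], c(0.25, 0.75), type = 7, names = FALSE)
  drop <- iv[m[iv] < q[1] | m[iv] > q[2]]
  traj$valid[drop] <- FALSE
  traj$dx[, drop] <- NA_real_
  traj$dy[, drop] <- NA_real_
  attr(traj, "filter_skipped") <- FALSE
  traj
}

#' Detect large movements inside a window
#'
#' A window is labelled moving when the median across valid points of the
#' frame-to-frame displacement step exceeds `spike_px` at any frame. The
#' default threshold (2 px per frame) is far above the largest breathing or
#' cardiac step the scene model produces (< 0.2 px per frame) but is crossed
#' by whole-body movements.
#'
#' @param traj a [trajectory_matrix()].
#' @param spike_px spike threshold on the median step, pixels per frame.
#' @return list with `moving` (logical) and `spike_times_s` (times of the
#'   offending frames, seconds from recording start).
#' @export
detect_movement <- function(traj, spike_px = 2) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  iv <- which(traj$valid)
  if (!length(iv)) return(list(moving = FALSE, spike_times_s = numeric(0)))
  sx <- diff(traj$dx[, iv, drop = FALSE]); sy <- diff(traj$dy[, iv, drop = FALSE])
  med <- apply(sqrt(sx^2 + sy^2), 1L, median, na.rm = TRUE)
  hit <- which(is.finite(med) & med > spike_px)
  list(moving = length(hit) > 0,
       spike_times_s = traj$window_start_s + hit / traj$fps)
}

#' Movement labels for a set of windows
#'
#' A window is labelled moving when a displacement spike falls inside it, or
#' fell within one window length before its start (the window "following" the
#' movement, taken as the next non-overlapping span rather than every 1 s
#' shift).
#'
#' @param spike_times_s spike times, seconds.
#' @param window_starts window start times, seconds.
#' @param window_s window length, seconds.
#' @return logical vector along `window_starts`.
#' @export
movement_labels <- function(spike_times_s, window_starts, window_s = 30) {
  vapply(window_starts, function(k) {
    any(spike_times_s >= k - window_s & spike_times_s < k + window_s)
  }, logical(1))
}

#' Track a full recording with movement-triggered re-selection
#'
#' Selects features on the first frame, tracks them continuously, and
#' whenever a large displacement spike is detected (median frame-to-frame
#' step above `spike_px`) closes the current tracking segment and samples a
#' fresh feature set from the spike frame, as overnight monitoring requires
#' after position changes. Windows are later cut from the segments; a window
#' that straddles a segment boundary contains the spike and is excluded as
#' moving anyway.
#'
#' @param frames list of matrices or `H x W x n` array.
#' @param fps frame rate.
#' @param cell_px,points_per_cell feature-grid parameters.
#' @param spike_px movement spike threshold, px/frame.
#' @param win_half LK patch half-width.
#' @return Object of class `tracked_recording`: list with `segments` (each
#'   with `start_frame`, `dx`, `dy`, `valid`), `spike_times_s`, `fps`,
#'   `n_frames`.
#' @export
track_recording <- function(frames, fps, cell_px = 40L, points_per_cell = 8L,
                            spike_px = 2, win_half = 5L) {
  frames <- as_frame_list(frames)
  n_frames <- length(frames)
  segments <- list()
  spikes <- numeric(0)
  seg_start <- 1L
  while (seg_start < n_frames) {
    feats <- select_features(frames[[seg_start]], cell_px, points_per_cell)
    if (!nrow(feats)) break
    traj <- track_window(frames[seg_start:n_frames], feats, fps,
                         window_start_s = (seg_start - 1) / fps,
                         win_half = win_half, stop_on_spike_px = spike_px)
    segments[[length(segments) + 1L]] <- list(
      start_frame = seg_start, dx = traj$dx, dy = traj$dy,
      valid = traj$valid)
    spike_frame <- attr(traj, "spike_frame")
    if (is.null(spike_frame)) break
    spikes <- c(spikes, traj$window_start_s + (spike_frame - 1) / fps)
    seg_start <- seg_start + spike_frame - 1L
  }
  structure(list(segments = segments, spike_times_s = spikes, fps = fps,
                 n_frames = n_frames),
            class = "tracked_recording")
}

#' Extract one window's trajectories from a tracked recording
#'
#' Re-zeroes displacements at the window's first frame. Returns `NULL` when
#' no tracking segment spans the whole window (the spike that split the
#' segments lies inside the window, which is excluded as moving).
#'
#' @param tracked a [track_recording()] result.
#' @param start_s window start, seconds.
#' @param window_s window length, seconds.
#' @return A [trajectory_matrix()] or `NULL`.
#' @export
window_trajectory <- function(tracked, start_s, window_s = 30) {
  f0 <- round(start_s * tracked$fps) + 1L
  f1 <- f0 + round(window_s * tracked$fps) - 1L
  for (seg in tracked$segments) {
    s0 <- seg$start_frame; s1 <- seg$start_frame + nrow(seg$dx) - 1L
    if (f0 >= s0 && f1 <= s1) {
      rows <- (f0 - s0 + 1L):(f1 - s0 + 1L)
      dx <- seg$dx[rows, , drop = FALSE]; dy <- seg$dy[rows, , drop = FALSE]
      valid <- seg$valid & !is.na(dx[1, ]) & !is.na(dx[nrow(dx), ])
      dx <- sweep(dx, 2L, dx[1L, ]); dy <- sweep(dy, 2L, dy[1L, ])
      return(trajectory_matrix(dx, dy, tracked$fps, start_s, valid))
    }
  }
  NULL
}
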