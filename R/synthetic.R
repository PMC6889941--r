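#' Synthetic sleep-scene parameters
#'
#' Bundles the parameters of the synthetic recording generator. The generator
#' emulates what the estimation pipeline consumes: a textured torso whose
#' surface moves with breathing (slow, ~1 px sinusoid), with the much smaller
#' ballistocardiographic pulse (sub-pixel, harmonically rich), with broadband
#' displacement noise, and with occasional large whole-body movements.
#'
#' `resp_rate` and `heart_rate` may be scalars or per-second vectors (one
#' value per second of recording) to simulate drifting rates. `heart_rate = 0`
#' disables the cardiac component entirely.
#'
#' @param duration_s recording length in seconds (> 0).
#' @param fps frame rate, frames/s.
#' @param width,height frame size in pixels.
#' @param resp_rate breathing rate, br/min, in \[1, 100\].
#' @param heart_rate heart rate, bpm, 0 or in \[20, 140\].
#' @param resp_amp_px breathing displacement amplitude, pixels.
#' @param cardiac_amp_px cardiac displacement amplitude, pixels.
#' @param cardiac_harmonics number of harmonics above the cardiac fundamental
#'   (amplitudes halve with each order, giving the pulse-train-like spectrum
#'   the harmonic-periodicity score relies on).
#' @param noise_sigma_px standard deviation of white displacement noise,
#'   pixels.
#' @param movement_events list of `c(start_s, duration_s, magnitude_px)`
#'   triples; each is a smooth persistent ramp of the whole torso.
#' @param texture_seed integer seed for the speckle texture and all generator
#'   noise.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(duration_s, fps = 30, width = 640, height = 480,
                         resp_rate = 15, heart_rate = 72,
                         resp_amp_px = 1.5, cardiac_amp_px = 0.25,
                         cardiac_harmonics = 2L, noise_sigma_px = 0.05,
                         movement_events = list(), texture_seed = 1L) {
  if (duration_s <= 0 || fps <= 0) stopf("duration_s and fps must be positive")
  if (any(resp_rate < 1 | resp_rate > 100))
    stopf("resp_rate must lie in [1, 100] br/min")
  if (any(heart_rate != 0 & (heart_rate < 20 | heart_rate > 140)))
    stopf("heart_rate must be 0 or in [20, 140] bpm")
  if (resp_amp_px < 0 || cardiac_amp_px < 0 || noise_sigma_px < 0)
    stopf("amplitudes must be non-negative")
  structure(list(
    duration_s = duration_s, fps = fps, width = as.integer(width),
    height = as.integer(height), resp_rate = resp_rate,
    heart_rate = heart_rate, resp_amp_px = resp_amp_px,
    cardiac_amp_px = cardiac_amp_px,
    cardiac_harmonics = as.integer(cardiac_harmonics),
    noise_sigma_px = noise_sigma_px, movement_events = movement_events,
    texture_seed = as.integer(texture_seed)
  ), class = "scene_params")
}

# Per-frame instantaneous rate (Hz) from a scalar or per-second series.
rate_per_frame <- function(rate, n_frames, fps) {
  t <- (seq_len(n_frames) - 1) / fps
  if (length(rate) == 1L) rep(rate / 60, n_frames)
  else rate[pmin(floor(t) + 1L, length(rate))] / 60
}

# Cumulative phase (cycles) of an instantaneous frequency series.
phase_cycles <- function(f_hz, fps) cumsum(f_hz) / fps - f_hz[1] / fps

# Smoothstep movement ramp: sum over events, persists after each event.
movement_displacement <- function(events, t) {
  d <- numeric(length(t))
  for (ev in events) {
    u <- clamp((t - ev[1]) / max(ev[2], 1e-9), 0, 1)
    d <- d + ev[3] * (3 * u^2 - 2 * u^3)
  }
  d
}

# Common scene motion components evaluated per frame.
scene_motion <- function(params, n_frames) {
  t <- (seq_len(n_frames) - 1) / params$fps
  fr <- rate_per_frame(params$resp_rate, n_frames, params$fps)
  resp <- params$resp_amp_px * sin(2 * pi * phase_cycles(fr, params$fps))
  if (all(params$heart_rate == 0) || params$cardiac_amp_px == 0) {
    card <- numeric(n_frames)
    r_peaks <- numeric(0)
  } else {
    fc <- rate_per_frame(params$heart_rate, n_frames, params$fps)
    phi <- phase_cycles(fc, params$fps)
    k <- seq_len(1L + params$cardiac_harmonics)
    wts <- 0.5^(k - 1)
    card <- numeric(n_frames)
    for (i in seq_along(k)) card <- card + wts[i] * cos(2 * pi * k[i] * phi)
    card <- params$cardiac_amp_px * card / sum(wts)
    # R-peaks where the cardiac phase crosses whole cycles
    cross <- which(diff(floor(phi)) == 1L)
    r_peaks <- vapply(cross, function(i) {
      target <- floor(phi[i + 1])
      t[i] + (target - phi[i]) / (phi[i + 1] - phi[i]) / params$fps
    }, numeric(1))
  }
  mov <- movement_displacement(params$movement_events, t)
  list(t = t, resp = resp, card = card, mov = mov, r_peak_times_s = r_peaks)
}

# Ground-truth manifest shared by all generator outputs.
build_manifest <- function(params, r_peaks) {
  n_sec <- ceiling(params$duration_s)
  per_sec <- function(rate) {
    if (length(rate) == 1L) rep(rate, n_sec)
    else rate[pmin(seq_len(n_sec), length(rate))]
  }
  list(
    resp_rate_series = per_sec(params$resp_rate),
    heart_rate_series = per_sec(params$heart_rate),
    movement_intervals = lapply(params$movement_events,
                                function(ev) c(ev[1], min(ev[1] + ev[2], params$duration_s))),
    r_peak_times_s = r_peaks
  )
}

#' Generate synthetic feature-point trajectories
#'
#' Unit-level stand-in for the output of the tracking stage: each point's
#' vertical displacement is the breathing sinusoid plus the cardiac pulse
#' train plus Gaussian noise, with smooth-ramp movement events; horizontal
#' displacement carries noise and a fraction of the movement. Per-point gain
#' factors (drawn once from the texture seed) vary the breathing and cardiac
#' amplitudes across points, as posture does across the torso.
#'
#' @param params a [scene_params()] object.
#' @param n_points number of tracked points (>= 1).
#' @return list with `traj` (a `trajectory_matrix`) and `manifest` (ground
#'   truth: per-second rate series, movement intervals, R-peak times).
#' @export
gen_trajectories <- function(params, n_points = 64L) {
  stopifnot(inherits(params, "scene_params"))
  if (n_points < 1L) stopf("n_points must be >= 1")
  n_frames <- round(params$duration_s * params$fps)
  m <- scene_motion(params, n_frames)
  with_seed(params$texture_seed, {
    g_resp <- runif(n_points, 0.7, 1.3)
    g_card <- runif(n_points, 0.5, 1.5)
    dy <- outer(m$resp, g_resp) + outer(m$card, g_card) + m$mov +
      matrix(rnorm(n_frames * n_points, sd = params$noise_sigma_px),
             n_frames, n_points)
    dx <- 0.2 * m$mov +
      matrix(rnorm(n_frames * n_points, sd = params$noise_sigma_px),
             n_frames, n_points)
  })
  dy <- sweep(dy, 2L, dy[1L, ])
  dx <- sweep(dx, 2L, dx[1L, ])
  list(traj = trajectory_matrix(dx, dy, params$fps, window_start_s = 0),
       manifest = build_manifest(params, m$r_peak_times_s))
}

# Speckle texture canvas with the torso ellipse cut out of a dark background.
# `margin` pads the canvas so shifted sampling never leaves it.
torso_canvas <- function(params, margin) {
  H <- params$height; W <- params$width
  ch <- H + 2L * margin; cw <- W + 2L * margin
  tex <- with_seed(params$texture_seed,
                   matrix(runif(ch * cw, 40, 255), ch, cw))
  cx <- W / 2 + margin; cy <- H / 2 + margin
  rx <- 0.35 * W; ry <- 0.40 * H
  xs <- matrix(seq_len(cw), ch, cw, byrow = TRUE)
  ys <- matrix(seq_len(ch), ch, cw)
  inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  canvas <- matrix(10, ch, cw)
  canvas[inside] <- tex[inside]
  # camera point-spread: soften the speckle so sub-pixel shifts change
  # appearance smoothly, as optics do (pixel-iid texture would alias)
  canvas <- box3(canvas) / 9
  list(canvas = canvas, margin = margin, cx = cx, cy = cy, rx = rx, ry = ry)
}

# Bilinear sample of matrix img at (x, y) vectors (1-based, col=x, row=y).
bilinear_sample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- clamp(x, 1, W - 1e-6); y <- clamp(y, 1, H - 1e-6)
  x0 <- pmin(floor(x), W - 1L); y0 <- pmin(floor(y), H - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + (x0 - 1) * H
  v00 <- img[i00];        v10 <- img[i00 + H]
  v01 <- img[i00 + 1];    v11 <- img[i00 + H + 1]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Generate a synthetic near-infrared video
#'
#' Renders a high-contrast speckle-textured elliptical torso over a dark
#' background and translates it by the scene's displacement law. Breathing
#' displacement grows towards the lower torso (abdomen) and cardiac
#' displacement towards one side, so that the two sources are spatially as
#' well as spectrally distinct. Frames are 8-bit monochrome.
#'
#' @param params a [scene_params()] object; `width` and `height` must be at
#'   least one 40 px grid cell.
#' @return list with `frames` (integer array `height x width x n_frames`,
#'   values 0-255), `fps`, and `manifest` as in [gen_trajectories()].
#' @export
gen_video <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  if (params$width < 40L || params$height < 40L)
    stopf("frame must be at least one 40 px grid cell")
  n_frames <- round(params$duration_s * params$fps)
  m <- scene_motion(params, n_frames)
  noise <- if (params$noise_sigma_px > 0) {
    with_seed(params$texture_seed + 1L,
              rnorm(n_frames, sd = params$noise_sigma_px))
  } else numeric(n_frames)
  # spatial gain peak values (see per-pixel gains below)
  max_dy <- max(abs(1.4 * m$resp) + abs(1.5 * m$card) + abs(m$mov) + abs(noise))
  max_dx <- max(abs(0.2 * m$mov))
  margin_x <- params$width / 2 - 0.35 * params$width
  margin_y <- params$height / 2 - 0.40 * params$height
  if (max_dy > margin_y || max_dx > margin_x)
    stopf("motion amplitude (%.1f px) exceeds the torso-to-border margin",
          max(max_dy, max_dx))
  tc <- torso_canvas(params, margin = ceiling(max(max_dy, max_dx)) + 2L)
  H <- params$height; W <- params$width
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  # breathing stronger toward the abdomen (larger y), cardiac toward one side
  g_resp <- clamp(0.6 + 0.8 * (ys - (tc$cy - tc$margin - tc$ry)) / (2 * tc$ry), 0.6, 1.4)
  g_card <- clamp(0.5 + 1.0 * ((tc$cx - tc$margin + tc$rx) - xs) / (2 * tc$rx), 0.5, 1.5)
  frames <- array(0L, dim = c(H, W, n_frames))
  for (i in seq_len(n_frames)) {
    dy <- g_resp * m$resp[i] + g_card * m$card[i] + m$mov[i] + noise[i]
    dx <- 0.2 * m$mov[i]
    v <- bilinear_sample(tc$canvas, xs - dx + tc$margin, ys - dy + tc$margin)
    frames[, , i] <- as.integer(clamp(round(v), 0, 255))
  }
  list(frames = frames, fps = params$fps,
       manifest = build_manifest(params, m$r_peak_times_s))
}

#' Generate a synthetic single-lead ECG
#'
#' One Gaussian-shaped R-wave per beat; the beat-to-beat interval follows the
#' instantaneous heart-rate series with optional multiplicative jitter.
#'
#' @param heart_rate_series bpm, one value per second; all in \[20, 140\].
#' @param fs sampling rate, Hz (default 250).
#' @param rr_jitter fractional standard deviation of the RR interval.
#' @param r_width_s Gaussian R-wave standard deviation in seconds.
#' @param seed RNG seed for the jitter.
#' @return list with `signal`, `t` (seconds), `fs`, `r_peak_times_s`.
#' @export
gen_ecg <- function(heart_rate_series, fs = 250, rr_jitter = 0,
                    r_width_s = 0.012, seed = 1L) {
  if (any(heart_rate_series < 20 | heart_rate_series > 140))
    stopf("heart rates must lie in [20, 140] bpm")
  if (fs * r_width_s < 2)
    stopf("sampling rate %.0f Hz too low to resolve a %.0f ms R-wave",
          fs, 1000 * r_width_s)
  duration <- length(heart_rate_series)
  if (duration == 0L)
    return(list(signal = numeric(0), t = numeric(0), fs = fs,
                r_peak_times_s = numeric(0)))
  peaks <- with_seed(seed, {
    tb <- 60 / heart_rate_series[1] / 2   # first beat half a period in
    out <- numeric(0)
    while (tb < duration) {
      out <- c(out, tb)
      rate <- heart_rate_series[min(floor(tb) + 1L, duration)]
      iv <- 60 / rate * (1 + if (rr_jitter > 0) rnorm(1, 0, rr_jitter) else 0)
      tb <- tb + max(iv, 0.25)
    }
    out
  })
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  hw <- ceiling(5 * r_width_s * fs)
  for (tb in peaks) {
    c0 <- round(tb * fs) + 1L
    idx <- max(1L, c0 - hw):min(n, c0 + hw)
    sig[idx] <- sig[idx] + exp(-(t[idx] - tb)^2 / (2 * r_width_s^2))
  }
  list(signal = sig, t = t, fs = fs, r_peak_times_s = peaks)
}

#' Generate a synthetic respiratory inductance plethysmography trace
#'
#' Phase-continuous sinusoid following the instantaneous breathing rate.
#'
#' @param resp_rate_series br/min, one value per second; all in \[1, 100\].
#' @param fs sampling rate, Hz (default 25).
#' @return list with `signal`, `t` (seconds), `fs`.
#' @export
gen_rip <- function(resp_rate_series, fs = 25) {
  if (any(resp_rate_series < 1 | resp_rate_series > 100))
    stopf("respiratory rates must lie in [1, 100] br/min")
  duration <- length(resp_rate_series)
  if (duration == 0L)
    return(list(signal = numeric(0), t = numeric(0), fs = fs))
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  f <- resp_rate_series[pmin(floor(t) + 1L, duration)] / 60
  list(signal = sin(2 * pi * phase_cycles(f, fs)), t = t, fs = fs)
}

#' Simulate a complete synthetic recording
#'
#' Convenience bundle: video frames plus paired ECG and RIP traces that share
#' the scene's ground-truth rate series.
#'
#' @param params a [scene_params()] object.
#' @param rr_jitter fractional RR-interval jitter passed to [gen_ecg()].
#' @return list with `frames`, `fps`, `manifest`, `ecg`, `rip`.
#' @export
simulate_recording <- function(params, rr_jitter = 0.02) {
  vid <- gen_video(params)
  ecg <- if (all(params$heart_rate == 0)) NULL else
    gen_ecg(vid$manifest$heart_rate_series, rr_jitter = rr_jitter,
            seed = params$texture_seed + 2L)
  rip <- gen_rip(vid$manifest$resp_rate_series)
  c(vid, list(ecg = ecg, rip = rip))
}
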