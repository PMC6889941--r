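# Shared fixture builders. Everything is generated in code at test time;
# small frame sizes keep the suite fast while preserving the 40 px grid.

small_scene <- function(duration_s = 35, resp_rate = 15, heart_rate = 72,
                        noise_sigma_px = 0.05, movement_events = list(),
                        seed = 1L, width = 160L, height = 120L, ...) {
  scene_params(duration_s, fps = 30, width = width, height = height,
               resp_rate = resp_rate, heart_rate = heart_rate,
               noise_sigma_px = noise_sigma_px,
               movement_events = movement_events, texture_seed = seed, ...)
}

# Fully textured speckle frame (corners everywhere).
speckle_frame <- function(width, height, seed = 1L) {
  set.seed(seed)
  matrix(round(runif(width * height, 0, 255)), height, width)
}

# Direct FFT oracle: dominant frequency of a signal by plain argmax of the
# unpadded periodogram (independent of amplitude_spectrum).
fft_peak_hz <- function(x, fs) {
  n <- length(x)
  a <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]
  which.max(a[-1]) * fs / n   # skip DC
}

# Build a tracked_recording from generated trajectories, replicating the
# tracker's online spike-splitting so the window plumbing can be exercised
# without rendering video.
tracked_from_traj <- function(gen, fps = 30, spike_px = 2) {
  dx <- gen$traj$dx; dy <- gen$traj$dy
  n <- nrow(dx)
  med <- apply(sqrt(diff(dx)^2 + diff(dy)^2), 1L, median, na.rm = TRUE)
  segments <- list(); spikes <- numeric(0)
  start <- 1L
  repeat {
    hits <- which(med > spike_px)
    hits <- hits[hits >= start]
    if (!length(hits)) {
      segments[[length(segments) + 1L]] <- list(
        start_frame = start,
        dx = dx[start:n, , drop = FALSE], dy = dy[start:n, , drop = FALSE],
        valid = gen$traj$valid)
      break
    }
    j <- hits[1]                       # step between frames j and j + 1
    segments[[length(segments) + 1L]] <- list(
      start_frame = start,
      dx = dx[start:(j + 1L), , drop = FALSE],
      dy = dy[start:(j + 1L), , drop = FALSE],
      valid = gen$traj$valid)
    spikes <- c(spikes, j / fps)
    start <- j + 1L
    if (start >= n) break
  }
  structure(list(segments = segments, spike_times_s = spikes, fps = fps,
                 n_frames = n),
            class = "tracked_recording")
}
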