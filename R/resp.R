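# Stack a trajectory's valid per-point displacement series (vertical then
# horizontal) into an n_frames x n_signals matrix, mean-removed per column.
trajectory_signals <- function(traj) {
  iv <- which(traj$valid)
  if (!length(iv)) return(NULL)
  S <- cbind(traj$dy[, iv, drop = FALSE], traj$dx[, iv, drop = FALSE])
  sweep(S, 2L, colMeans(S))
}

invalid_estimate <- function(window_start_s, reason) {
  rate_series(window_start_s, rate = NA_real_, quality = NA_real_,
              valid = FALSE, reason = reason)
}

#' Respiratory rate from one window of trajectories
#'
#' Principal component analysis of the (displacement-filtered) point
#' trajectories; both displacement coordinates enter as separate signals
#' since the breathing direction depends on posture. Among the first
#' `n_pc` components, the one with the highest fraction of spectral amplitude
#' inside the breathing band is selected (ties to the lower index); the rate
#' is 60 times the parabolic-refined dominant peak of that component, and the
#' quality is the peak's harmonic periodicity.
#'
#' @param traj a [trajectory_matrix()], already filtered by
#'   [filter_by_displacement()] and not labelled moving.
#' @param band breathing band in Hz; the default 0.1-1.0 Hz is 6-60 br/min.
#' @param n_pc number of leading principal components searched.
#' @param n_fft FFT length for the window spectra.
#' @return One-row [rate_series()]; invalid with reason `no_features` when no
#'   valid points remain, `out_of_band` when no spectral peak lies in band.
#' @export
estimate_rr_window <- function(traj, band = c(0.1, 1.0), n_pc = 5L,
                               n_fft = 8192L) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  S <- trajectory_signals(traj)
  if (is.null(S)) return(invalid_estimate(traj$window_start_s, "no_features"))
  pc <- prcomp(S, center = FALSE, scale. = FALSE)
  k <- min(n_pc, ncol(pc$x))
  specs <- lapply(seq_len(k), function(i)
    amplitude_spectrum(pc$x[, i], traj$fps, n_fft))
  in_band_frac <- vapply(specs, function(sp) {
    tot <- sum(sp$amps[sp$freqs > 0])
    if (tot <= 0) return(0)
    sum(sp$amps[sp$freqs >= band[1] & sp$freqs <= band[2]]) / tot
  }, numeric(1))
  if (all(in_band_frac <= 0))
    return(invalid_estimate(traj$window_start_s, "out_of_band"))
  best <- which.max(in_band_frac)   # ties resolve to the lower index
  pk <- spectral_peaks(specs[[best]], band, max_n = 1L)
  if (!nrow(pk)) return(invalid_estimate(traj$window_start_s, "out_of_band"))
  hp <- harmonic_periodicity(specs[[best]], pk$freq[1])$hp
  rate_series(traj$window_start_s, rate = 60 * pk$freq[1], quality = hp,
              valid = TRUE, reason = "ok")
}

# Shared window loop over a tracked recording; `estimator` maps a trajectory
# (and the window's moving label) to a one-row rate_series.
run_windows <- function(tracked, window_s, step_s, spike_px, estimator) {
  duration_s <- tracked$n_frames / tracked$fps
  starts <- segment_windows(duration_s, window_s, step_s)
  if (!length(starts)) {
    out <- rate_series(numeric(0))
    return(out)
  }
  moving <- movement_labels(tracked$spike_times_s, starts, window_s)
  rows <- lapply(seq_along(starts), function(i) {
    if (moving[i]) return(invalid_estimate(starts[i], "moving"))
    traj <- window_trajectory(tracked, starts[i], window_s)
    if (is.null(traj) || !any(traj$valid))
      return(invalid_estimate(starts[i], "no_features"))
    traj <- suppressWarnings(filter_by_displacement(traj))
    estimator(traj)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Respiratory-rate series for a tracked recording
#'
#' Applies [estimate_rr_window()] on sliding windows (default 30 s with 29 s
#' overlap). Windows overlapping or immediately following a movement spike
#' are emitted invalid with reason `moving`.
#'
#' @param tracked a [track_recording()] result.
#' @param config a [pipeline_config()]; supplies window length, step, bands
#'   and FFT size.
#' @return A [rate_series()] with one row per window.
#' @export
run_rr <- function(tracked, config = pipeline_config()) {
  stopifnot(inherits(tracked, "tracked_recording"))
  band <- config$rr_band_brmin / 60
  run_windows(tracked, config$window_s, config$step_s, config$spike_px,
              function(traj) estimate_rr_window(traj, band = band,
                                                n_fft = config$n_fft))
}
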