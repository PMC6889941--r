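#' Heart-rate estimator configuration
#'
#' @param hr_band heart-rate search band in bpm; default 20-140, the upper
#'   end intentionally above realistic sleeping values for robustness.
#' @param prior_bpm "reasonable heart rate" prior; must equal the band
#'   midpoint (80 bpm for the default band).
#' @param max_candidates candidate frequencies scored per window (default 12).
#' @param n_ica number of independent components unmixed per window.
#' @param n_fft FFT length for window spectra.
#' @param ica_seed RNG seed for the ICA initialisation.
#' @return list of class `hr_config`.
#' @export
hr_config <- function(hr_band = c(20, 140), prior_bpm = mean(hr_band),
                      max_candidates = 12L, n_ica = 8L, n_fft = 8192L,
                      ica_seed = 1L) {
  if (!isTRUE(all.equal(prior_bpm, mean(hr_band))))
    stopf("prior_bpm (%g) must be the midpoint of hr_band (%g)",
          prior_bpm, mean(hr_band))
  structure(list(hr_band = hr_band, prior_bpm = prior_bpm,
                 max_candidates = as.integer(max_candidates),
                 n_ica = as.integer(n_ica), n_fft = as.integer(n_fft),
                 ica_seed = as.integer(ica_seed)),
            class = "hr_config")
}

#' Score heart-rate candidate frequencies
#'
#' Each candidate frequency `f` (bpm) with harmonic periodicity `hp` is
#' scored as
#'
#' \deqn{S = 2 s_1 + (1 - s_2) + (1 - s_3)}
#'
#' where \eqn{s_1} is the candidate's harmonic periodicity divided by the sum
#' over all candidates, \eqn{s_2} the absolute difference from the previous
#' window's estimate normalized by the band width and clamped to \[0, 1\],
#' and \eqn{s_3} the same for the distance from the prior rate (80 bpm, the
#' band midpoint). With no previous estimate, \eqn{s_2} is set equal to
#' \eqn{s_3}. When all periodicities are zero, \eqn{s_1} is uniform.
#'
#' @param cands data frame with columns `f` (bpm) and `hp`; 1 to
#'   `max_candidates` rows, all `f` inside the band.
#' @param prev_bpm previous window's estimate, or `NULL`.
#' @param cfg an [hr_config()].
#' @return data frame with columns `f, s1, s2, s3, S` plus attribute
#'   `winner` (row index of the selected candidate: highest `S`, ties broken
#'   toward the candidate closest to `prev_bpm` — or to the prior when there
#'   is none — then toward the lowest frequency).
#' @export
score_candidates <- function(cands, prev_bpm = NULL, cfg = hr_config()) {
  if (!nrow(cands)) stopf("no candidates to score")
  if (nrow(cands) > cfg$max_candidates)
    stopf("more than %d candidates", cfg$max_candidates)
  if (any(cands$f < cfg$hr_band[1] | cands$f > cfg$hr_band[2]))
    stopf("candidates outside the heart-rate band")
  width <- diff(cfg$hr_band)
  hp_sum <- sum(cands$hp)
  s1 <- if (hp_sum > 0) cands$hp / hp_sum else rep(1 / nrow(cands), nrow(cands))
  s3 <- clamp(abs(cfg$prior_bpm - cands$f) / width, 0, 1)
  s2 <- if (is.null(prev_bpm)) s3 else clamp(abs(prev_bpm - cands$f) / width, 0, 1)
  S <- 2 * s1 + (1 - s2) + (1 - s3)
  out <- data.frame(f = cands$f, s1 = s1, s2 = s2, s3 = s3, S = S)
  anchor <- if (is.null(prev_bpm)) cfg$prior_bpm else prev_bpm
  ord <- order(-S, abs(out$f - anchor), out$f)
  attr(out, "winner") <- ord[1]
  out
}

#' Heart rate from one window of trajectories
#'
#' The filtered trajectories are reduced to `n_ica` dimensions by PCA
#' whitening and unmixed with (seeded) FastICA. Every component's amplitude
#' spectrum contributes its band-limited peaks; candidates are pooled over
#' components, ranked by harmonic periodicity, truncated to the top
#' `max_candidates`, and scored with [score_candidates()]. The winner's
#' frequency is the estimate; its harmonic periodicity is the quality.
#'
#' @param traj a filtered, non-moving [trajectory_matrix()].
#' @param prev_bpm previous valid estimate (bpm) or `NULL`.
#' @param cfg an [hr_config()].
#' @return One-row [rate_series()].
#' @export
estimate_hr_window <- function(traj, prev_bpm = NULL, cfg = hr_config()) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  S <- trajectory_signals(traj)
  if (is.null(S)) return(invalid_estimate(traj$window_start_s, "no_features"))
  src <- fast_ica(S, cfg$n_ica, seed = cfg$ica_seed)
  if (is.null(src)) return(invalid_estimate(traj$window_start_s, "no_features"))
  band_hz <- cfg$hr_band / 60
  cands <- do.call(rbind, lapply(seq_len(ncol(src)), function(i) {
    sp <- amplitude_spectrum(src[, i], traj$fps, cfg$n_fft)
    pk <- spectral_peaks(sp, band_hz, max_n = cfg$max_candidates)
    if (!nrow(pk)) return(NULL)
    hp <- vapply(pk$freq, function(f) harmonic_periodicity(sp, f)$hp, numeric(1))
    data.frame(f = 60 * pk$freq, hp = hp)
  }))
  cands <- cands[is.finite(cands$hp), , drop = FALSE]
  if (is.null(cands) || !nrow(cands))
    return(invalid_estimate(traj$window_start_s, "out_of_band"))
  cands <- head(cands[order(cands$hp, decreasing = TRUE), , drop = FALSE],
                cfg$max_candidates)
  sc <- score_candidates(cands, prev_bpm, cfg)
  w <- attr(sc, "winner")
  rate_series(traj$window_start_s, rate = sc$f[w], quality = cands$hp[w],
              valid = TRUE, reason = "ok")
}

#' Heart-rate series for a tracked recording
#'
#' Applies [estimate_hr_window()] on sliding windows. The previous-window
#' estimate chains across consecutive valid windows and resets after any
#' moving window, so a position change cannot drag the continuity term
#' across the gap.
#'
#' @param tracked a [track_recording()] result.
#' @param config a [pipeline_config()].
#' @return A [rate_series()] with one row per window.
#' @export
run_hr <- function(tracked, config = pipeline_config()) {
  stopifnot(inherits(tracked, "tracked_recording"))
  cfg <- hr_config(hr_band = config$hr_band_bpm, prior_bpm = config$prior_bpm,
                   max_candidates = config$max_candidates,
                   n_ica = config$n_ica, n_fft = config$n_fft,
                   ica_seed = config$seed)
  duration_s <- tracked$n_frames / tracked$fps
  starts <- segment_windows(duration_s, config$window_s, config$step_s)
  if (!length(starts)) return(rate_series(numeric(0)))
  moving <- movement_labels(tracked$spike_times_s, starts, config$window_s)
  prev <- NULL
  rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    if (moving[i]) {
      rows[[i]] <- invalid_estimate(starts[i], "moving")
      prev <- NULL
      next
    }
    traj <- window_trajectory(tracked, starts[i], config$window_s)
    if (is.null(traj) || !any(traj$valid)) {
      rows[[i]] <- invalid_estimate(starts[i], "no_features")
      next
    }
    traj <- suppressWarnings(filter_by_displacement(traj))
    est <- estimate_hr_window(traj, prev, cfg)
    if (est$valid) prev <- est$rate
    rows[[i]] <- est
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rate_series", "data.frame")
  out
}
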