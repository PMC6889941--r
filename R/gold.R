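#' Detect R-peaks in a single-lead ECG
#'
#' Band-limits the signal to the QRS band (5-30 Hz Butterworth, zero-phase),
#' thresholds at half the rolling 2 s maximum, finds local maxima at least
#' `refractory_s` apart, and refines each peak to sub-sample precision by
#' fitting a parabola through the three samples around it.
#'
#' @param ecg numeric vector of ECG samples.
#' @param fs sampling rate, Hz (default 250).
#' @param refractory_s minimum separation between peaks, seconds.
#' @return Object of class `r_peak_series`: list with strictly increasing
#'   `peak_times_s` and `fs`. Empty on a flat signal.
#' @export
detect_r_peaks <- function(ecg, fs = 250, refractory_s = 0.25) {
  if (length(ecg) < 2 * fs) stopf("need at least 2 s of ECG")
  if (sd(ecg) < 1e-12)
    return(structure(list(peak_times_s = numeric(0), fs = fs),
                     class = "r_peak_series"))
  bf <- signal::butter(2, c(5, 30) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, ecg))
  w <- round(2 * fs)
  roll_max <- zoo::rollapply(zoo::zoo(x), width = w, FUN = max,
                             partial = TRUE, align = "center")
  thr <- 0.5 * as.numeric(roll_max)
  n <- length(x)
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] > thr[i] & x[i] > 0]
  if (!length(cand))
    return(structure(list(peak_times_s = numeric(0), fs = fs),
                     class = "r_peak_series"))
  # enforce refractory period, keeping the larger peak
  keep <- integer(0)
  min_gap <- round(refractory_s * fs)
  for (c0 in cand) {
    if (length(keep) && c0 - keep[length(keep)] < min_gap) {
      if (x[c0] > x[keep[length(keep)]]) keep[length(keep)] <- c0
    } else keep <- c(keep, c0)
  }
  t_ref <- vapply(keep, function(k) {
    (k - 1 + parabolic_offset(x[k - 1], x[k], x[k + 1])) / fs
  }, numeric(1))
  structure(list(peak_times_s = t_ref, fs = fs), class = "r_peak_series")
}

#' Instantaneous heart rate from R-peaks
#'
#' At each beat from the sixth onward, the rate is 60 divided by the mean of
#' the five preceding R-R intervals, time-stamped at that beat.
#'
#' @param peaks an `r_peak_series` (or list with `peak_times_s`).
#' @param n_avg number of consecutive R-R intervals averaged (default 5).
#' @return data frame with `t_s` and `bpm`; empty with fewer than
#'   `n_avg + 1` peaks.
#' @export
instantaneous_hr <- function(peaks, n_avg = 5L) {
  pt <- peaks$peak_times_s
  if (length(pt) < n_avg + 1L)
    return(data.frame(t_s = numeric(0), bpm = numeric(0)))
  rr <- diff(pt)
  mean_rr <- as.numeric(stats::filter(rr, rep(1 / n_avg, n_avg), sides = 1))
  idx <- n_avg:length(rr)
  data.frame(t_s = pt[idx + 1L], bpm = 60 / mean_rr[idx])
}

#' Window-averaged gold-standard heart rate
#'
#' Mean of the instantaneous heart-rate values whose timestamps fall in each
#' sliding window (default 30 s windows, 1 s apart); windows containing no
#' beat are invalid.
#'
#' @param inst data frame from [instantaneous_hr()].
#' @param duration_s recording length; defaults to the last timestamp.
#' @param window_s,step_s window grid parameters.
#' @return A [rate_series()] on the estimator's window grid.
#' @export
window_average_hr <- function(inst, duration_s = NULL, window_s = 30,
                              step_s = 1) {
  if (is.null(duration_s))
    duration_s <- if (nrow(inst)) max(inst$t_s) else 0
  starts <- segment_windows(duration_s, window_s, step_s)
  if (!length(starts)) return(rate_series(numeric(0)))
  vals <- vapply(starts, function(k) {
    v <- inst$bpm[inst$t_s >= k & inst$t_s < k + window_s]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  ok <- is.finite(vals)
  rate_series(starts, rate = vals, quality = NA_real_, valid = ok,
              reason = ifelse(ok, "ok", "no_features"))
}

#' Gold-standard respiratory rate from a RIP trace
#'
#' Per sliding window: linear detrend, amplitude spectrum, parabolic-refined
#' dominant peak inside 1-100 br/min; flat windows are invalid.
#'
#' @param rip numeric vector of RIP samples (chest + abdomen sum).
#' @param fs sampling rate, Hz (default 25).
#' @param window_s,step_s window grid parameters.
#' @param band validity band in br/min.
#' @param n_fft FFT length.
#' @return A [rate_series()] on the estimator's window grid.
#' @export
gold_rr_from_rip <- function(rip, fs = 25, window_s = 30, step_s = 1,
                             band = c(1, 100), n_fft = 8192L) {
  duration_s <- length(rip) / fs
  starts <- segment_windows(duration_s, window_s, step_s)
  if (!length(starts)) return(rate_series(numeric(0)))
  band_hz <- c(band[1] / 60, min(band[2] / 60, fs / 2 * 0.999))
  rows <- lapply(starts, function(k) {
    i0 <- round(k * fs) + 1L
    seg <- rip[i0:min(i0 + round(window_s * fs) - 1L, length(rip))]
    if (length(seg) < 2L || sd(seg) < 1e-12)
      return(invalid_estimate(k, "out_of_band"))
    sp <- amplitude_spectrum(seg, fs, n_fft)
    pk <- spectral_peaks(sp, band_hz, max_n = 1L)
    if (!nrow(pk)) return(invalid_estimate(k, "out_of_band"))
    hp <- harmonic_periodicity(sp, pk$freq[1])$hp
    rate_series(k, rate = 60 * pk$freq[1], quality = hp, valid = TRUE,
                reason = "ok")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Read a two-column signal CSV
#'
#' Expects columns `time_s` and `value` with a uniform sampling grid.
#'
#' @param path file path.
#' @return list with `signal`, `t`, `fs`.
#' @export
read_signal_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stopf("%s: expected columns time_s, value", path)
  dt <- diff(df$time_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt))
    stopf("%s: time axis is not uniform", path)
  list(signal = df$value, t = df$time_s,
       fs = if (length(dt)) 1 / stats::median(dt) else NA_real_)
}

#' Write a two-column signal CSV
#'
#' @param signal numeric samples.
#' @param fs sampling rate, Hz.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, fs, path) {
  write.csv(data.frame(time_s = (seq_along(signal) - 1) / fs,
                       value = signal),
            path, row.names = FALSE)
  invisible(path)
}
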