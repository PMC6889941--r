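#' Pipeline configuration
#'
#' All tunable constants of the toolchain in one validated list. The prior
#' heart rate must equal the midpoint of the heart-rate band (80 bpm for
#' 20-140).
#'
#' @param cell_px feature-grid cell size, pixels.
#' @param points_per_cell feature points per cell.
#' @param window_s analysis window length, seconds.
#' @param step_s window step, seconds (`window_s - step_s` is the overlap).
#' @param fps video frame rate, frames/s.
#' @param hr_band_bpm heart-rate search/validity band, bpm.
#' @param rr_band_brmin breathing estimation band, br/min (the wider 1-100
#'   br/min range is applied only as the gold-standard validity filter).
#' @param prior_bpm prior ("reasonable") heart rate, bpm.
#' @param max_candidates heart-rate candidates scored per window.
#' @param spike_px movement spike threshold, px/frame.
#' @param n_fft FFT length for window spectra.
#' @param n_ica independent components per window.
#' @param seed master seed for all stochastic steps (ICA initialisation).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cell_px = 40L, points_per_cell = 8L,
                            window_s = 30, step_s = 1, fps = 30,
                            hr_band_bpm = c(20, 140),
                            rr_band_brmin = c(6, 60),
                            prior_bpm = 80, max_candidates = 12L,
                            spike_px = 2, n_fft = 8192L, n_ica = 8L,
                            seed = 1L) {
  cfg <- list(cell_px = as.integer(cell_px),
              points_per_cell = as.integer(points_per_cell),
              window_s = window_s, step_s = step_s, fps = fps,
              hr_band_bpm = as.numeric(hr_band_bpm),
              rr_band_brmin = as.numeric(rr_band_brmin),
              prior_bpm = prior_bpm,
              max_candidates = as.integer(max_candidates),
              spike_px = spike_px, n_fft = as.integer(n_fft),
              n_ica = as.integer(n_ica), seed = as.integer(seed))
  if (cfg$window_s <= 0 || cfg$step_s <= 0 || cfg$step_s > cfg$window_s)
    stopf("need 0 < step_s <= window_s")
  if (!isTRUE(all.equal(cfg$prior_bpm, mean(cfg$hr_band_bpm))))
    stopf("prior_bpm (%g) must be the midpoint of hr_band_bpm (%g)",
          cfg$prior_bpm, mean(cfg$hr_band_bpm))
  if (cfg$cell_px < 1L || cfg$points_per_cell < 1L || cfg$fps <= 0)
    stopf("cell_px, points_per_cell and fps must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Write or read a pipeline configuration (YAML)
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write or read video frames as a PNG directory
#'
#' Frames are stored as 8-bit grayscale PNGs `frame_000001.png, ...` plus a
#' small `meta.json` recording the frame rate.
#'
#' @param frames `H x W x n` integer array (0-255) or list of matrices.
#' @param fps frame rate.
#' @param dir directory path (created if needed).
#' @return `write_frames_png` returns `dir` invisibly; `read_frames_png`
#'   returns list with `frames` (array) and `fps`.
#' @export
write_frames_png <- function(frames, fps, dir) {
  fl <- as_frame_list(frames)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(fl)) {
    png::writePNG(fl[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  jsonlite::write_json(list(fps = fps, n_frames = length(fl)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  fl <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * 255)
  })
  frames <- array(0L, dim = c(nrow(fl[[1]]), ncol(fl[[1]]), length(fl)))
  for (i in seq_along(fl)) frames[, , i] <- as.integer(fl[[i]])
  list(frames = frames, fps = meta$fps)
}

#' Run the full estimation pipeline
#'
#' Tracks the video, estimates breathing and heart-rate series, extracts the
#' gold standards when ECG/RIP signals are supplied, and computes agreement
#' reports (overall and, when annotations are given, stratified). When
#' `out_dir` is set, the rate series are written as CSV, the reports as JSON
#' and a plain-text log summarising window exclusions.
#'
#' @param video list with `frames` and `fps` (e.g. from [gen_video()] or
#'   [read_frames_png()]), or a PNG directory path.
#' @param ecg optional list with `signal` and `fs` (e.g. from [gen_ecg()] or
#'   [read_signal_csv()]).
#' @param rip optional list with `signal` and `fs`.
#' @param annotations optional annotation data frame
#'   (see [stratified_metrics()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `rr`, `hr` (rate series), `gold_rr`, `gold_hr`,
#'   `report` (list with `rr`/`hr` agreement reports, `NULL` without gold
#'   inputs), `strata`, `tracked`, `log` (character vector).
#' @export
run_pipeline <- function(video, ecg = NULL, rip = NULL, annotations = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(video)) video <- read_frames_png(video)
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  tracked <- track_recording(video$frames, video$fps,
                             cell_px = config$cell_px,
                             points_per_cell = config$points_per_cell,
                             spike_px = config$spike_px)
  note("tracked %d frames in %d segment(s); %d movement spike(s)",
       tracked$n_frames, length(tracked$segments),
       length(tracked$spike_times_s))

  rr <- run_rr(tracked, config)
  hr <- run_hr(tracked, config)
  note("estimated %d windows: rr valid %d, hr valid %d",
       nrow(rr), sum(rr$valid), sum(hr$valid))

  duration_s <- tracked$n_frames / tracked$fps
  gold_hr <- gold_rr <- NULL
  report <- strata <- NULL
  if (!is.null(ecg)) {
    peaks <- detect_r_peaks(ecg$signal, ecg$fs)
    gold_hr <- window_average_hr(instantaneous_hr(peaks), duration_s,
                                 config$window_s, config$step_s)
  }
  if (!is.null(rip)) {
    gold_rr <- gold_rr_from_rip(rip$signal, rip$fs, config$window_s,
                                config$step_s, n_fft = config$n_fft)
  }
  if (!is.null(gold_hr) || !is.null(gold_rr)) {
    report <- list()
    if (!is.null(gold_rr)) {
      mask <- exclusion_mask(rr, gold_rr, "rr")
      report$rr <- agreement_metrics(rr, gold_rr, mask, c(1, 0.5))
      note("rr agreement: %d used, excluded: %s", report$rr$n_windows_used,
           paste(names(report$rr$n_excluded_by_reason),
                 report$rr$n_excluded_by_reason, collapse = ", "))
      if (!is.null(annotations))
        strata$rr <- stratified_metrics(rr, gold_rr, mask, annotations,
                                        c(1, 0.5))
    }
    if (!is.null(gold_hr)) {
      mask <- exclusion_mask(hr, gold_hr, "hr")
      report$hr <- agreement_metrics(hr, gold_hr, mask, c(5, 2.5))
      note("hr agreement: %d used, excluded: %s", report$hr$n_windows_used,
           paste(names(report$hr$n_excluded_by_reason),
                 report$hr$n_excluded_by_reason, collapse = ", "))
      if (!is.null(annotations))
        strata$hr <- stratified_metrics(hr, gold_hr, mask, annotations,
                                        c(5, 2.5))
    }
  }

  out <- list(rr = rr, hr = hr, gold_rr = gold_rr, gold_hr = gold_hr,
              report = report, strata = strata, tracked = tracked, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_rate_series(rr, file.path(out_dir, "rr.csv"))
    write_rate_series(hr, file.path(out_dir, "hr.csv"))
    if (!is.null(gold_rr))
      write_rate_series(gold_rr, file.path(out_dir, "gold_rr.csv"))
    if (!is.null(gold_hr))
      write_rate_series(gold_hr, file.path(out_dir, "gold_hr.csv"))
    if (!is.null(report)) {
      rep_json <- lapply(report, function(r) {
        r <- unclass(r)
        r$pct_within <- as.list(r$pct_within)
        r$n_excluded_by_reason <- as.list(r$n_excluded_by_reason)
        r
      })
      jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    writeLines(log, file.path(out_dir, "run.log"))
  }
  out
}
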