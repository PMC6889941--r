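#' Per-window rate estimates
#'
#' A `rate_series` is a data frame with one row per sliding analysis window,
#' the common currency of the estimators, the gold-standard extractors and the
#' evaluation module. Columns:
#' \describe{
#'   \item{window_start_s}{window start time in seconds}
#'   \item{rate}{estimated rate (br/min for breathing, bpm for heart rate);
#'     `NA` when invalid}
#'   \item{quality}{harmonic-periodicity score of the selected peak in
#'     \[0, 1\], `NA` where undefined}
#'   \item{valid}{logical; whether the window produced a usable estimate}
#'   \item{reason}{one of `"ok"`, `"moving"`, `"no_features"`,
#'     `"out_of_band"`}
#' }
#'
#' @param window_start_s numeric vector of window starts (seconds).
#' @param rate numeric vector of rates.
#' @param quality numeric vector of quality scores.
#' @param valid logical vector.
#' @param reason character vector of reason codes.
#' @return A data frame of class `rate_series`.
#' @export
rate_series <- function(window_start_s, rate = NA_real_, quality = NA_real_,
                        valid = FALSE, reason = "out_of_band") {
  n <- length(window_start_s)
  df <- data.frame(
    window_start_s = as.numeric(window_start_s),
    rate = rep_len(as.numeric(rate), n),
    quality = rep_len(as.numeric(quality), n),
    valid = rep_len(as.logical(valid), n),
    reason = rep_len(as.character(reason), n),
    stringsAsFactors = FALSE
  )
  bad <- df$valid & df$reason != "ok"
  if (any(bad)) stopf("valid windows must carry reason 'ok' (%d violations)", sum(bad))
  class(df) <- c("rate_series", "data.frame")
  df
}

#' Write or read a rate series as CSV
#'
#' Plain five-column CSV (`window_start_s, rate, quality, valid, reason`).
#'
#' @param x a `rate_series`.
#' @param path file path.
#' @return `write_rate_series` returns `path` invisibly; `read_rate_series`
#'   returns a `rate_series`.
#' @export
write_rate_series <- function(x, path) {
  stopifnot(inherits(x, "rate_series"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_series
#' @export
read_rate_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  rate_series(df$window_start_s, df$rate, df$quality, df$valid, df$reason)
}
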