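# Minimal European Data Format (EDF) support: enough to pull one labelled
# signal out of a standard 16-bit EDF recording, plus a writer used to build
# test fixtures in code. Continuous recordings only; no EDF+ annotations.

read_edf_header <- function(con) {
  ascii <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  h <- list(version = ascii(8), patient = ascii(80), recording = ascii(80),
            start_date = ascii(8), start_time = ascii(8))
  h$header_bytes <- as.integer(ascii(8))
  ascii(44)  # reserved
  h$n_records <- as.integer(ascii(8))
  h$record_duration_s <- as.numeric(ascii(8))
  h$ns <- as.integer(ascii(4))
  ns <- h$ns
  field <- function(n) vapply(seq_len(ns), function(i) ascii(n), character(1))
  h$labels <- field(16)
  field(80)  # transducer
  h$units <- field(8)
  h$phys_min <- as.numeric(field(8))
  h$phys_max <- as.numeric(field(8))
  h$dig_min <- as.numeric(field(8))
  h$dig_max <- as.numeric(field(8))
  field(80)  # prefiltering
  h$samples_per_record <- as.integer(field(8))
  field(32)  # reserved
  h
}

#' Read one signal from an EDF file
#'
#' Selects the channel whose label matches `label` (case-insensitive
#' substring) and returns its physically calibrated samples.
#'
#' @param path EDF file path.
#' @param label channel label to select, e.g. `"ECG"`.
#' @return list with `signal`, `fs`, `label`.
#' @export
read_edf_signal <- function(path, label) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  hit <- grep(label, h$labels, ignore.case = TRUE, fixed = FALSE)
  if (!length(hit)) stopf("%s: no channel matching '%s' (have: %s)",
                          path, label, paste(h$labels, collapse = ", "))
  ch <- hit[1]
  spr <- h$samples_per_record
  out <- numeric(h$n_records * spr[ch])
  gain <- (h$phys_max[ch] - h$phys_min[ch]) / (h$dig_max[ch] - h$dig_min[ch])
  for (r in seq_len(h$n_records)) {
    for (s in seq_len(h$ns)) {
      v <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      if (s == ch)
        out[((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
          h$phys_min[ch] + (v - h$dig_min[ch]) * gain
    }
  }
  list(signal = out, fs = spr[ch] / h$record_duration_s,
       label = h$labels[ch])
}

#' Write signals to a minimal EDF file
#'
#' One-second data records, 16-bit samples scaled to each signal's range.
#' Intended for building small test recordings; not a clinical exporter.
#'
#' @param signals named list of numeric vectors.
#' @param fs named (or recycled) numeric vector of sampling rates, Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path) {
  ns <- length(signals)
  fs <- rep_len(fs, ns)
  dur <- unique(round(lengths(signals) / fs, 6))
  if (length(dur) != 1L) stopf("signals must share one duration")
  n_rec <- as.integer(ceiling(dur))
  pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(pad(x, n)), con)
  phys_min <- vapply(signals, function(s) min(s, -1e-6), numeric(1))
  phys_max <- vapply(signals, function(s) max(s, 1e-6), numeric(1))
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (nm in names(signals)) wr(nm, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("au", 8)
  for (i in seq_len(ns)) wr(sprintf("%.4g", phys_min[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.4g", phys_max[i]), 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs[i], 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * fs[i] + 1):(r * fs[i])
      v <- signals[[i]][pmin(idx, length(signals[[i]]))]
      dig <- round(-32768 + (v - phys_min[i]) /
                     (phys_max[i] - phys_min[i]) * 65535)
      writeBin(as.integer(clamp(dig, -32768, 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
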