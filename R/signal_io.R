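#' Multichannel EEG recording container
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param rate Sampling rate in Hz (> 0).
#' @param channel_names Optional character vector; defaults to rownames or
#'   "ch1".."chN".
#' @param id Optional source identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_names = NULL, id = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) stopf("`data` must be a numeric matrix")
  assert_scalar_num(rate, "rate")
  if (rate <= 0) stopf("`rate` must be > 0")
  if (is.null(channel_names)) channel_names <- rownames(data)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stopf("`channel_names` length must equal channel count")
  rownames(data) <- channel_names
  structure(list(data = data, rate = rate, channel_names = channel_names,
                 id = id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Fixed-length EEG segment (10 s window)
#'
#' The unit of all downstream analysis: a channels x samples matrix spanning
#' exactly 10 seconds at the given rate (2560 samples at the default 256 Hz).
#'
#' @param data Numeric matrix, channels x (rate * 10) samples, microvolts.
#' @param rate Sampling rate in Hz.
#' @param label "ictal", "interictal" or "unknown".
#' @param source_id Provenance string.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, rate = 256, label = "unknown",
                        source_id = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) stopf("`data` must be a numeric matrix")
  if (!all(is.finite(data))) stopf("segment data must be finite")
  if (ncol(data) != rate * 10)
    stopf("segment must span exactly 10 s: expected %d samples, got %d",
          rate * 10, ncol(data))
  label <- match.arg(label, c("ictal", "interictal", "unknown"))
  structure(list(data = data, rate = rate, label = label,
                 source_id = source_id),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d channels x %d samples @ %g Hz, label=%s\n",
              nrow(x$data), ncol(x$data), x$rate, x$label))
  invisible(x)
}

# assert the 23-channel contract used by the network/Kuramoto stages
check_channels <- function(data, allow_other_channels = FALSE) {
  if (nrow(data) != 23L && !allow_other_channels)
    stopf(paste("expected 23 channels, got %d; the network stages are",
                "specified at N = 23 (set allow_other_channels = TRUE to override)"),
          nrow(data))
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# EDF (European Data Format, 16-bit) reading and writing. The format is a
# 256-byte ASCII header, 256 ASCII bytes per signal, then int16
# little-endian data records (one record per second here).

pad <- function(s, width) formatC(as.character(s), width = width, flag = "-")

#' Write a recording or segment as an EDF file
#'
#' 16-bit EDF with one data record per second. Physical scaling is symmetric
#' per file (max absolute amplitude), so the round-trip quantization error is
#' at most `range / 2^15`.
#'
#' @param rec An `eeg_recording` or `eeg_segment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  if (inherits(rec, "eeg_segment"))
    rec <- eeg_recording(rec$data, rec$rate, id = rec$source_id)
  if (!inherits(rec, "eeg_recording")) stopf("`rec` must be a recording or segment")
  if (rec$rate != round(rec$rate)) stopf("EDF writer requires an integer rate")
  ns <- nrow(rec$data)
  spr <- as.integer(rec$rate)                 # samples per 1-s record
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec * spr != ncol(rec$data))
    stopf("recording length must be a whole number of seconds for EDF export")
  rng <- max(abs(rec$data), 1e-6)
  pmin_ <- -rng; pmax_ <- rng
  dig <- round((rec$data - pmin_) / (pmax_ - pmin_) * 65535 - 32768)
  dig[dig > 32767] <- 32767; dig[dig < -32768] <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic", 80), pad(rec$id, 80),
    "01.01.00", "00.00.00",
    pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)
  field(rep(formatC(pmin_, format = "g", digits = 6), ns), 8)
  field(rep(formatC(pmax_, format = "g", digits = 6), ns), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports the 16-bit EDF layout written by [write_edf()] and standard
#' uniform-rate EDF recordings. Channel order is preserved as stored.
#'
#' @param path Path to an EDF file.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    stopf("`path` must be a non-empty file path")
  if (!file.exists(path)) stopf("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nbytes) readChar(con, nbytes, useBytes = TRUE)
  rd(8)                                        # version
  rd(80); id <- trimws(rd(80))
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1) stopf("malformed EDF header: bad signal count")
  rdf <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  labels <- rdf(16); rdf(80); rdf(8)
  pmin_ <- as.numeric(rdf(8)); pmax_ <- as.numeric(rdf(8))
  dmin_ <- as.numeric(rdf(8)); dmax_ <- as.numeric(rdf(8))
  rdf(80)
  spr <- as.integer(rdf(8))
  rdf(32)
  if (length(unique(spr)) != 1L)
    stopf("non-uniform sampling rate across EDF channels (%s)",
          paste(unique(spr), collapse = ", "))
  rate <- spr[1] / dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    if (length(raw) < ns * spr[1]) stopf("truncated EDF data record %d", r)
    block <- matrix(raw, nrow = spr[1], ncol = ns)   # channel-major record
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block)
  }
  phys <- data * (pmax_ - pmin_) / (dmax_ - dmin_) +
    (pmin_ - dmin_ * (pmax_ - pmin_) / (dmax_ - dmin_))
  eeg_recording(phys, rate, channel_names = labels, id = id)
}

# ---------------------------------------------------------------------------

#' Split a recording into non-overlapping fixed-length segments
#'
#' Consecutive non-overlapping windows of `window_s` seconds; a trailing
#' partial window is dropped, so the segment count is
#' `floor(duration / window_s)`.
#'
#' @param rec An `eeg_recording`.
#' @param window_s Window length in seconds (default 10).
#' @param label Label to attach to every segment.
#' @return List of `eeg_segment`s (possibly empty, with a warning).
#' @export
segment_recording <- function(rec, window_s = 10, label = "unknown") {
  if (!inherits(rec, "eeg_recording")) stopf("`rec` must be an eeg_recording")
  if (window_s != 10)
    stopf("downstream analysis is specified for 10 s windows")
  win <- as.integer(rec$rate * window_s)
  n_seg <- ncol(rec$data) %/% win
  if (n_seg == 0L) {
    warning("recording shorter than one window; returning no segments")
    return(list())
  }
  lapply(seq_len(n_seg), function(k) {
    cols <- ((k - 1L) * win + 1L):(k * win)
    eeg_segment(rec$data[, cols, drop = FALSE], rate = rec$rate, label = label,
                source_id = sprintf("%s#%d", rec$id, k))
  })
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the filter is zero-phase and preserves the
#' instantaneous-phase structure used by the Hilbert stage. Default edges
#' 0.5-40 Hz.
#'
#' @param seg An `eeg_segment` (or `eeg_recording`).
#' @param lo,hi Band edges in Hz; requires `0 < lo < hi < rate/2`.
#' @param order Butterworth design order (default 4).
#' @return Object of the same class with filtered data.
#' @export
bandpass_filter <- function(seg, lo = 0.5, hi = 40, order = 4) {
  obj <- seg
  if (inherits(seg, "eeg_segment") || inherits(seg, "eeg_recording")) {
    data <- seg$data; rate <- seg$rate
  } else stopf("`seg` must be an eeg_segment or eeg_recording")
  if (!(lo > 0 && lo < hi && hi < rate / 2))
    stopf("band edges must satisfy 0 < lo < hi < rate/2 (Nyquist %g Hz)", rate / 2)
  bf <- signal::butter(order, c(lo, hi) / (rate / 2), type = "pass")
  filt <- t(apply(data, 1L, function(x) signal::filtfilt(bf, x)))
  dimnames(filt) <- dimnames(data)
  obj$data <- filt
  obj
}

#' Artifact-removal hook
#'
#' Placeholder stage for artifact cleaning (e.g. ICA-based removal of blink
#' and muscle components on real scalp EEG). The synthetic generator produces
#' artifact-free signals, so the default method is a no-op; the hook exists
#' so a real-data workflow can slot a cleaning step into the pipeline without
#' changing downstream code.
#'
#' @param seg An `eeg_segment`.
#' @param method Only "none" is implemented.
#' @return The segment, unchanged.
#' @export
remove_artifacts <- function(seg, method = c("none")) {
  method <- match.arg(method)
  seg
}

#' Welch power spectral density
#'
#' Averaged modified periodogram (Hann window, 50% overlap). Used to verify
#' the realized band-power fractions of generated signals.
#'
#' @param x Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param n_per_seg Samples per Welch segment (default 512).
#' @return List with `freq` (Hz) and `power` (density per Hz).
#' @export
welch_psd <- function(x, rate, n_per_seg = 512) {
  n <- length(x)
  if (n < n_per_seg) n_per_seg <- 2^floor(log2(n))
  step <- n_per_seg %/% 2
  starts <- seq(1, n - n_per_seg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_per_seg) / (n_per_seg + 1))
  scale <- sum(w^2) * rate
  nf <- n_per_seg %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + n_per_seg - 1)] * w
    P <- abs(fft(seg))^2 / scale
    half <- P[seq_len(nf)]
    half[2:(nf - 1)] <- 2 * half[2:(nf - 1)]
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1) * rate / n_per_seg, power = acc / length(starts))
}

#' Band-power fraction from a Welch spectrum
#'
#' @param x Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param band Length-2 numeric (lo, hi) in Hz.
#' @param total_band Frequency range defining the total (default 0-128 Hz).
#' @return Fraction of Welch power inside `band`.
#' @export
welch_band_fraction <- function(x, rate, band, total_band = c(0, rate / 2)) {
  psd <- welch_psd(x, rate)
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  tot <- psd$freq >= total_band[1] & psd$freq <= total_band[2]
  sum(psd$power[sel]) / sum(psd$power[tot])
}
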