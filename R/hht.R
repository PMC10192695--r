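#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by envelope
#' sifting: at each pass the mean of the cubic-spline envelopes through the
#' local maxima and minima is subtracted, and a mode is accepted when the
#' Cauchy-type criterion `sum((h_prev - h)^2) / sum(h_prev^2)` falls below
#' `stop_sd` (or after `max_sift` passes). Decomposition stops at `max_imfs`
#' or when the residual has fewer than two maxima or two minima. Envelope
#' splines mirror-extend two extrema beyond each boundary to suppress end
#' swings.
#'
#' The decomposition is exactly additive: `rowSums(imfs) + residual`
#' reconstructs the input to floating-point accuracy.
#'
#' @param x Numeric vector (length >= 16, finite).
#' @param max_imfs Maximum number of modes (default 10).
#' @param stop_sd Sifting stop criterion (default 0.2).
#' @param max_sift Maximum sifting passes per mode (default 100; sifting also
#'   continues until the mode is admissible).
#' @return An `imf_set`: list with `imfs` (length(x) x n_imf matrix) and
#'   `residual`.
#' @export
emd <- function(x, max_imfs = 10L, stop_sd = 0.2, max_sift = 100L) {
  if (!is.numeric(x)) stopf("`x` must be numeric")
  if (length(x) < 16L) stopf("`x` must have at least 16 samples")
  if (!all(is.finite(x))) stopf("`x` must be finite")
  res <- emd_cpp(as.numeric(x), as.integer(max_imfs), stop_sd,
                 as.integer(max_sift))
  structure(list(imfs = res$imfs, residual = res$residual,
                 n = length(x)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs over %d samples\n", ncol(x$imfs), x$n))
  invisible(x)
}

#' Count extrema and zero crossings of a series
#'
#' Used to check IMF admissibility (extrema and zero-crossing counts may
#' differ by at most one).
#'
#' @param x Numeric vector.
#' @return Named integer vector: `extrema`, `zero_crossings`.
#' @export
count_extrema_crossings <- function(x) {
  d <- diff(x)
  s <- sign(d)
  s <- s[s != 0]
  extrema <- if (length(s) > 1) sum(diff(s) != 0) else 0L
  sg <- sign(x)
  sg <- sg[sg != 0]
  zc <- if (length(sg) > 1) sum(diff(sg) != 0) else 0L
  c(extrema = as.integer(extrema), zero_crossings = as.integer(zc))
}

#' Analytic signal via the Hilbert transform
#'
#' Builds `z(t) = x(t) + j * H[x](t)` by the FFT half-spectrum method and
#' returns the instantaneous amplitude `a(t) = |z|`, the unwrapped phase
#' `theta(t)`, and the instantaneous frequency as the central-difference
#' derivative of the phase divided by 2*pi. Samples where the amplitude is
#' below `1e-8 * max(a)` get `NA` frequency (division-noise guard).
#'
#' @param imf Numeric vector (length >= 4).
#' @param rate Sampling rate in Hz.
#' @return An `analytic_signal`: list with `amplitude`, `phase`,
#'   `inst_freq` (Hz, `NA` where masked), `rate`.
#' @export
hilbert_analytic <- function(imf, rate) {
  if (!is.numeric(imf) || length(imf) < 4L)
    stopf("`imf` must be a numeric vector of length >= 4")
  if (!all(is.finite(imf))) stopf("`imf` must be finite")
  n <- length(imf)
  H <- numeric(n)
  if (n %% 2 == 0) {
    H[1] <- 1; H[n / 2 + 1] <- 1; H[2:(n / 2)] <- 2
  } else {
    H[1] <- 1; H[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(imf) * H, inverse = TRUE) / n
  a <- Mod(z)
  ph <- unwrap_phase(Arg(z))
  f <- numeric(n)
  f[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) / 2
  f[1] <- ph[2] - ph[1]
  f[n] <- ph[n] - ph[n - 1]
  f <- f * rate / (2 * pi)
  mask <- a < 1e-8 * max(a, 0)
  f[mask] <- NA_real_
  structure(list(amplitude = a, phase = ph, inst_freq = f, rate = rate),
            class = "analytic_signal")
}

# phase unwrapping: add multiples of 2*pi so jumps stay below pi
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Hilbert spectrum
#'
#' Time-frequency energy distribution H(omega, t): for every IMF and every
#' time sample, the squared instantaneous amplitude `a(t)^2` is accumulated
#' into the (time bin, instantaneous-frequency bin) cell. Samples with
#' masked or out-of-range instantaneous frequency are discarded and excluded
#' from the conservation total.
#'
#' @param imfset An [emd()] result.
#' @param rate Sampling rate in Hz.
#' @param freq_range Length-2 numeric, Hz (default 0-40).
#' @param n_freq_bins Number of frequency bins (default 80, >= 2).
#' @param n_time_bins Number of time bins (default 100).
#' @return A `hilbert_spectrum`: list with `grid` (time bins x freq bins),
#'   `time_edges` (s), `freq_edges` (Hz), `total_energy` (in-range sum of
#'   squared amplitudes).
#' @export
hilbert_spectrum <- function(imfset, rate, freq_range = c(0, 40),
                             n_freq_bins = 80L, n_time_bins = 100L) {
  if (!inherits(imfset, "imf_set")) stopf("`imfset` must be an imf_set")
  if (n_freq_bins < 2L) stopf("`n_freq_bins` must be >= 2")
  n <- imfset$n
  lo <- freq_range[1]; hi <- freq_range[2]
  grid <- matrix(0, n_time_bins, n_freq_bins)
  tbin <- pmin(floor((seq_len(n) - 1) / n * n_time_bins) + 1L, n_time_bins)
  total <- 0
  k <- ncol(imfset$imfs)
  if (k > 0) {
    for (m in seq_len(k)) {
      as_ <- hilbert_analytic(imfset$imfs[, m], rate)
      f <- as_$inst_freq
      ok <- !is.na(f) & f >= lo & f <= hi
      if (!any(ok)) next
      fbin <- pmin(floor((f[ok] - lo) / (hi - lo) * n_freq_bins) + 1L,
                   n_freq_bins)
      e <- as_$amplitude[ok]^2
      total <- total + sum(e)
      cell <- tbin[ok] + (fbin - 1L) * n_time_bins
      agg <- rowsum(e, group = cell)
      at <- as.integer(rownames(agg))
      grid[at] <- grid[at] + agg[, 1L]
    }
  }
  structure(list(grid = grid,
                 time_edges = seq(0, n / rate, length.out = n_time_bins + 1L),
                 freq_edges = seq(lo, hi, length.out = n_freq_bins + 1L),
                 total_energy = total),
            class = "hilbert_spectrum")
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat(sprintf("<hilbert_spectrum> %d time x %d freq bins, %.3g total energy\n",
              nrow(x$grid), ncol(x$grid), x$total_energy))
  invisible(x)
}

#' Plot a Hilbert spectrum
#'
#' @param x A `hilbert_spectrum`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.hilbert_spectrum <- function(x, ...) {
  graphics::image(x = x$time_edges, y = x$freq_edges, z = x$grid,
                  xlab = "time (s)", ylab = "frequency (Hz)", ...)
  invisible(x)
}

#' Hilbert marginal spectrum
#'
#' Time-integral of the Hilbert spectrum: total energy contribution per
#' frequency bin (the column sums of the grid, exactly).
#'
#' @param hs A [hilbert_spectrum()].
#' @return A `marginal_spectrum`: list with `energy` (per frequency bin) and
#'   `freq_edges`.
#' @export
marginal_spectrum <- function(hs) {
  if (!inherits(hs, "hilbert_spectrum")) stopf("`hs` must be a hilbert_spectrum")
  structure(list(energy = colSums(hs$grid), freq_edges = hs$freq_edges),
            class = "marginal_spectrum")
}

#' Band-energy fractions from a marginal spectrum
#'
#' Assigns frequency bins to the conventional delta/theta/alpha/beta bands by
#' bin-center membership and reports each band's share of total energy.
#' Gaps between bands mean the fractions may sum to less than 1.
#'
#' @param ms A [marginal_spectrum()].
#' @return A `band_energies`: list with `fractions` (named, delta/theta/
#'   alpha/beta), `total_energy`, and `zero_energy` flag (fractions reported
#'   as 0 when the spectrum is empty).
#' @export
band_energy_fractions <- function(ms) {
  if (!inherits(ms, "marginal_spectrum")) stopf("`ms` must be a marginal_spectrum")
  centers <- (ms$freq_edges[-1] + ms$freq_edges[-length(ms$freq_edges)]) / 2
  total <- sum(ms$energy)
  bands <- eeg_bands()
  fr <- vapply(bands, function(b) {
    sel <- centers >= b[1] & centers <= b[2]
    if (total > 0) sum(ms$energy[sel]) / total else 0
  }, numeric(1))
  structure(list(fractions = fr, total_energy = total,
                 zero_energy = total <= 0),
            class = "band_energies")
}

#' Per-segment band energies through the full HHT path
#'
#' Runs EMD, the Hilbert spectrum and the marginal spectrum on every channel
#' of a segment, pools the marginal energy across channels, and returns the
#' pooled band fractions.
#'
#' @param seg An `eeg_segment`.
#' @param ... Passed to [hilbert_spectrum()].
#' @return A `band_energies` for the pooled marginal spectrum.
#' @export
segment_band_energies <- function(seg, ...) {
  if (!inherits(seg, "eeg_segment")) stopf("`seg` must be an eeg_segment")
  pooled <- NULL
  for (ch in seq_len(nrow(seg$data))) {
    hs <- hilbert_spectrum(emd(seg$data[ch, ]), rate = seg$rate, ...)
    ms <- marginal_spectrum(hs)
    pooled <- if (is.null(pooled)) ms$energy else pooled + ms$energy
    edges <- ms$freq_edges
  }
  band_energy_fractions(structure(list(energy = pooled, freq_edges = edges),
                                  class = "marginal_spectrum"))
}

#' Per-channel Hilbert spectra of a segment
#'
#' @param seg An `eeg_segment`.
#' @param ... Passed to [hilbert_spectrum()].
#' @return List of one `hilbert_spectrum` per channel.
#' @export
segment_spectra <- function(seg, ...) {
  if (!inherits(seg, "eeg_segment")) stopf("`seg` must be an eeg_segment")
  lapply(seq_len(nrow(seg$data)), function(ch)
    hilbert_spectrum(emd(seg$data[ch, ]), rate = seg$rate, ...))
}

#' Export a Hilbert spectrum as a PNG image
#'
#' @param hs A `hilbert_spectrum`.
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
write_hs_png <- function(hs, path, width = 640, height = 480) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(hs)
  invisible(path)
}

#' Export a marginal spectrum as CSV
#'
#' Writes two columns, `freq_hz` (bin centers) and `energy`.
#'
#' @param ms A `marginal_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marginal_csv <- function(ms, path) {
  centers <- (ms$freq_edges[-1] + ms$freq_edges[-length(ms$freq_edges)]) / 2
  write.csv(data.frame(freq_hz = centers, energy = ms$energy), path,
            row.names = FALSE)
  invisible(path)
}
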