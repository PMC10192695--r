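#' Regime specification for synthetic EEG generation
#'
#' Describes one generation regime (ictal or interictal): how signal power is
#' distributed over the conventional EEG bands, the overall amplitude, the
#' strength of the directed ground-truth coupling, and the pink-noise level.
#'
#' Defaults encode the two regimes the pipeline is designed to contrast:
#' interictal energy concentrated in the delta band with weaker coupling, and
#' ictal energy shifted to higher bands with larger amplitude and stronger
#' coupling.
#'
#' @param label "ictal" or "interictal".
#' @param band_weights Named numeric vector of power fractions for
#'   delta/theta/alpha/beta; must be nonnegative and sum to 1 (within 1e-12).
#'   Defaults depend on `label`.
#' @param amplitude_scale Unitless multiplier on the whole signal.
#' @param coupling_strength Unitless scale on the ground-truth coupling
#'   matrix; must be >= 0.
#' @param noise_sd Standard deviation of the additive pink noise relative to
#'   the unit-power oscillatory part.
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @return An object of class `regime_spec`.
#' @export
regime_spec <- function(label = c("ictal", "interictal"),
                        band_weights = NULL,
                        amplitude_scale = NULL,
                        coupling_strength = NULL,
                        noise_sd = 0.2,
                        seed = 1L) {
  label <- match.arg(label)
  if (is.null(band_weights)) {
    band_weights <- if (label == "interictal")
      c(delta = 0.7, theta = 0.1, alpha = 0.1, beta = 0.1)
    else
      c(delta = 0.15, theta = 0.2, alpha = 0.25, beta = 0.4)
  }
  if (is.null(names(band_weights)))
    names(band_weights) <- c("delta", "theta", "alpha", "beta")
  if (length(band_weights) != 4L || any(!is.finite(band_weights)))
    stopf("`band_weights` must be 4 finite fractions (delta/theta/alpha/beta)")
  if (any(band_weights < 0))
    stopf("`band_weights` must be nonnegative")
  if (abs(sum(band_weights) - 1) > 1e-12)
    stopf("`band_weights` must sum to 1 (got %.15g)", sum(band_weights))
  if (is.null(amplitude_scale))
    amplitude_scale <- if (label == "ictal") 2 else 1
  if (is.null(coupling_strength))
    coupling_strength <- if (label == "ictal") 1 else 0.5
  assert_scalar_num(coupling_strength, "coupling_strength")
  if (coupling_strength < 0) stopf("`coupling_strength` must be >= 0")
  assert_scalar_num(amplitude_scale, "amplitude_scale")
  assert_scalar_num(noise_sd, "noise_sd")
  structure(
    list(label = label, band_weights = band_weights,
         amplitude_scale = amplitude_scale,
         coupling_strength = coupling_strength,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "regime_spec")
}

#' @export
print.regime_spec <- function(x, ...) {
  cat("<regime_spec>", x$label, "\n")
  cat("  band_weights:",
      paste(sprintf("%s=%.2f", names(x$band_weights), x$band_weights),
            collapse = " "), "\n")
  cat(sprintf("  amplitude_scale=%.2f coupling_strength=%.2f noise_sd=%.2f seed=%d\n",
              x$amplitude_scale, x$coupling_strength, x$noise_sd, x$seed))
  invisible(x)
}

#' Focus-block channel indices
#'
#' The six channels forming the strongly coupled "focus" block of the ictal
#' ground-truth topology. They are spread across the channel list so their
#' Kuramoto natural frequencies (assigned by channel index) span \[0, 1\]
#' rather than clustering at one end.
#'
#' @return Integer vector of 6 channel indices.
#' @export
focus_block_channels <- function() c(2L, 6L, 10L, 13L, 17L, 21L)

#' Ground-truth coupling topology for a regime
#'
#' Returns the 23 x 23 nonnegative directed base coupling matrix (row =
#' driver, column = receiver, zero diagonal) used by [generate_segment()].
#' The two regimes deliberately differ in topology so that the downstream
#' network contrasts exist by construction:
#'
#' * interictal: a hub-clustered "windmill" -- channel 1 broadcasts one-way
#'   to every other channel (weight 1.3), and the remaining 22 channels form
#'   11 mutually coupled leaf pairs (weight 1.8); each pair plus the hub is
#'   a triangle. Locally clustered with short paths through the hub, but the
#'   weak broadcast from a frequency-extreme hub cannot entrain the
#'   mutually locked pairs, so global synchronization is poor.
#' * ictal: a ring lattice (each channel coupled to its four nearest ring
#'   neighbours in both directions, weight 1.0) over an order in which the
#'   six focus-block channels ([focus_block_channels()]) are contiguous and
#'   the rest are deterministically scrambled, plus the all-to-all focus
#'   block (weight 1.3). Denser and more distributed; the block acts as a
#'   coherent core that entrains the network.
#'
#' The realized ground truth of a segment is this base matrix times the
#' spec's `coupling_strength`.
#'
#' @param label "ictal" or "interictal".
#' @return A 23 x 23 matrix with zero diagonal.
#' @export
ground_truth_topology <- function(label = c("ictal", "interictal")) {
  label <- match.arg(label)
  n <- 23L
  G <- matrix(0, n, n)
  if (label == "interictal") {
    hub <- 1L
    leaves <- setdiff(seq_len(n), hub)
    G[hub, leaves] <- 1.3                       # one-way broadcast
    pairs <- matrix(leaves, ncol = 2L, byrow = TRUE)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1L]; b <- pairs[r, 2L]
      G[a, b] <- G[b, a] <- 1.8                 # tight leaf pairs
    }
  } else {
    block <- focus_block_channels()
    rest <- setdiff(seq_len(n), block)
    ord <- c(block, rest[(5L * (0:16)) %% 17L + 1L])  # block-contiguous ring
    for (i in seq_len(n)) for (d in c(1L, 2L)) {
      a <- ord[i]; b <- ord[((i - 1L + d) %% n) + 1L]
      G[a, b] <- G[b, a] <- 1.0                 # ring lattice, k = 2
    }
    G[block, block] <- 1.3                      # focus block
    diag(G) <- 0
  }
  dimnames(G) <- list(scalp_channel_names(), scalp_channel_names())
  G
}

# pink (1/f) noise: spectrally shaped white noise, normalized to unit sd
pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))           # avoid division by zero at DC
  f <- pmin(f, n - f + 1)             # fold to two-sided frequency magnitude
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x / s else x
}

#' Generate one synthetic 23-channel EEG segment
#'
#' Builds a 23 x 2560 segment (10 s at 256 Hz): each channel is a sum of one
#' amplitude-modulated sinusoid per conventional band (carrier frequency
#' drawn within the band, component power proportional to the regime's band
#' weight) plus pink noise; directed inter-channel influence is then realized
#' by adding lagged, scaled copies of driver channels into receiver channels
#' according to the ground-truth coupling matrix.
#'
#' @param spec A [regime_spec()].
#' @param coupling Optional 23 x 23 nonnegative base coupling matrix (row =
#'   driver); defaults to [ground_truth_topology()] for the regime's label.
#'   The effective coupling is `coupling * spec$coupling_strength`.
#' @param lag Coupling lag in samples (default 1, the single-step influence
#'   that symbol-level transfer entropy with unit delay detects directly).
#' @return A list with elements `segment` (an `eeg_segment`) and `truth`
#'   (class `ground_truth`: the effective coupling matrix and the label).
#' @export
generate_segment <- function(spec, coupling = NULL, lag = 1L) {
  if (!inherits(spec, "regime_spec")) stopf("`spec` must be a regime_spec")
  n_ch <- 23L; fs <- 256L; n <- fs * 10L
  if (is.null(coupling)) coupling <- ground_truth_topology(spec$label)
  if (!is.matrix(coupling) || any(dim(coupling) != n_ch))
    stopf("`coupling` must be a 23 x 23 matrix")
  if (any(coupling < 0) || any(diag(coupling) != 0))
    stopf("`coupling` must be nonnegative with a zero diagonal")
  G <- coupling * spec$coupling_strength
  bands <- eeg_bands()
  tt <- (seq_len(n) - 1) / fs

  out <- with_seed(spec$seed, {
    base <- matrix(0, n_ch, n)
    for (ch in seq_len(n_ch)) {
      x <- numeric(n)
      for (b in seq_along(bands)) {
        wgt <- spec$band_weights[[b]]
        if (wgt <= 0) next
        rng <- bands[[b]]
        f0 <- runif(1, rng[1] + 0.1 * diff(rng), rng[2] - 0.1 * diff(rng))
        fm <- runif(1, 0.2, 0.8)
        ph <- runif(2, 0, 2 * pi)
        comp <- sin(2 * pi * f0 * tt + ph[1]) *
          (1 + 0.3 * sin(2 * pi * fm * tt + ph[2]))
        x <- x + comp / sd(comp) * sqrt(wgt)
      }
      base[ch, ] <- x + spec$noise_sd * pink_noise(n)
    }
    mixed <- base
    idx <- which(G > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      j <- idx[r, 1L]; i <- idx[r, 2L]     # driver j -> receiver i
      lagged <- c(numeric(lag), base[j, seq_len(n - lag)])
      mixed[i, ] <- mixed[i, ] + G[j, i] * lagged
    }
    mixed * spec$amplitude_scale * 30      # microvolt scale
  })

  rownames(out) <- scalp_channel_names()
  seg <- eeg_segment(out, rate = fs, label = spec$label,
                     source_id = sprintf("synth-%s-seed%d", spec$label, spec$seed))
  truth <- structure(list(coupling = G, label = spec$label),
                     class = "ground_truth")
  list(segment = seg, truth = truth)
}

#' Generate a balanced labeled dataset of synthetic segments
#'
#' Produces `n_per_class` ictal and `n_per_class` interictal segments with
#' alternating labels. Per-segment seeds are derived deterministically from
#' `master_seed` by fixed integer hashing
#' (`(48271 * master + 104729 * index + 12345) mod (2^31 - 1)`), so a dataset
#' is exactly reconstructable from its master seed.
#'
#' @param n_per_class Number of segments per class (>= 1).
#' @param ictal_spec,interictal_spec Template [regime_spec()]s; their seeds
#'   are replaced by the derived per-segment seeds.
#' @param master_seed Integer master seed.
#' @return An `eeg_dataset`: list with `segments`, `labels`, `truths`,
#'   `master_seed`.
#' @export
generate_dataset <- function(n_per_class,
                             ictal_spec = regime_spec("ictal"),
                             interictal_spec = regime_spec("interictal"),
                             master_seed = 1L) {
  if (!is.numeric(n_per_class) || length(n_per_class) != 1L || n_per_class < 1)
    stopf("`n_per_class` must be an integer >= 1")
  n_per_class <- as.integer(n_per_class)
  labels <- rep(c("interictal", "ictal"), n_per_class)
  segments <- vector("list", 2L * n_per_class)
  truths <- vector("list", 2L * n_per_class)
  for (k in seq_along(labels)) {
    spec <- if (labels[k] == "ictal") ictal_spec else interictal_spec
    spec$seed <- derive_seed(master_seed, k)
    gen <- generate_segment(spec)
    segments[[k]] <- gen$segment
    truths[[k]] <- gen$truth
  }
  structure(list(segments = segments, labels = labels, truths = truths,
                 master_seed = as.integer(master_seed)),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d segments (%d ictal / %d interictal), master_seed=%d\n",
              length(x$segments), sum(x$labels == "ictal"),
              sum(x$labels == "interictal"), x$master_seed))
  invisible(x)
}

#' Unidirectionally coupled autoregressive pair
#'
#' Fixture for validating directed-coupling estimators. Generates
#' `x[t+1] = a * x[t] + eps[t]` and `y[t+1] = b * y[t] + c * x[t] + eta[t]`
#' with independent unit-variance Gaussian innovations, so information flows
#' from X to Y only.
#'
#' @param n Series length (>= 100).
#' @param c Coupling coefficient in \[0, 1\].
#' @param seed Integer seed.
#' @param a,b Autoregressive coefficients (defaults 0.5).
#' @return List with numeric vectors `x` and `y`.
#' @export
generate_coupled_pair <- function(n, c, seed = 1L, a = 0.5, b = 0.5) {
  if (!is.numeric(n) || length(n) != 1L || n < 100)
    stopf("`n` must be an integer >= 100")
  assert_scalar_num(c, "c")
  if (c < 0 || c > 1) stopf("`c` must be in [0, 1]")
  n <- as.integer(n)
  with_seed(seed, {
    eps <- rnorm(n); eta <- rnorm(n)
    x <- as.numeric(stats::filter(eps, a, method = "recursive"))
    xlag <- c(0, x[-n])
    y <- as.numeric(stats::filter(c * xlag + eta, b, method = "recursive"))
    list(x = x, y = y)
  })
}
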