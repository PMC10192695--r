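---
title: "Methods: time-frequency and network characterization of epileptic EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-frequency and network characterization of epileptic EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictalnet)
```

## Overview

`ictalnet` characterizes multichannel scalp EEG in the ictal (seizure) and
interictal states along two complementary arms:

1. **Time-frequency arm.** Each channel is decomposed by empirical mode
   decomposition (EMD), mapped to a Hilbert spectrum (HS) and Hilbert
   marginal spectrum (HMS), summarized as band-energy fractions
   (delta 0.5–3, theta 4–7, alpha 8–13, beta 14–30 Hz), and — for
   classification — the 23 per-channel HS images of a 10 s segment are
   stacked into a tensor and fed to a small convolutional network.
2. **Network arm.** Directed pairwise coupling between channels is
   estimated by symbolic transfer entropy (STE); thresholding the 23×23
   STE matrix yields a weighted directed brain network that is summarized
   by four graph metrics and used as the coupling matrix of a Kuramoto
   phase-oscillator model to probe synchronization dynamics.

All analyses operate on 10 s, 23-channel segments sampled at 256 Hz, the
convention of public scalp-EEG seizure corpora. Because such corpora cannot
be redistributed, the package ships a synthetic-EEG generator with known
ground truth; every quantitative claim the test suite makes is about data
constructed to contain the corresponding contrast, not about any clinical
recording.

## Empirical mode decomposition and the Hilbert spectrum

EMD iteratively subtracts the mean of the cubic-spline envelopes through
the local maxima and minima ("sifting") until the component satisfies the
mode conditions. Choices the literature leaves open, fixed here:

* **Envelope boundaries.** Two extrema are mirror-reflected beyond each
  end of the signal before spline fitting; this suppresses end swings of
  the envelopes without inventing data.
* **Stopping rule.** A mode is accepted when the Cauchy-type criterion
  `sum((h_prev - h)^2)/sum(h_prev^2) < 0.2` *and* the mode is admissible
  (extrema and zero-crossing counts differ by at most one). Admissibility
  is checked explicitly because on broadband signals the SD criterion
  alone can stop while riding waves remain; up to 100 sifting passes are
  allowed (typically fewer than 10 are used).
* **Termination.** Decomposition stops after 10 modes or when the
  residual has fewer than two maxima or two minima.

The decomposition is exactly additive by construction, so
`rowSums(imfs) + residual` reproduces the input to floating-point
accuracy; the suite asserts 1e-9 relative on random segments.

Each mode's analytic signal is built by the FFT half-spectrum method; the
instantaneous frequency is the central difference of the unwrapped phase.
Samples with amplitude below `1e-8 * max(a)` have their frequency masked
(phase is meaningless there). The HS accumulates squared amplitude into a
100 (time) × 80 (frequency) grid over 0–40 Hz; the HMS is its exact
time-sum, and band fractions are bin-center sums over the conventional
bands. Energy conservation between HS and HMS is exact rearrangement and
is asserted exactly. One caveat documented by the tests: the FFT analytic
signal is distorted over roughly the first and last 1–2 % of samples, so
about 5 % of a pure tone's energy lands outside its frequency bin; the
interior of the grid concentrates > 99 %.

## Symbolic transfer entropy and network construction

Each channel is symbolized by ordinal patterns: windows of `m = 3`
consecutive samples (delay `tau = 1`) map to the lexicographic rank of
their rank-order pattern, ties broken toward the earlier index. With six
symbols and ~2,558 windows per segment the transition histograms are well
populated. Transfer entropy is then the plug-in estimate of

> STE(J→I) = Σ p(i⁺, i, j) log₂ [ p(i⁺ | i, j) / p(i⁺ | i) ]

with single-symbol histories on both sides (the `history_k`, `history_l`
options generalize to longer symbol histories). Zero-probability terms
contribute nothing and the estimate is floored at zero; identical streams
give exactly zero. Base-2 logarithms give bits.

The empirical plug-in floor for independent band-limited noise at this
segment length is about 0.012 bits on average with a tail just above
0.02; the operating edge threshold of 0.02 bits therefore sits at the
upper edge of the noise floor, and thresholded networks on pure noise are
almost empty (the suite asserts the floor's mean and maximum). A sparser
0.08 threshold is retained for display purposes; its network is provably
a subset of the 0.02 network.

Graph metrics are computed on the symmetrized graph (undirected weight =
max of the two directed weights — any detected link is preserved):

* mean shortest path (binary hops by default; weighted mode uses 1/weight
  distances; unreachable pairs are excluded and their fraction reported),
* Watts–Strogatz clustering (nodes of degree < 2 contribute 0),
* global efficiency (unreachable pairs contribute 0),
* synchronizability as the Laplacian eigenratio λ₂/λ_max of the binary
  symmetrized graph (0 with a flag when disconnected).

All four are validated against independent brute-force oracles
(Bellman–Ford and boolean-matrix-power distances, explicit triangle
enumeration, Jacobi eigenvalues) on every connected graph with up to six
nodes and on random graphs with up to eight.

## Kuramoto synchronization

The phase model dθᵢ/dt = ωᵢ + (K/N) Σⱼ G\_ij sin(θⱼ − θᵢ) is integrated
with fixed-step classical RK4 (dt = 0.01 s, horizon 1000 s, trajectories
saved every 10 steps; the suite verifies ≥ 3.5 observed convergence
order, the uncoupled closed form, and the two-oscillator locking
threshold to 2 %). `N = 23` matches the channel count; `K = 3.5`;
intrinsic frequencies are the deterministic even grid ωᵢ = i/(N−1) on
[0, 1] — "evenly distributed" is read as the grid rather than uniform
draws, with `random_omega = TRUE` as the alternative. Initial phases are
seeded uniform on [0, 2π). `G` is the thresholded STE matrix, transposed
into receiver orientation (`as_coupling()`), used directed as-is.

Synchronization is quantified by the order parameter r(t) (modulus of the
mean unit phasor) and by the time to sustained synchronization: the first
time r ≥ 0.9 after which it never drops below 0.85.

**Comparing networks.** Raw STE weights are a few hundredths of a bit, so
(K/N)·G is far too small to overcome the [0, 1] frequency spread within
the horizon; some overall coupling scale is unavoidable for the dynamics
to express differences at all. Two protocols were considered. Matching
each network's *total* weight to a common budget erases the overall
coupling-strength difference between regimes — and hands sparse networks
a per-edge advantage that, in calibration, made weakly coupled interictal
networks synchronize *faster* than ictal ones, the opposite of the
mechanism of interest. The package therefore applies one *common*
multiplicative scale (`sync_coupling_scale()`, 130) to every network in a
comparison: relative strength between networks is preserved, and the
scale is chosen once so that strongly coupled networks lock within the
1000 s horizon while weakly coupled ones remain incoherent.
`match_total_weight()` is provided for users who want the
equal-budget protocol explicitly.

## The synthetic-EEG generator

Each channel is a sum of four amplitude-modulated sinusoids, one per
conventional band (carrier drawn uniformly within the band, power
proportional to the regime's band weights), plus 1/f-shaped pink noise
(`noise_sd = 0.2` relative to unit signal power). Directed influence is
realized by adding one-sample-lagged, scaled copies of driver channels
into receivers according to a ground-truth coupling matrix; with the STE
defaults (m = 3, τ = 1, single-symbol histories) a one-sample lag is the
influence the estimator's transition probabilities condition on directly,
which makes the ground truth cleanly recoverable. The lag is a parameter
for users who want to study estimator mismatch (at lag 4 the detection
rate drops from ~0.8 to ~0.25 — a property of symbol-level estimators
worth knowing about).

The two regimes encode the contrasts of interest:

| property | interictal | ictal |
|---|---|---|
| band weights (δ, θ, α, β) | 0.70, 0.10, 0.10, 0.10 | 0.15, 0.20, 0.25, 0.40 |
| amplitude scale | 1 | 2 |
| coupling strength | 0.5 | 1.0 |
| topology | one-way hub (channel 1, w = 1.3) + 11 mutually coupled leaf pairs (w = 1.8) | ring lattice k = 2 (w = 1.0) + all-to-all 6-channel focus block (w = 1.3) |

The topologies were designed (and frozen before the tests were written)
so the realized, thresholded STE networks differ in the directions the
ictal/interictal literature reports: the hub-and-pairs "windmill" gives
short paths, high clustering and high efficiency but a low Laplacian
eigenratio (the hub's degree inflates λ_max) and poor entrainment — the
hub sits at a frequency extreme and its broadcast is too weak to align
the mutually locked pairs; the ictal ring-plus-focus-block is denser and
more homogeneous, with longer paths but a higher eigenratio, and its
focus block — six channels whose natural frequencies span [0, 1] and
whose ring positions are contiguous under a deterministically scrambled
ordering — locks into a coherent core at the population mean frequency
and entrains the network. Two details matter and cost nothing
structurally: scrambling the ring order (a graph isomorphism) removes the
systematic frequency gradient that otherwise locks rings into traveling
waves, and spreading the block's channels removes the rigid low-frequency
cluster that otherwise beats against the rest.

Coupling weights sit near the STE detection optimum deliberately: the
estimator's response to mixing strength is non-monotone (a receiver
dominated by its driver becomes predictable from its own past, and the
apparent transfer falls), so weights around 0.7–1.3 effective mixing give
detection rates of 0.8–0.9 while keeping segments band-realistic.

What the generator does *not* emulate: spike-wave seizure morphology,
artifacts (blinks, EMG), volume conduction, nonstationary onset dynamics,
or any claim about the true connectivity of clinical recordings. Passing
contrasts therefore demonstrate that the pipeline detects what it is
designed to detect, not that clinical data behave this way.

## The classifier

The network is the smallest standard image stack: conv(32, 3×3)-ReLU-
maxpool(2×2)-conv(64, 3×3)-ReLU-maxpool(2×2)-dropout(0.5)-dense(64)-
softmax(2), trained with Adam (lr 1e-3) on a seed-stratified 80/20 split
of per-segment min-max-normalized 23×80×100 stacks. It is implemented in
compiled code with a private deterministic random stream, so training is
exactly reproducible for a given configuration on a single thread. The
synthetic classes differ strongly in band structure and amplitude, so
high held-out accuracy shows the chain (HS stack → CNN) is wired
correctly rather than that seizure detection is easy; the label-shuffle
control confirms chance-level behaviour when the signal is destroyed.
An 80/20 split is the evaluation protocol; leave-one-out is not
implemented.

## Problem sizes and numerical choices

Test-suite problem sizes: 50 segments per class for band-energy and
network contrasts, 20 per class for synchronization timing, 100 per class
for classifier training, 50 seeds for estimator-direction checks,
exhaustive graph sweeps to n = 6 plus 100 random graphs to n = 8.
The acceptance script uses 50 segments per class for classification,
25 per class for networks and band energies, and 10 per class for
synchronization timing.

Degenerate inputs are defined, not errors: constant signals decompose to
zero modes; zero spectra yield zero fractions with a flag; empty networks
flag path length as undefined and give zero efficiency; disconnected
graphs report zero synchronizability with a flag. EDF export quantizes to
16 bits over a symmetric per-file physical range (round-trip error at
most range/2¹⁵).

## Known limitations

* EMD is the classic single-channel variant; no ensemble or multivariate
  extensions, so mode mixing on real EEG is possible.
* The STE estimator is the plug-in histogram form without surrogate
  correction; its small-sample bias floor is documented above and the
  fixed 0.02 threshold inherits it.
* The Kuramoto stage is first-order, non-delayed, and uses one common
  coupling scale; conclusions are about relative, not absolute, timing.
* The ICA artifact-removal stage of real-EEG workflows is a no-op hook
  (`remove_artifacts()`); synthetic data contain no artifacts.
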