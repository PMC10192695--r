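# ictalnet

Whole-brain characterization of epileptic EEG in R: Hilbert–Huang
time–frequency analysis with image-based seizure classification, directed
functional brain networks from symbolic transfer entropy, graph-theoretic
comparison of ictal vs. interictal states, and Kuramoto phase-oscillator
simulation of seizure synchronization — exercised end to end on synthetic
multichannel EEG with known ground truth.

## Who this is for

Researchers studying seizure dynamics in multichannel scalp EEG
(23 channels, 256 Hz, 10 s segments — the conventions of public scalp-EEG
seizure corpora) who want a self-contained, tested implementation of the
full analysis chain, plus a ground-truth synthetic generator for validating
each stage before touching clinical data.

## The methods

**Time–frequency arm.** Empirical mode decomposition sifts each channel
into intrinsic mode functions; the analytic signal z(t) = a(t)·e^{jθ(t)} of
each mode yields instantaneous amplitude and frequency ω(t) = dθ/dt, and
the Hilbert spectrum H(ω, t) accumulates |a(t)|² on a time–frequency grid
(0–40 Hz). Its time integral (the marginal spectrum) gives band energies
over δ (0.5–3), θ (4–7), α (8–13), β (14–30 Hz). Per-segment stacks of the
23 channel spectra feed a small CNN
(conv 32·3×3 – pool 2×2 – conv 64·3×3 – pool 2×2 – dropout – dense –
softmax, Adam optimizer, 80/20 split).

**Network arm.** Channels are symbolized by ordinal patterns (m = 3,
τ = 1) and every ordered channel pair gets a symbolic transfer entropy

    STE(J→I) = Σ p(i⁺, i, j) · log₂[ p(i⁺ | i, j) / p(i⁺ | i) ]   (bits),

giving a 23×23 directed weighted matrix; edges with STE ≥ 0.02 bits form
the brain network. Four metrics summarize it — mean shortest path,
clustering coefficient, global efficiency, and synchronizability
(Laplacian eigenratio λ₂/λ_max) — and the network serves as coupling
matrix G in the Kuramoto model

    dθᵢ/dt = ωᵢ + (K/N) Σⱼ G_ij sin(θⱼ − θᵢ),   N = 23, K = 3.5,

with ωᵢ evenly spaced on [0, 1]. Synchronization is tracked by the order
parameter r(t) and the time to sustained r ≥ 0.9.

## Worked example

```r
library(ictalnet)

# one synthetic segment per regime, preprocessed
ictal  <- bandpass_filter(generate_segment(regime_spec("ictal",      seed = 1))$segment)
inter  <- bandpass_filter(generate_segment(regime_spec("interictal", seed = 1))$segment)

# band energies through the HHT chain
round(segment_band_energies(inter)$fractions, 3)
#> delta theta alpha  beta
#> 0.642 0.073 0.082 0.114
round(segment_band_energies(ictal)$fractions, 3)
#> delta theta alpha  beta
#> 0.201 0.153 0.171 0.371

# directed brain networks
net_i <- threshold_network(ste_matrix(ictal), 0.02)
net_n <- threshold_network(ste_matrix(inter), 0.02)
net_i
#> <brain_network> 23 nodes, 118 directed edges (threshold 0.02, density 0.233)
net_n
#> <brain_network> 23 nodes, 78 directed edges (threshold 0.02, density 0.154)

rbind(ictal = network_metrics(net_i)[, c(2, 4, 5, 7)],
      inter = network_metrics(net_n)[, c(2, 4, 5, 7)])
#>       mean_shortest_path clustering_coefficient global_efficiency synchronizability
#> ictal               2.22                  0.624             0.562            0.0598
#> inter               1.78                  0.837             0.609            0.0435

# Kuramoto synchronization on the two networks (common coupling scale)
cs <- compare_sync(net_i, net_n, cfg = kuramoto_config(seed = 1))
c(ictal = cs$a$tts, interictal = cs$b$tts)
#>      ictal interictal
#>        5.2       25.2
```

The interictal segment keeps ~0.64 of its energy in the δ band while the
ictal segment shifts energy into β; the ictal network is denser with a
higher Laplacian eigenratio, and under a common coupling scale it reaches
sustained synchronization five times sooner at this seed (across many
seeds the median interictal network never locks within the horizon) —
the contrasts the synthetic regimes are constructed to contain.

A command-line driver for whole runs is installed at
`inst/scripts/run-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run-pipeline.R", package="ictalnet"))')" \
    --n-per-class 10 --seed 1 --out run1
```

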