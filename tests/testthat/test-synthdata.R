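test_that("regime specs validate band weights and coupling strength", {
  expect_error(regime_spec("ictal", band_weights = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(regime_spec("ictal", band_weights = c(-0.1, 0.5, 0.3, 0.3)),
               "nonnegative")
  expect_error(regime_spec("ictal", coupling_strength = -1), ">= 0")
  sp <- regime_spec("interictal")
  expect_equal(sum(sp$band_weights), 1)
  expect_equal(sp$band_weights[["delta"]], 0.7)
})

test_that("ground-truth topologies are nonnegative with zero diagonal", {
  for (lbl in c("ictal", "interictal")) {
    G <- ground_truth_topology(lbl)
    expect_identical(dim(G), c(23L, 23L))
    expect_true(all(G >= 0))
    expect_identical(unname(diag(G)), rep(0, 23))
  }
  # ictal is denser than interictal by construction
  expect_gt(sum(ground_truth_topology("ictal") > 0),
            sum(ground_truth_topology("interictal") > 0))
})

test_that("segment generation is deterministic and correctly shaped", {
  sp <- regime_spec("ictal", seed = 123)
  g1 <- generate_segment(sp)
  g2 <- generate_segment(sp)
  expect_identical(g1$segment$data, g2$segment$data)
  expect_identical(dim(g1$segment$data), c(23L, 2560L))
  expect_equal(g1$segment$rate, 256)
  expect_identical(g1$truth$coupling,
                   ground_truth_topology("ictal") * sp$coupling_strength)
  g3 <- generate_segment(regime_spec("ictal", seed = 124))
  expect_false(identical(g1$segment$data, g3$segment$data))
})

test_that("zero coupling leaves lagged cross-correlations at the noise floor", {
  g <- generate_segment(regime_spec("ictal", coupling_strength = 0, seed = 5))
  X <- g$segment$data
  cc <- vapply(1:10, function(k) {
    i <- 2 * k - 1; j <- 2 * k
    x <- X[i, -2560]; y <- X[j, -1]      # lag-1 cross-correlation
    abs(cor(x, y))
  }, numeric(1))
  # independent narrowband channels: small compared to the ~0.5+ values
  # coupled channel pairs show at the injection lag
  expect_lt(median(cc), 0.2)
  expect_true(all(g$truth$coupling == 0))
})

test_that("realized Welch band-power fractions track the requested weights", {
  for (lbl in c("ictal", "interictal")) {
    sp0 <- regime_spec(lbl)
    devs <- c()
    for (s in 1:20) {
      sp <- regime_spec(lbl, seed = 100 + s)
      g <- generate_segment(sp)
      # per-segment fractions: average over channels (individual channels
      # fluctuate more because carriers are drawn per channel)
      fr <- rowMeans(vapply(seq_len(23), function(ch)
        vapply(eeg_bands(), function(b)
          welch_band_fraction(g$segment$data[ch, ], 256, b), numeric(1)),
        numeric(4)))
      devs <- c(devs, abs(fr - sp0$band_weights))
    }
    expect_lt(max(devs), 0.15)
  }
})

test_that("mean STE from driver to receiver is nondecreasing in coupling strength", {
  topo <- ground_truth_topology("ictal")
  mean_ste <- vapply(c(0, 0.4, 0.8), function(strength) {
    mean(vapply(1:20, function(s) {
      sp <- regime_spec("ictal", coupling_strength = strength, seed = 500 + s)
      M <- ste_matrix(generate_segment(sp)$segment)
      mean(M[topo > 0])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ste) >= 0))
})

test_that("datasets are balanced, labelled and reconstructable", {
  expect_error(generate_dataset(0), ">= 1")
  ds <- generate_dataset(1, master_seed = 9)
  expect_length(ds$segments, 2L)
  expect_setequal(ds$labels, c("ictal", "interictal"))

  ds1 <- generate_dataset(3, master_seed = 42)
  ds2 <- generate_dataset(3, master_seed = 42)
  expect_identical(ds1$labels, ds2$labels)
  expect_identical(ds1$segments[[5]]$data, ds2$segments[[5]]$data)
  expect_identical(table(ds1$labels)[["ictal"]], 3L)
  # distinct per-segment seeds produce distinct signals
  expect_false(identical(ds1$segments[[1]]$data, ds1$segments[[3]]$data))
})

test_that("coupled AR pair has the designed direction and determinism", {
  expect_error(generate_coupled_pair(50, 0.5), ">= 100")
  expect_error(generate_coupled_pair(1000, -0.2), "\\[0, 1\\]")
  p1 <- generate_coupled_pair(1000, 0.8, seed = 3)
  p2 <- generate_coupled_pair(1000, 0.8, seed = 3)
  expect_identical(p1$x, p2$x)
  expect_identical(p1$y, p2$y)
  # c = 0: series are independent
  p0 <- generate_coupled_pair(20000, 0, seed = 4)
  expect_lt(abs(cor(p0$x[-20000], p0$y[-1])), 0.05)
  # c = 0.8: STE recovers the X -> Y direction
  cfg <- ste_config()
  p <- generate_coupled_pair(10000, 0.8, seed = 5)
  sx <- symbolize(p$x, cfg); sy <- symbolize(p$y, cfg)
  expect_gt(symbolic_transfer_entropy(sx, sy, cfg),
            symbolic_transfer_entropy(sy, sx, cfg))
})
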