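test_that("uncoupled oscillators advance linearly at their natural frequency", {
  cfg <- kuramoto_config(N = 3, K = 0, dt = 0.01, T = 100, seed = 2)
  traj <- simulate_kuramoto(matrix(0, 3, 3), cfg)
  final <- traj$phases[nrow(traj$phases), ]
  expect_lt(max(abs(final - cfg$theta0 - cfg$omega * 100)), 1e-6)
})

test_that("two oscillators lock at the closed-form phase difference", {
  # fixed point: sin(d) = dw * N / (K * (G12 + G21)) for locked dynamics
  G <- matrix(c(0, 1, 1, 0), 2, 2)
  dw <- 0.3
  cfg <- kuramoto_config(N = 2, K = 3.5, omega = c(0.5 + dw / 2, 0.5 - dw / 2),
                         theta0 = c(0.3, 0.1), dt = 0.01, T = 200,
                         save_stride = 1)
  traj <- simulate_kuramoto(G, cfg)
  d <- traj$phases[nrow(traj$phases), 1] - traj$phases[nrow(traj$phases), 2]
  expect_lt(abs(d - asin(dw * 2 / (3.5 * 2))), 1e-3)

  # below the locking threshold the difference drifts unboundedly
  cfg_drift <- kuramoto_config(N = 2, K = 0.25, omega = c(0.5 + dw / 2, 0.5 - dw / 2),
                               theta0 = c(0.3, 0.1), dt = 0.01, T = 200,
                               save_stride = 1)
  traj_d <- simulate_kuramoto(G, cfg_drift)
  dd <- traj_d$phases[, 1] - traj_d$phases[, 2]
  expect_gt(max(abs(dd - dd[1])), 2 * pi)
})

test_that("the lock/drift boundary matches the closed form within 2%", {
  # with K = 1, G12 = G21 = 1, N = 2: critical frequency difference = 1
  G <- matrix(c(0, 1, 1, 0), 2, 2)
  locks <- function(dw) {
    cfg <- kuramoto_config(N = 2, K = 1, omega = c(0.5 + dw / 2, 0.5 - dw / 2),
                           theta0 = c(0, 0), dt = 0.01, T = 300, save_stride = 10)
    traj <- simulate_kuramoto(G, cfg)
    d <- traj$phases[, 1] - traj$phases[, 2]
    late <- d[traj$times > 150]
    max(late) - min(late) < 0.1
  }
  for (dw in c(0.80, 0.90, 0.95, 0.98)) expect_true(locks(dw))
  for (dw in c(1.02, 1.05, 1.10, 1.20, 1.50, 2.00)) expect_false(locks(dw))
})

test_that("RK4 exhibits at least fourth-order-like convergence", {
  G <- matrix(c(0, 1, .5, .2, 0, 1, 1, .3, 0), 3, 3, byrow = TRUE)
  omega <- c(0.1, 0.5, 0.9)
  theta0 <- c(0, 2, 4)
  final <- function(dt) {
    cfg <- kuramoto_config(N = 3, K = 2, omega = omega, theta0 = theta0,
                           dt = dt, T = 10, save_stride = round(10 / dt))
    traj <- simulate_kuramoto(G, cfg)
    traj$phases[nrow(traj$phases), ]
  }
  e1 <- max(abs(final(0.1) - final(0.05)))
  e2 <- max(abs(final(0.05) - final(0.025)))
  order <- log2(e1 / e2)
  expect_gte(order, 3.5)
})

test_that("order parameter has the defining geometry", {
  mk_traj <- function(phases) structure(
    list(phases = phases, times = seq_len(nrow(phases)) - 1,
         config = kuramoto_config(N = ncol(phases))),
    class = "kuramoto_trajectory")
  allsame <- mk_traj(matrix(1.3, 2, 4))
  expect_equal(order_parameter(allsame)$r, c(1, 1))
  spread <- mk_traj(matrix(c(0, pi / 2, pi, 3 * pi / 2), 1, 4))
  expect_lt(order_parameter(spread)$r, 1e-12)

  # rotation invariance of r(t)
  G <- matrix(1, 5, 5) - diag(5)
  cfg <- kuramoto_config(N = 5, K = 2, dt = 0.01, T = 20, seed = 3)
  r1 <- order_parameter(simulate_kuramoto(G, cfg))$r
  cfg2 <- cfg; cfg2$theta0 <- cfg$theta0 + 1.7
  r2 <- order_parameter(simulate_kuramoto(G, cfg2))$r
  expect_lt(max(abs(r1 - r2)), 1e-9)
  expect_true(all(r1 >= 0 & r1 <= 1 + 1e-12))
})

test_that("time to synchronization respects threshold and dwell rules", {
  mk <- function(r) structure(list(r = r, psi = rep(0, length(r)),
                                   times = seq_along(r) - 1),
                              class = "sync_series")
  expect_identical(time_to_sync(mk(rep(1, 10))), 0)
  expect_true(is.na(time_to_sync(mk(rep(0.5, 10)))))
  # crosses early but dips below threshold - dwell_drop: first crossing invalid
  r <- c(0.95, 0.95, 0.5, 0.92, 0.93, 0.96)
  expect_identical(time_to_sync(mk(r)), 3)
  expect_error(time_to_sync(mk(rep(1, 3)), r_threshold = 1.5), "\\(0, 1\\]")
})

test_that("a strongly coupled complete graph synchronizes quickly", {
  G <- matrix(1, 23, 23) - diag(23)
  cfg <- kuramoto_config(T = 200, seed = 4)
  s <- order_parameter(simulate_kuramoto(G, cfg))
  expect_gt(s$r[length(s$r)], 0.9)
  expect_lt(time_to_sync(s), 20)
})

test_that("snapshots report unit-circle coordinates at requested times", {
  G <- matrix(1, 23, 23) - diag(23)
  cfg <- kuramoto_config(T = 200, seed = 5)
  traj <- simulate_kuramoto(G, cfg)
  sn <- snapshot(traj, times = c(0, 150))
  expect_identical(nrow(sn), 46L)
  expect_equal(sn$re^2 + sn$im^2, rep(1, 46))
  r0 <- sn$r[sn$time == 0][1]
  expect_lt(r0, 0.5)                       # seeded uniform initial phases
  # fully locked by t = 150: all oscillators within a narrow arc
  late <- sn[sn$time == 150, ]
  ang <- atan2(late$im, late$re)
  spread <- max(ang) - min(ang)
  spread <- min(spread, 2 * pi - spread)
  expect_lt(spread, 0.5)
  expect_error(snapshot(traj, times = 300), "within")
})

test_that("coupling conversion transposes source-oriented matrices", {
  M <- matrix(0, 23, 23)
  M[2, 7] <- 0.5                            # channel 2 drives channel 7
  class(M) <- c("ste_matrix", class(M))
  G <- as_coupling(M)
  expect_identical(G[7, 2], 0.5)            # row = receiver in G
  expect_identical(G[2, 7], 0)
  expect_error(simulate_kuramoto(matrix(0, 5, 5), kuramoto_config(N = 23)),
               "does not match")
  bad <- matrix(0.1, 23, 23)
  expect_error(simulate_kuramoto(bad, kuramoto_config()), "zero diagonal")
})

test_that("match_total_weight rescales to the reference budget", {
  A <- matrix(runif(16), 4, 4); diag(A) <- 0
  B <- matrix(runif(16), 4, 4); diag(B) <- 0
  expect_equal(sum(match_total_weight(A, reference = B)), sum(B))
  expect_equal(sum(match_total_weight(A, total = 7)), 7)
  expect_error(match_total_weight(matrix(0, 3, 3), total = 1), "zero total")
})
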