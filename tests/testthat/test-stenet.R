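test_that("ordinal symbolization matches brute-force pattern enumeration", {
  cfg <- ste_config()
  expect_identical(unique(symbolize(c(1, 2, 3, 4, 5), cfg)$symbols), 0)
  expect_identical(unique(symbolize(rep(2, 10), cfg)$symbols), 0)

  # lexicographic rank by enumerating all 6 patterns of m = 3
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  brute_symbol <- function(w) {
    r <- rank(w, ties.method = "first") - 1
    for (p in seq_along(perms)) if (all(r == perms[[p]] - 1)) return(p - 1L)
  }
  set.seed(31)
  for (rep in 1:20) {
    x <- sample(1:5, 7, replace = TRUE)
    got <- symbolize(x, cfg)$symbols
    want <- vapply(1:5, function(i) brute_symbol(x[i:(i + 2)]), 0L)
    expect_identical(got, as.numeric(want))
  }
  expect_identical(symbolize(c(3, 1, 2), cfg)$symbols, 4)  # sorts as (2,3,1)

  s <- symbolize(rnorm(100), cfg)
  expect_length(s$symbols, 98L)
  expect_true(all(s$symbols %in% 0:5))
  expect_error(symbolize(c(1, 2), cfg), "too short")
})

test_that("STE matches the hand-enumerated oracle on short streams", {
  cfg2 <- ste_config(embed_m = 2)
  mk <- function(sym) structure(list(symbols = sym, n_source = length(sym) + 1,
                                     config = cfg2), class = "symbol_sequence")
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(10:30, 1)
    sj <- sample(0:1, n, replace = TRUE)
    si <- sample(0:1, n, replace = TRUE)
    got <- symbolic_transfer_entropy(mk(sj), mk(si), cfg2)
    want <- oracle_ste(sj, si, S = 2)
    expect_lt(abs(got - want), 1e-12)
  }
  # m = 3 oracle too
  cfg3 <- ste_config()
  mk3 <- function(sym) structure(list(symbols = sym, n_source = length(sym) + 2,
                                      config = cfg3), class = "symbol_sequence")
  for (rep in 1:10) {
    sj <- sample(0:5, 40, replace = TRUE)
    si <- sample(0:5, 40, replace = TRUE)
    expect_lt(abs(symbolic_transfer_entropy(mk3(sj), mk3(si), cfg3) -
                    oracle_ste(sj, si, S = 6)), 1e-12)
  }
})

test_that("STE is exactly zero for identical streams and nonnegative always", {
  cfg <- ste_config()
  x <- rnorm(2560)
  s <- symbolize(x, cfg)
  expect_identical(symbolic_transfer_entropy(s, s, cfg), 0)
  set.seed(23)
  for (rep in 1:10) {
    a <- symbolize(rnorm(500), cfg)
    b <- symbolize(rnorm(500), cfg)
    expect_gte(symbolic_transfer_entropy(a, b, cfg), 0)
  }
})

test_that("independent symbol streams give near-zero STE at large n", {
  cfg <- ste_config()
  set.seed(29)
  vals <- vapply(1:10, function(s) {
    mk <- function() structure(list(symbols = sample(0:5, 1e5, replace = TRUE),
                                    n_source = 1e5 + 2, config = cfg),
                               class = "symbol_sequence")
    symbolic_transfer_entropy(mk(), mk(), cfg)
  }, numeric(1))
  expect_lt(max(vals), 0.01)
})

test_that("STE recovers the direction of coupled AR pairs", {
  cfg <- ste_config()
  hits <- vapply(1:50, function(s) {
    p <- generate_coupled_pair(10000, 0.8, seed = 5000 + s)
    sx <- symbolize(p$x, cfg); sy <- symbolize(p$y, cfg)
    symbolic_transfer_entropy(sx, sy, cfg) >
      symbolic_transfer_entropy(sy, sx, cfg)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("STE matrix has zero diagonal, a low noise floor, and block structure", {
  set.seed(19)
  noise <- bandpass_filter(eeg_segment(matrix(rnorm(23 * 2560), 23), rate = 256))
  M <- ste_matrix(noise)
  expect_identical(unname(diag(unclass(M))), rep(0, 23))
  # empirical plug-in floor at n = 2558: the 0.02 operating threshold sits
  # at the upper edge of this distribution
  off <- M[row(M) != col(M)]
  expect_lt(mean(off), 0.015)
  expect_lt(max(off), 0.025)

  seg <- segment_fixture()$ictal
  Mi <- ste_matrix(seg)
  blk <- focus_block_channels()
  inblock <- unclass(Mi)[blk, blk]
  inblock <- inblock[row(inblock) != col(inblock)]
  outside <- unclass(Mi)[-blk, -blk]
  outside <- outside[row(outside) != col(outside)]
  expect_gt(mean(inblock), mean(outside))
})

test_that("channel relabelling permutes the STE matrix consistently", {
  seg <- segment_fixture()$interictal
  small <- eeg_segment(seg$data, rate = 256)
  M <- unclass(ste_matrix(small))
  set.seed(7)
  perm <- sample(23)
  segp <- eeg_segment(seg$data[perm, ], rate = 256)
  Mp <- unclass(ste_matrix(segp))
  expect_equal(unname(Mp), unname(M[perm, perm]), tolerance = 1e-12)
})

test_that("network thresholding retains exactly the suprathreshold edges", {
  m <- matrix(c(0, .05, .01, .03, 0, .09, 0, 0, 0), 3, byrow = TRUE)
  net <- threshold_network(m, 0.02)
  expect_identical(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight >= 0.02))

  empty <- threshold_network(matrix(0.001, 3, 3) - diag(0.001, 3), 0.02)
  expect_identical(nrow(empty$edges), 0L)
  expect_error(threshold_network(m, -0.1), ">= 0")

  # 0.08 network is a subset of the 0.02 network
  M <- unclass(ste_matrix(segment_fixture()$ictal))
  e02 <- threshold_network(M, 0.02)$edges
  e08 <- threshold_network(M, 0.08)$edges
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(e08) %in% key(e02)))
  expect_lte(nrow(e08), nrow(e02))
})
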