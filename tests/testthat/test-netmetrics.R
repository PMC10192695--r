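path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
path3[2, 3] <- path3[3, 2] <- 1
complete <- function(n) matrix(1, n, n) - diag(n)

test_that("closed-form metric values hold", {
  expect_equal(as.numeric(mean_shortest_path(as_net(path3))), 4 / 3)
  expect_equal(as.numeric(mean_shortest_path(as_net(complete(5)))), 1)
  expect_equal(global_efficiency(as_net(path3)), 5 / 6)
  expect_equal(global_efficiency(as_net(complete(6))), 1)
  expect_equal(clustering_coefficient(as_net(complete(4))), 1)
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(clustering_coefficient(as_net(star)), 0)
  # K_n Laplacian eigenvalues {0, n (x n-1)} -> ratio 1
  expect_equal(as.numeric(synchronizability(as_net(complete(7)))), 1)
  # C4 eigenvalues {0, 2, 2, 4} -> ratio 1/2
  c4 <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; c4[i, j] <- c4[j, i] <- 1 }
  expect_equal(as.numeric(synchronizability(as_net(c4))), 0.5)
  # two disjoint triangles: lambda_2 = 0, flagged
  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- complete(3); two_tri[4:6, 4:6] <- complete(3)
  s <- synchronizability(as_net(two_tri))
  expect_identical(as.numeric(s), 0)
  expect_identical(attr(s, "flag"), "disconnected")
  # empty graph: efficiency 0, path flagged
  none <- as_net(matrix(0, 4, 4))
  expect_equal(global_efficiency(none), 0)
  p <- mean_shortest_path(none)
  expect_true(is.na(p))
  expect_identical(attr(p, "flag"), "no_edges")
})

test_that("metrics equal brute-force oracles on random graphs up to n = 8", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    A <- random_adjacency(n, p = runif(1, 0.3, 0.8))
    if (all(A == 0)) next
    net <- as_net(A)
    expect_equal(as.numeric(mean_shortest_path(net)), oracle_mean_path(A))
    expect_equal(global_efficiency(net), oracle_efficiency(A))
    expect_equal(clustering_coefficient(net), oracle_clustering(A))
    expect_equal(as.numeric(synchronizability(net)),
                 oracle_laplacian_eigenratio(A), tolerance = 1e-7)
  }
})

test_that("weighted distances use inverse edge weight", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 2       # distance 1/2
  A[2, 3] <- A[3, 2] <- 4       # distance 1/4
  net <- as_net(A)
  expect_equal(as.numeric(mean_shortest_path(net, "weighted")),
               mean(c(0.5, 0.25, 0.75)))
  expect_equal(global_efficiency(net, "weighted"),
               mean(c(2, 4, 4 / 3)))
})

test_that("metrics agree with igraph on random graphs", {
  set.seed(123)
  for (rep in 1:10) {
    A <- random_adjacency(7, 0.5)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    net <- as_net(A)
    if (igraph::is_connected(g)) {
      expect_equal(as.numeric(mean_shortest_path(net)),
                   igraph::mean_distance(g))
    }
    expect_equal(clustering_coefficient(net),
                 mean(igraph::transitivity(g, type = "localundirected",
                                           isolates = "zero")))
    expect_equal(global_efficiency(net), igraph::global_efficiency(g))
  }
})

test_that("group summaries report means, sds and ictal-interictal differences", {
  net <- as_net(complete(5))
  r1 <- network_metrics(net, label = "ictal")
  r2 <- network_metrics(net, label = "interictal")
  gs <- group_summary(rbind(r1, r1, r2, r2))
  expect_true(all(gs$difference == 0))
  expect_error(group_summary(rbind(r1, r1)), "both labels")
  expect_error(group_summary(rbind(r1, r1, r2)), "at least 2")

  cf <- contrast_fixture()
  reports <- rbind(do.call(rbind, lapply(cf$ictal, `[[`, "metrics")),
                   do.call(rbind, lapply(cf$interictal, `[[`, "metrics")))
  gs2 <- group_summary(reports)
  expect_gt(gs2$difference[["synchronizability"]], 0)
  expect_gt(gs2$difference[["n_edges"]], 0)
})

test_that("the four group contrasts match the expected seizure-network directions", {
  cf <- contrast_fixture()
  m <- function(side, col) mean(vapply(cf[[side]],
                                       function(x) x$metrics[[col]],
                                       numeric(1)), na.rm = TRUE)
  expect_gt(m("ictal", "mean_shortest_path"), m("interictal", "mean_shortest_path"))
  expect_lt(m("ictal", "clustering_coefficient"), m("interictal", "clustering_coefficient"))
  expect_lt(m("ictal", "global_efficiency"), m("interictal", "global_efficiency"))
  expect_gt(m("ictal", "synchronizability"), m("interictal", "synchronizability"))
})
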