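# Independent brute-force oracles used to validate the package's metric and
# estimator implementations. These deliberately use different algorithms
# than the implementation (Bellman-Ford vs Floyd-Warshall, explicit triple
# enumeration vs matrix powers, characteristic-polynomial roots vs LAPACK).

# all-pairs shortest distances by per-source Bellman-Ford relaxation
oracle_distances <- function(A, weighted = FALSE) {
  n <- nrow(A)
  W <- matrix(Inf, n, n)
  W[A > 0] <- if (weighted) 1 / A[A > 0] else 1
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (src in seq_len(n)) {
    d <- rep(Inf, n); d[src] <- 0
    for (iter in seq_len(n)) {
      for (u in seq_len(n)) for (v in seq_len(n)) {
        if (is.finite(d[u]) && is.finite(W[u, v]) && d[u] + W[u, v] < d[v])
          d[v] <- d[u] + W[u, v]
      }
    }
    D[src, ] <- d
  }
  D
}

oracle_mean_path <- function(A) {
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

oracle_efficiency <- function(A) {
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

# per-node triangle fraction by explicit neighbour-pair enumeration
oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) { ci[i] <- 0; next }
    closed <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] > 0) closed <- closed + 1
    ci[i] <- closed / (k * (k - 1) / 2)
  }
  mean(ci)
}

# eigenvalues by classical Jacobi rotations: an accurate symmetric
# eigensolver independent of LAPACK
oracle_sym_eigenvalues <- function(M, sweeps = 100) {
  A <- M
  n <- nrow(A)
  for (sw in seq_len(sweeps)) {
    if (sqrt(sum(A[upper.tri(A)]^2)) < 1e-13) break
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      if (abs(A[p, q]) > 1e-15) {
        phi <- 0.5 * atan2(2 * A[p, q], A[q, q] - A[p, p])
        cs <- cos(phi); sn <- sin(phi)
        J <- diag(n); J[p, p] <- cs; J[q, q] <- cs
        J[p, q] <- sn; J[q, p] <- -sn
        A <- t(J) %*% A %*% J
      }
    }
  }
  sort(diag(A))
}

oracle_laplacian_eigenratio <- function(A) {
  Ab <- (A > 0) * 1
  L <- diag(rowSums(Ab)) - Ab
  ev <- oracle_sym_eigenvalues(L)
  n <- nrow(L)
  lmax <- ev[n]
  l2 <- ev[2]
  if (lmax <= 1e-9) return(0)
  if (l2 <= 1e-7 * max(lmax, 1)) return(0)
  l2 / lmax
}

# brute-force symbolic transfer entropy by explicit probability tables
oracle_ste <- function(sj, si, S, base = 2) {
  n <- length(si)
  tab <- table(factor(si[-1], levels = 0:(S - 1)),
               factor(si[-n], levels = 0:(S - 1)),
               factor(sj[-n], levels = 0:(S - 1)))
  total <- sum(tab)
  ste <- 0
  for (a in 1:S) for (b in 1:S) for (c in 1:S) {
    p_abc <- tab[a, b, c] / total
    if (p_abc == 0) next
    p_bc <- sum(tab[, b, c]) / total
    p_ab <- sum(tab[a, b, ]) / total
    p_b <- sum(tab[, b, ]) / total
    ste <- ste + p_abc * log((p_abc / p_bc) / (p_ab / p_b), base = base)
  }
  max(ste, 0)
}

# brute-force AUC over all positive/negative pairs, ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# seeded random symmetric adjacency on n nodes
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(runif(sum(up)) < p)
  A <- A + t(A)
  A
}

# wrap a plain matrix as the brain_network the metric functions accept
as_net <- function(A) {
  n <- nrow(A)
  idx <- which(A > 0 & row(A) != col(A), arr.ind = TRUE)
  structure(list(nodes = paste0("n", seq_len(n)),
                 edges = data.frame(from = idx[, 1], to = idx[, 2],
                                    weight = A[idx]),
                 adjacency = A, threshold = 0, n_nodes = n,
                 density = nrow(idx) / (n * (n - 1))),
            class = "brain_network")
}
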