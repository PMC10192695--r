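# Graph metrics are computed on the symmetrized graph: undirected weight =
# max of the two directed weights, so any detected link is preserved.

# symmetrized weighted adjacency from a brain_network or square matrix
symmetrize_adjacency <- function(net) {
  A <- if (inherits(net, "brain_network")) net$adjacency else net
  if (!is.matrix(A) || nrow(A) != ncol(A)) stopf("need a square adjacency matrix")
  W <- pmax(A, t(A))
  diag(W) <- 0
  W
}

# all-pairs shortest path distances (Floyd-Warshall); cost = 1 per edge in
# binary mode, 1/weight in weighted mode; Inf for unreachable
all_pairs_distances <- function(W, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  has <- W > 0
  D[has] <- if (mode == "binary") 1 else 1 / W[has]
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)
    upd <- Dk < D
    D[upd] <- Dk[upd]
  }
  D
}

#' Mean shortest path length
#'
#' Average shortest-path length over all reachable ordered node pairs of the
#' symmetrized graph. Binary mode counts hops; weighted mode uses edge
#' distance `1/weight`. Unreachable pairs are excluded from the mean and
#' their fraction is reported as the attribute `unreachable_frac`.
#'
#' @param net A `brain_network` (or square weighted adjacency matrix).
#' @param mode "binary" (default) or "weighted".
#' @return Mean path length (NA with attribute `flag = "no_edges"` for an
#'   edgeless graph), with attribute `unreachable_frac`.
#' @export
mean_shortest_path <- function(net, mode = c("binary", "weighted")) {
  W <- symmetrize_adjacency(net)
  if (nrow(W) < 2L) stopf("need at least 2 nodes")
  D <- all_pairs_distances(W, mode)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  if (!any(W > 0)) {
    out <- NA_real_
    attr(out, "flag") <- "no_edges"
    attr(out, "unreachable_frac") <- 1
    return(out)
  }
  out <- mean(off[finite])
  attr(out, "unreachable_frac") <- mean(!finite)
  out
}

#' Mean clustering coefficient
#'
#' Watts-Strogatz clustering on the symmetrized binary graph: per node the
#' fraction of connected neighbour pairs; nodes of degree < 2 contribute 0;
#' the mean over all nodes is returned.
#'
#' @param net A `brain_network` (or square weighted adjacency matrix).
#' @return Mean clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  W <- symmetrize_adjacency(net)
  if (nrow(W) < 3L) stopf("need at least 3 nodes")
  A <- (W > 0) * 1
  k <- rowSums(A)
  A3 <- A %*% A %*% A
  ci <- ifelse(k >= 2, diag(A3) / (k * (k - 1)), 0)
  mean(ci)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance on the
#' symmetrized graph; unreachable pairs contribute 0. Equals 1 for a
#' complete unweighted graph.
#'
#' @param net A `brain_network` (or square weighted adjacency matrix).
#' @param mode "binary" (default) or "weighted".
#' @return Efficiency in \[0, 1\] (binary mode).
#' @export
global_efficiency <- function(net, mode = c("binary", "weighted")) {
  W <- symmetrize_adjacency(net)
  if (nrow(W) < 2L) stopf("need at least 2 nodes")
  D <- all_pairs_distances(W, mode)
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Laplacian-eigenratio synchronizability
#'
#' Ratio `lambda_2 / lambda_max` of the combinatorial Laplacian of the
#' symmetrized binary graph. Equals 1 for a complete graph; a disconnected
#' graph returns 0 with attribute `flag = "disconnected"`.
#'
#' @param net A `brain_network` (or square weighted adjacency matrix).
#' @return Eigenratio in \[0, 1\].
#' @export
synchronizability <- function(net) {
  W <- symmetrize_adjacency(net)
  A <- (W > 0) * 1
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  lmax <- ev[length(ev)]
  l2 <- ev[2]
  if (lmax <= 1e-12) {
    out <- 0
    attr(out, "flag") <- "empty"
    return(out)
  }
  if (l2 <= 1e-9 * lmax) {
    out <- 0
    attr(out, "flag") <- "disconnected"
    return(out)
  }
  l2 / lmax
}

#' All network metrics of one network
#'
#' One row with the four summary properties (binary mean shortest path,
#' clustering coefficient, binary global efficiency, Laplacian-eigenratio
#' synchronizability), their weighted-path variants, and bookkeeping columns.
#'
#' @param net A `brain_network`.
#' @param label Optional label column.
#' @return A one-row data.frame (class `metrics_report`).
#' @export
network_metrics <- function(net, label = NA_character_) {
  msp_b <- mean_shortest_path(net, "binary")
  msp_w <- mean_shortest_path(net, "weighted")
  out <- data.frame(
    label = label,
    mean_shortest_path = as.numeric(msp_b),
    mean_shortest_path_weighted = as.numeric(msp_w),
    clustering_coefficient = clustering_coefficient(net),
    global_efficiency = global_efficiency(net, "binary"),
    global_efficiency_weighted = global_efficiency(net, "weighted"),
    synchronizability = as.numeric(synchronizability(net)),
    n_nodes = net$n_nodes,
    n_edges = nrow(net$edges),
    density = net$density,
    unreachable_frac = attr(msp_b, "unreachable_frac"),
    stringsAsFactors = FALSE)
  class(out) <- c("metrics_report", class(out))
  out
}

#' Group summary of metric reports
#'
#' Per-label mean and SD of each metric plus the difference of means
#' (ictal minus interictal). No hypothesis test is performed.
#'
#' @param reports A data.frame of stacked [network_metrics()] rows with a
#'   `label` column, or a list of such rows.
#' @return List with `summary` (data.frame: metric, label, mean, sd) and
#'   `difference` (named vector of ictal - interictal mean differences).
#' @export
group_summary <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  labs <- unique(reports$label)
  if (length(labs) < 2L) stopf("need reports for both labels")
  counts <- table(reports$label)
  if (any(counts < 2L)) stopf("need at least 2 reports per label")
  metrics <- c("mean_shortest_path", "clustering_coefficient",
               "global_efficiency", "synchronizability", "n_edges")
  rows <- list()
  for (m in metrics) for (l in labs) {
    v <- reports[[m]][reports$label == l]
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, label = l, mean = mean(v, na.rm = TRUE),
      sd = sd(v, na.rm = TRUE), stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  diffs <- vapply(metrics, function(m) {
    mi <- summary$mean[summary$metric == m & summary$label == "ictal"]
    mn <- summary$mean[summary$metric == m & summary$label == "interictal"]
    if (length(mi) == 1L && length(mn) == 1L) mi - mn else NA_real_
  }, numeric(1))
  list(summary = summary, difference = diffs)
}
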