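#' Configuration for symbolic transfer entropy
#'
#' Ordinal-pattern symbolization with embedding length `embed_m` and delay
#' `delay_tau`, symbol-history lengths `history_k` (target) and `history_l`
#' (source), and logarithm base (2, so results are in bits).
#'
#' @param embed_m Ordinal pattern length (>= 2, default 3: six symbols).
#' @param delay_tau Embedding delay in samples (>= 1, default 1).
#' @param history_k,history_l Symbol-history lengths (>= 1, default 1 each:
#'   single-symbol conditioning).
#' @param log_base Logarithm base (default 2).
#' @return An object of class `ste_config`.
#' @export
ste_config <- function(embed_m = 3L, delay_tau = 1L,
                       history_k = 1L, history_l = 1L, log_base = 2) {
  if (embed_m < 2L) stopf("`embed_m` must be >= 2")
  if (delay_tau < 1L) stopf("`delay_tau` must be >= 1")
  if (history_k < 1L || history_l < 1L) stopf("history lengths must be >= 1")
  structure(list(embed_m = as.integer(embed_m),
                 delay_tau = as.integer(delay_tau),
                 history_k = as.integer(history_k),
                 history_l = as.integer(history_l),
                 log_base = log_base),
            class = "ste_config")
}

#' Ordinal-pattern symbolization
#'
#' Maps each window of `embed_m` values at spacing `delay_tau` to the
#' lexicographic rank (0-based, in `0 .. m!-1`) of its rank-order pattern.
#' Ties are broken by position: the earlier index counts as smaller, so a
#' constant window always maps to the ascending pattern (symbol 0).
#'
#' @param x Numeric vector, length > `(embed_m - 1) * delay_tau`.
#' @param cfg An [ste_config()].
#' @return A `symbol_sequence`: list with integer `symbols`, `n_source`,
#'   and the config.
#' @export
symbolize <- function(x, cfg = ste_config()) {
  m <- cfg$embed_m; tau <- cfg$delay_tau
  n <- length(x)
  span <- (m - 1L) * tau
  if (n <= span) stopf("series too short: need length > %d", span)
  ns <- n - span
  # ranks within each window via pairwise comparisons (vectorized over windows)
  cols <- lapply(0:(m - 1L), function(k) x[(1L + k * tau):(ns + k * tau)])
  rank_of <- vector("list", m)
  for (k in seq_len(m)) {
    r <- integer(ns)
    for (j in seq_len(m)) {
      if (j == k) next
      r <- r + as.integer(cols[[j]] < cols[[k]] |
                            (cols[[j]] == cols[[k]] & j < k))
    }
    rank_of[[k]] <- r                    # 0-based rank of position k
  }
  # Lehmer code: lexicographic rank of the rank sequence as a permutation
  sym <- integer(ns)
  fact <- factorial((m - 1L):0L)
  for (k in seq_len(m - 1L)) {
    smaller_later <- integer(ns)
    for (j in (k + 1L):m)
      smaller_later <- smaller_later + as.integer(rank_of[[j]] < rank_of[[k]])
    sym <- sym + smaller_later * fact[k]
  }
  structure(list(symbols = sym, n_source = n, config = cfg),
            class = "symbol_sequence")
}

# compound state index from `h` consecutive symbols (oldest first); state i
# ends at symbol position i + h - 1; 0-based states over alphabet size S^h
compound_states <- function(sym, h, S) {
  ns <- length(sym) - h + 1L
  st <- numeric(ns)
  for (d in seq_len(h)) st <- st * S + sym[d:(d + ns - 1L)]
  st
}

#' Symbolic transfer entropy between two symbol sequences
#'
#' Plug-in estimate (in bits by default) of the transfer entropy from source
#' J to target I on the symbol level:
#' `STE(J->I) = sum p(i_{n+1}, i_n, j_n) * log[ p(i_{n+1} | i_n, j_n) /
#' p(i_{n+1} | i_n) ]`, with histories of `history_k` target symbols and
#' `history_l` source symbols. Zero-probability terms contribute 0 and the
#' result is floored at 0.
#'
#' @param sym_j,sym_i `symbol_sequence`s of equal length (source, target).
#' @param cfg An [ste_config()]; must match the symbolization config.
#' @return STE in bits (nonnegative scalar).
#' @export
symbolic_transfer_entropy <- function(sym_j, sym_i, cfg = ste_config()) {
  if (!inherits(sym_j, "symbol_sequence") || !inherits(sym_i, "symbol_sequence"))
    stopf("inputs must be symbol_sequence objects")
  a_i <- sym_i$symbols; a_j <- sym_j$symbols
  if (length(a_i) != length(a_j)) stopf("symbol sequences must have equal length")
  S <- factorial(cfg$embed_m)
  k <- cfg$history_k; l <- cfg$history_l
  h <- max(k, l)
  ns <- length(a_i)
  if (ns < h + 1L) stopf("symbol sequences too short for the history lengths")
  # align histories ending at time t = h .. ns-1 (1-based: positions h..ns-1)
  ipast <- compound_states(a_i, k, S)          # ends at positions k..ns
  jpast <- compound_states(a_j, l, S)          # ends at positions l..ns
  nt <- ns - h                                 # transitions
  inext <- a_i[(h + 1L):ns]
  ip <- ipast[(h - k + 1L):(h - k + nt)]
  jp <- jpast[(h - l + 1L):(h - l + nt)]
  Sk <- S^k; Sl <- S^l
  idx <- (inext * Sk + ip) * Sl + jp + 1
  counts <- tabulate(idx, nbins = S * Sk * Sl)
  arr <- array(counts, dim = c(Sl, Sk, S))     # [j_past, i_past, i_next]
  c_bc <- apply(arr, c(1, 2), sum)             # (j_past, i_past)
  c_ab <- apply(arr, c(2, 3), sum)             # (i_past, i_next)
  c_b <- rowSums(c_ab)                         # i_past marginal
  nz <- which(arr > 0, arr.ind = TRUE)
  cj <- nz[, 1L]; ci <- nz[, 2L]; ca <- nz[, 3L]
  c_abc <- arr[nz]
  terms <- c_abc * log((c_abc * c_b[ci]) /
                         (c_ab[cbind(ci, ca)] * c_bc[cbind(cj, ci)]))
  max(sum(terms) / sum(c_abc) / log(cfg$log_base), 0)
}

#' Pairwise STE matrix of a segment
#'
#' Symbolizes each channel once and computes the symbolic transfer entropy
#' for every ordered channel pair. Row = source channel J, column = target
#' channel I; the diagonal is exactly zero.
#'
#' @param seg An `eeg_segment` (23 channels unless overridden).
#' @param cfg An [ste_config()].
#' @param allow_other_channels Set `TRUE` to relax the 23-channel contract.
#' @return An `ste_matrix`: channels x channels matrix (bits) with channel
#'   names, class attribute `ste_matrix`.
#' @export
ste_matrix <- function(seg, cfg = ste_config(), allow_other_channels = FALSE) {
  if (!inherits(seg, "eeg_segment")) stopf("`seg` must be an eeg_segment")
  check_channels(seg$data, allow_other_channels)
  nch <- nrow(seg$data)
  syms <- lapply(seq_len(nch), function(ch) symbolize(seg$data[ch, ], cfg))
  M <- matrix(0, nch, nch)
  for (j in seq_len(nch)) for (i in seq_len(nch)) {
    if (i == j) next
    M[j, i] <- symbolic_transfer_entropy(syms[[j]], syms[[i]], cfg)
  }
  nm <- rownames(seg$data)
  if (is.null(nm)) nm <- paste0("ch", seq_len(nch))
  dimnames(M) <- list(source = nm, target = nm)
  class(M) <- c("ste_matrix", class(M))
  M
}

#' Threshold an STE matrix into a directed brain network
#'
#' Retains every directed edge whose STE weight is at least `threshold`
#' (and positive). The reference operating threshold is 0.02 bits; 0.08 is
#' the sparser display threshold.
#'
#' @param m An `ste_matrix` (or plain square matrix with zero diagonal).
#' @param threshold Nonnegative edge threshold (default 0.02).
#' @return A `brain_network`: list with `nodes`, `edges` (data.frame from/
#'   to/weight), `adjacency` (thresholded weighted matrix, row = source),
#'   `threshold`, `n_nodes`, `density`.
#' @export
threshold_network <- function(m, threshold = 0.02) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stopf("`m` must be a square matrix")
  assert_scalar_num(threshold, "threshold")
  if (threshold < 0) stopf("`threshold` must be >= 0")
  n <- nrow(m)
  A <- unclass(m)
  keep <- A >= threshold & A > 0
  diag(keep) <- FALSE
  A[!keep] <- 0
  nodes <- rownames(m)
  if (is.null(nodes)) nodes <- paste0("ch", seq_len(n))
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                      weight = A[idx], stringsAsFactors = FALSE)
  edges <- edges[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, adjacency = A,
                 threshold = threshold, n_nodes = n,
                 density = nrow(edges) / (n * (n - 1))),
            class = "brain_network")
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("<brain_network> %d nodes, %d directed edges (threshold %.3g, density %.3f)\n",
              x$n_nodes, nrow(x$edges), x$threshold, x$density))
  invisible(x)
}

#' Export an STE matrix as CSV
#'
#' @param m An `ste_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ste_csv <- function(m, path) {
  df <- as.data.frame(unclass(m))
  df <- cbind(channel = rownames(m), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
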