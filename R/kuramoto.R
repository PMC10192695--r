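#' Kuramoto simulation configuration
#'
#' Parameters for integrating `dtheta_i/dt = omega_i + (K/N) * sum_j G_ij *
#' sin(theta_j - theta_i)` with fixed-step classical RK4.
#'
#' Intrinsic frequencies default to the deterministic even grid
#' `omega_i = i/(N-1)` over \[0, 1\]; set `random_omega = TRUE` to draw them
#' uniformly at random instead. Initial phases are drawn uniformly over
#' \[0, 2*pi) from `seed`.
#'
#' @param N Number of oscillators (default 23).
#' @param K Coupling constant (default 3.5, >= 0).
#' @param omega Optional intrinsic frequency vector (length N).
#' @param theta0 Optional initial phases (length N).
#' @param dt Integration step in seconds (default 0.01, > 0).
#' @param T Time horizon (default 1000).
#' @param save_stride Save every `save_stride`-th step (default 10).
#' @param seed Integer seed for phases (and frequencies if random).
#' @param random_omega Draw omega ~ U\[0,1\] instead of the even grid.
#' @return An object of class `kuramoto_config`.
#' @export
kuramoto_config <- function(N = 23L, K = 3.5, omega = NULL, theta0 = NULL,
                            dt = 0.01, T = 1000, save_stride = 10L,
                            seed = 1L, random_omega = FALSE) {
  if (K < 0) stopf("`K` must be >= 0")
  if (dt <= 0) stopf("`dt` must be > 0")
  if (T < dt) stopf("`T` must be >= dt")
  N <- as.integer(N)
  if (is.null(omega))
    omega <- if (random_omega) with_seed(seed + 1L, runif(N))
             else if (N > 1L) (seq_len(N) - 1) / (N - 1) else 0
  if (length(omega) != N) stopf("`omega` must have length N")
  if (is.null(theta0)) theta0 <- with_seed(seed, runif(N, 0, 2 * pi))
  if (length(theta0) != N) stopf("`theta0` must have length N")
  structure(list(N = N, K = K, omega = omega, theta0 = theta0, dt = dt,
                 T = T, save_stride = as.integer(save_stride),
                 seed = as.integer(seed)),
            class = "kuramoto_config")
}

#' Integrate the Kuramoto model on a coupling matrix
#'
#' `G[i, j]` is the coupling weight with which oscillator j acts on
#' oscillator i (the equation's G_ij). Use [as_coupling()] to convert an STE
#' matrix or thresholded brain network (whose rows are sources) into this
#' orientation.
#'
#' @param G Nonnegative N x N coupling matrix with zero diagonal.
#' @param cfg A [kuramoto_config()] with matching N.
#' @return A `kuramoto_trajectory`: list with `phases` (saved steps x N,
#'   radians, unwrapped), `times` (s), and the config.
#' @export
simulate_kuramoto <- function(G, cfg = kuramoto_config()) {
  if (!is.matrix(G) || nrow(G) != ncol(G)) stopf("`G` must be square")
  if (nrow(G) != cfg$N) stopf("dim(G) = %d does not match N = %d", nrow(G), cfg$N)
  if (any(G < 0)) stopf("`G` must be nonnegative")
  if (any(diag(G) != 0)) stopf("`G` must have a zero diagonal")
  n_steps <- round(cfg$T / cfg$dt)
  phases <- kuramoto_rk4_cpp(unname(G), cfg$omega, cfg$theta0, cfg$K,
                             cfg$dt, n_steps, cfg$save_stride)
  times <- seq(0, by = cfg$dt * cfg$save_stride, length.out = nrow(phases))
  structure(list(phases = phases, times = times, config = cfg),
            class = "kuramoto_trajectory")
}

#' @export
print.kuramoto_trajectory <- function(x, ...) {
  cat(sprintf("<kuramoto_trajectory> N=%d, t in [0, %g] s, %d saved steps\n",
              x$config$N, max(x$times), nrow(x$phases)))
  invisible(x)
}

#' Coupling matrix for the Kuramoto stage
#'
#' Transposes an STE matrix or a thresholded network's adjacency (row =
#' source channel) into the simulator's receiver-oriented convention
#' `G[i, j]` = weight of j acting on i. The thresholded network is the
#' default coupling; pass an `ste_matrix` for raw (unthresholded) coupling.
#'
#' @param x A `brain_network` or `ste_matrix`.
#' @return Matrix suitable for [simulate_kuramoto()].
#' @export
as_coupling <- function(x) {
  A <- if (inherits(x, "brain_network")) x$adjacency else unclass(x)
  if (!is.matrix(A) || nrow(A) != ncol(A)) stopf("`x` must be square")
  t(A)
}

#' Common coupling scale for cross-network synchronization comparisons
#'
#' Raw symbolic-transfer-entropy edge weights are a few hundredths of a bit,
#' far too small for the Kuramoto coupling term `(K/N) * G_ij` to compete
#' with the \[0, 1\] spread of natural frequencies within the simulated
#' horizon. Comparing synchronization behaviour across networks therefore
#' applies one common multiplicative scale to every network -- preserving
#' the relative coupling strength between regimes, which is the quantity the
#' ictal/interictal contrast rests on -- rather than normalizing each
#' network individually. The default (130) places the denser, more strongly
#' coupled networks inside the locking regime within a 1000 s horizon while
#' weaker networks remain incoherent.
#'
#' @return The scale constant.
#' @export
sync_coupling_scale <- function() 130

#' Synchronization comparison between two brain networks
#'
#' Scales both coupling matrices by the same factor
#' ([sync_coupling_scale()]), integrates the Kuramoto model with a shared
#' configuration, and reports each network's order-parameter series and time
#' to sustained synchronization.
#'
#' @param net_a,net_b `brain_network`s (or coupling matrices).
#' @param cfg A [kuramoto_config()].
#' @param scale Common coupling scale.
#' @return List of two elements (`a`, `b`), each with `sync` (a
#'   `sync_series`) and `tts` (time to synchronization, `NA` if never).
#' @export
compare_sync <- function(net_a, net_b, cfg = kuramoto_config(),
                         scale = sync_coupling_scale()) {
  one <- function(x) {
    G <- if (inherits(x, "brain_network")) as_coupling(x) else x
    traj <- simulate_kuramoto(G * scale, cfg)
    s <- order_parameter(traj)
    list(sync = s, tts = time_to_sync(s))
  }
  list(a = one(net_a), b = one(net_b))
}

#' Rescale a coupling matrix to a reference total weight
#'
#' Comparing synchronization speed across networks requires comparable
#' overall coupling budgets; this scales `G` so its total weight equals that
#' of `reference` (or an explicit `total`).
#'
#' @param G Coupling matrix.
#' @param reference Matrix whose total weight is the target (or NULL).
#' @param total Explicit target total (used if `reference` is NULL).
#' @return Rescaled matrix.
#' @export
match_total_weight <- function(G, reference = NULL, total = NULL) {
  target <- if (!is.null(reference)) sum(reference) else total
  if (is.null(target)) stopf("need `reference` or `total`")
  s <- sum(G)
  if (s <= 0) stopf("`G` has zero total weight")
  G * (target / s)
}

#' Order-parameter time series
#'
#' Mean-field modulus r(t) and mean phase psi(t), defined by
#' \eqn{r(t) e^{j\psi(t)} = N^{-1} \sum_i e^{j\theta_i(t)}}. r = 1 iff all
#' phases coincide (mod 2*pi); r near 0 for incoherent phases.
#'
#' @param traj A [simulate_kuramoto()] trajectory.
#' @return A `sync_series`: list with `r`, `psi`, `times`.
#' @export
order_parameter <- function(traj) {
  if (!inherits(traj, "kuramoto_trajectory")) stopf("`traj` must be a kuramoto_trajectory")
  z <- rowMeans(exp(1i * traj$phases))
  structure(list(r = Mod(z), psi = Arg(z), times = traj$times),
            class = "sync_series")
}

#' Time to reach sustained synchronization
#'
#' First time at which `r(t) >= r_threshold` and `r` stays at or above
#' `r_threshold - dwell_drop` for the rest of the horizon; `NA` if never.
#'
#' @param series A [order_parameter()] result.
#' @param r_threshold Threshold in (0, 1\] (default 0.9).
#' @param dwell_drop Allowed dip below the threshold afterwards (default 0.05).
#' @return Time in seconds, or `NA_real_`.
#' @export
time_to_sync <- function(series, r_threshold = 0.9, dwell_drop = 0.05) {
  if (!inherits(series, "sync_series")) stopf("`series` must be a sync_series")
  if (r_threshold <= 0 || r_threshold > 1) stopf("`r_threshold` must be in (0, 1]")
  r <- series$r
  n <- length(r)
  ok_after <- rev(cumprod(rev(r >= r_threshold - dwell_drop))) > 0
  hit <- which(r >= r_threshold & ok_after)
  if (length(hit) == 0L) return(NA_real_)
  series$times[hit[1L]]
}

#' Complex-plane snapshots of oscillator phases
#'
#' Unit-circle coordinates `exp(j theta_i(t))` at the requested times
#' (defaults 0, 150 and 1000 s), with the instantaneous order parameter.
#'
#' @param traj A [simulate_kuramoto()] trajectory.
#' @param times Numeric vector of times within the horizon.
#' @return Data.frame with `time`, `oscillator`, `re`, `im`, `r`.
#' @export
snapshot <- function(traj, times = c(0, 150, 1000)) {
  if (!inherits(traj, "kuramoto_trajectory")) stopf("`traj` must be a kuramoto_trajectory")
  if (any(times < 0 | times > max(traj$times) + 1e-9))
    stopf("requested times must lie within [0, %g]", max(traj$times))
  out <- lapply(times, function(tm) {
    k <- which.min(abs(traj$times - tm))
    th <- traj$phases[k, ]
    data.frame(time = tm, oscillator = seq_along(th),
               re = cos(th), im = sin(th),
               r = Mod(mean(exp(1i * th))))
  })
  do.call(rbind, out)
}
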