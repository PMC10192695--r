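// Fixed-step classical RK4 integrator for the Kuramoto phase model
//   dtheta_i/dt = omega_i + (K/N) * sum_j G[i,j] * sin(theta_j - theta_i)
// G[i,j] is the coupling weight of oscillator j acting on i.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void deriv(const std::vector<double>& th, const double* G,
                  const double* omega, double KoverN, int N,
                  std::vector<double>& dth) {
  for (int i = 0; i < N; ++i) {
    double acc = 0.0;
    const double thi = th[i];
    for (int j = 0; j < N; ++j) {
      const double g = G[i + (size_t)N * j];   // column-major [i,j]
      if (g != 0.0) acc += g * std::sin(th[j] - thi);
    }
    dth[i] = omega[i] + KoverN * acc;
  }
}

// [[Rcpp::export]]
NumericMatrix kuramoto_rk4_cpp(NumericMatrix G, NumericVector omega,
                               NumericVector theta0, double K,
                               double dt, int n_steps, int save_stride) {
  const int N = G.nrow();
  const double KoverN = K / (double)N;
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> k1(N), k2(N), k3(N), k4(N), tmp(N);
  const int n_saved = n_steps / save_stride + 1;
  NumericMatrix out(n_saved, N);
  for (int i = 0; i < N; ++i) out(0, i) = th[i];

  int row = 1;
  for (int step = 1; step <= n_steps; ++step) {
    deriv(th, G.begin(), omega.begin(), KoverN, N, k1);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + 0.5 * dt * k1[i];
    deriv(tmp, G.begin(), omega.begin(), KoverN, N, k2);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + 0.5 * dt * k2[i];
    deriv(tmp, G.begin(), omega.begin(), KoverN, N, k3);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + dt * k3[i];
    deriv(tmp, G.begin(), omega.begin(), KoverN, N, k4);
    for (int i = 0; i < N; ++i)
      th[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (step % save_stride == 0 && row < n_saved) {
      for (int i = 0; i < N; ++i) out(row, i) = th[i];
      ++row;
    }
  }
  return out;
}
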