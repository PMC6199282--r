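// Monte Carlo kernel for the heterogeneous-environment spatial prisoner's
// dilemma. Sites are indexed 0..N-1 in R's column-major order
// (s = row + col*L, 0-based). All randomness comes from R's RNG stream so
// runs seeded with set.seed() are bit-reproducible across R and C++.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// neighbour order per site: up, down, left, right (periodic wrap);
// must match the R-level convention in selection_probabilities().
static void build_neighbors(int L, std::vector<int> &nbr) {
  const int N = L * L;
  nbr.resize(4 * static_cast<size_t>(N));
  for (int col = 0; col < L; ++col) {
    for (int row = 0; row < L; ++row) {
      const int s = row + col * L;
      nbr[4 * s + 0] = (row == 0 ? L - 1 : row - 1) + col * L;
      nbr[4 * s + 1] = (row == L - 1 ? 0 : row + 1) + col * L;
      nbr[4 * s + 2] = row + (col == 0 ? L - 1 : col - 1) * L;
      nbr[4 * s + 3] = row + (col == L - 1 ? 0 : col + 1) * L;
    }
  }
}

// weak PD payoff of site s against its 4 neighbours: R=1, T=b, P=S=0,
// so the payoff is (#cooperating neighbours) * (1 if C, b if D).
static inline double payoff_of(int s, const int *strat, const int *nbr,
                               double b) {
  const int nc = strat[nbr[4 * s]] + strat[nbr[4 * s + 1]] +
                 strat[nbr[4 * s + 2]] + strat[nbr[4 * s + 3]];
  return strat[s] ? static_cast<double>(nc) : b * nc;
}

// Quenched fields: environment H (mean neighbour h) and cumulative softmax
// selection weights exp(alpha*h_y) over the 4 neighbours (max-shifted for
// numerical stability). Both are fixed for a whole run.
static void build_fields(const double *h, const std::vector<int> &nbr, int N,
                         double alpha, std::vector<double> &env,
                         std::vector<double> &selcum) {
  env.resize(N);
  selcum.resize(4 * static_cast<size_t>(N));
  for (int s = 0; s < N; ++s) {
    const double h0 = h[nbr[4 * s]], h1 = h[nbr[4 * s + 1]],
                 h2 = h[nbr[4 * s + 2]], h3 = h[nbr[4 * s + 3]];
    env[s] = (h0 + h1 + h2 + h3) / 4.0;
    const double m = std::max(std::max(h0, h1), std::max(h2, h3));
    const double w0 = std::exp(alpha * (h0 - m));
    const double w1 = std::exp(alpha * (h1 - m));
    const double w2 = std::exp(alpha * (h2 - m));
    const double w3 = std::exp(alpha * (h3 - m));
    const double tot = w0 + w1 + w2 + w3;
    selcum[4 * s + 0] = w0 / tot;
    selcum[4 * s + 1] = selcum[4 * s + 0] + w1 / tot;
    selcum[4 * s + 2] = selcum[4 * s + 1] + w2 / tot;
    selcum[4 * s + 3] = 1.0;
  }
}

static void check_inputs(const IntegerMatrix &strategies,
                         const NumericMatrix &h_field) {
  const int L = strategies.nrow();
  if (L < 2 || strategies.ncol() != L)
    stop("strategies must be a square matrix with side >= 2");
  if (h_field.nrow() != L || h_field.ncol() != L)
    stop("h_field dimensions must match strategies");
  for (int i = 0; i < L * L; ++i)
    if (strategies[i] != 0 && strategies[i] != 1)
      stop("strategies must be coded 0 (D) / 1 (C)");
}

struct StepOut {
  int focal, neighbor;
  double f_focal, f_neighbor;
  bool adopted, flipped;
};

// One elementary update. RNG draw order is fixed: (focal if not forced),
// neighbour, adoption — the adoption draw happens even when s_x == s_y so
// the stream position does not depend on the configuration.
static inline StepOut do_step(int *strat, const std::vector<int> &nbr,
                              const std::vector<double> &env,
                              const std::vector<double> &selcum, int N,
                              double b, double u, double K, int focal,
                              bool apply) {
  int x = focal;
  if (x < 0) {
    x = static_cast<int>(unif_rand() * N);
    if (x >= N) x = N - 1;
  }
  const double fx = (1.0 - u) * payoff_of(x, strat, nbr.data(), b) + u * env[x];
  const double r = unif_rand();
  int k = 0;
  while (k < 3 && r >= selcum[4 * x + k]) ++k;
  const int y = nbr[4 * x + k];
  const double fy = (1.0 - u) * payoff_of(y, strat, nbr.data(), b) + u * env[y];
  const double w = 1.0 / (1.0 + std::exp((fx - fy) / K));
  const bool adopted = unif_rand() < w;
  const bool flipped = adopted && (strat[x] != strat[y]);
  if (apply && adopted) strat[x] = strat[y];
  StepOut out;
  out.focal = x;
  out.neighbor = y;
  out.f_focal = fx;
  out.f_neighbor = fy;
  out.adopted = adopted;
  out.flipped = flipped;
  return out;
}

// Run n_sweeps full Monte Carlo steps (L^2 elementary updates each) on
// `strategies`, mutating it in place. Returns the cooperator fraction after
// each executed sweep. With stop_when_absorbed, stops at the end of the
// sweep in which an absorbing state (all C or all D) is reached.
// [[Rcpp::export]]
List cpp_run_sweeps(IntegerMatrix strategies, NumericMatrix h_field, double b,
                    double u, double alpha, double K, int n_sweeps,
                    bool stop_when_absorbed) {
  check_inputs(strategies, h_field);
  const int L = strategies.nrow(), N = L * L;
  std::vector<int> nbr;
  build_neighbors(L, nbr);
  std::vector<double> env, selcum;
  build_fields(h_field.begin(), nbr, N, alpha, env, selcum);
  int *strat = strategies.begin();

  int ncoop = 0;
  for (int i = 0; i < N; ++i) ncoop += strat[i];
  bool absorbed = (ncoop == 0 || ncoop == N);

  NumericVector rho(n_sweeps);
  int executed = 0;
  for (int t = 0; t < n_sweeps; ++t) {
    if (stop_when_absorbed && absorbed) break;
    for (int i = 0; i < N; ++i) {
      StepOut ev = do_step(strat, nbr, env, selcum, N, b, u, K, -1, true);
      if (ev.flipped) ncoop += (strat[ev.focal] == 1) ? 1 : -1;
    }
    rho[t] = static_cast<double>(ncoop) / N;
    executed = t + 1;
    absorbed = (ncoop == 0 || ncoop == N);
  }
  NumericVector rho_out(executed);
  std::copy(rho.begin(), rho.begin() + executed, rho_out.begin());
  return List::create(_["rho"] = rho_out, _["executed"] = executed,
                      _["absorbed"] = absorbed);
}

// One elementary update, mutating `strategies` in place. focal is a 0-based
// linear site index, or -1 to draw it uniformly. Returns the event record.
// [[Rcpp::export]]
List cpp_elementary_step(IntegerMatrix strategies, NumericMatrix h_field,
                         double b, double u, double alpha, double K,
                         int focal) {
  check_inputs(strategies, h_field);
  const int L = strategies.nrow(), N = L * L;
  if (focal < -1 || focal >= N) stop("focal site index out of bounds");
  std::vector<int> nbr;
  build_neighbors(L, nbr);
  std::vector<double> env, selcum;
  build_fields(h_field.begin(), nbr, N, alpha, env, selcum);
  StepOut ev = do_step(strategies.begin(), nbr, env, selcum, N, b, u, K,
                       focal, true);
  return List::create(_["focal"] = ev.focal, _["neighbor"] = ev.neighbor,
                      _["focal_fitness"] = ev.f_focal,
                      _["neighbor_fitness"] = ev.f_neighbor,
                      _["adopted"] = ev.adopted, _["flipped"] = ev.flipped);
}

// Monte Carlo flip frequency for a frozen configuration: n_trials forced
// elementary updates at `focal` that are never applied, counting how often
// the focal strategy would change. Used to test the kernel against the
// exact oracle.
// [[Rcpp::export]]
int cpp_flip_count(IntegerMatrix strategies, NumericMatrix h_field, double b,
                   double u, double alpha, double K, int focal, int n_trials) {
  check_inputs(strategies, h_field);
  const int L = strategies.nrow(), N = L * L;
  if (focal < 0 || focal >= N) stop("focal site index out of bounds");
  std::vector<int> nbr;
  build_neighbors(L, nbr);
  std::vector<double> env, selcum;
  build_fields(h_field.begin(), nbr, N, alpha, env, selcum);
  int *strat = strategies.begin();
  int count = 0;
  for (int t = 0; t < n_trials; ++t) {
    StepOut ev = do_step(strat, nbr, env, selcum, N, b, u, K, focal, false);
    if (ev.flipped) ++count;
  }
  return count;
}

// As above but with a random focal each trial (the full elementary-step
// distribution including the 1/N focal draw); returns per-site flip counts.
// [[Rcpp::export]]
IntegerVector cpp_flip_counts_random_focal(IntegerMatrix strategies,
                                           NumericMatrix h_field, double b,
                                           double u, double alpha, double K,
                                           int n_trials) {
  check_inputs(strategies, h_field);
  const int L = strategies.nrow(), N = L * L;
  std::vector<int> nbr;
  build_neighbors(L, nbr);
  std::vector<double> env, selcum;
  build_fields(h_field.begin(), nbr, N, alpha, env, selcum);
  int *strat = strategies.begin();
  IntegerVector counts(N);
  for (int t = 0; t < n_trials; ++t) {
    StepOut ev = do_step(strat, nbr, env, selcum, N, b, u, K, -1, false);
    if (ev.flipped) ++counts[ev.focal];
  }
  return counts;
}
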