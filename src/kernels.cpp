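// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Viterbi decoding of a Gaussian-emission HMM over conductance classes.
// x: samples; mu, sd: per-class emission parameters; logA: k x k log
// transition probabilities; logpi: log initial probabilities.
// Returns the 1-based MAP class path.
// [[Rcpp::export(name = ".viterbi_gauss")]]
IntegerVector viterbi_gauss(NumericVector x, NumericVector mu, NumericVector sd,
                            NumericMatrix logA, NumericVector logpi) {
  const int n = x.size(), k = mu.size();
  std::vector<double> prev(k), cur(k);
  IntegerMatrix bp(n, k);
  std::vector<double> lognorm(k), inv2var(k);
  for (int j = 0; j < k; ++j) {
    lognorm[j] = -std::log(sd[j]) - 0.5 * std::log(2.0 * M_PI);
    inv2var[j] = 0.5 / (sd[j] * sd[j]);
  }
  for (int j = 0; j < k; ++j) {
    double d = x[0] - mu[j];
    prev[j] = logpi[j] + lognorm[j] - d * d * inv2var[j];
  }
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < k; ++j) {
      double best = prev[0] + logA(0, j);
      int arg = 0;
      for (int i = 1; i < k; ++i) {
        double v = prev[i] + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      double d = x[t] - mu[j];
      cur[j] = best + lognorm[j] - d * d * inv2var[j];
      bp(t, j) = arg;
    }
    std::swap(prev, cur);
  }
  IntegerVector path(n);
  int arg = 0;
  for (int j = 1; j < k; ++j) if (prev[j] > prev[arg]) arg = j;
  path[n - 1] = arg + 1;
  for (int t = n - 1; t > 0; --t) {
    arg = bp(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}

// Gillespie direct-method core. lambda: exit rate per state; cum: row a =
// cumulative jump probabilities over that state's targets (padded with 1);
// targets: matching 1-based target states (padded with 0); s0: 1-based
// initial state. Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export(name = ".ssa_path")]]
List ssa_path(NumericVector lambda, NumericMatrix cum, IntegerMatrix targets,
              int s0, double duration) {
  std::vector<int> st;
  std::vector<double> t0, dw;
  const int ncol = cum.ncol();
  int s = s0 - 1;
  double t = 0.0;
  bool absorbed = false;
  while (t < duration) {
    st.push_back(s + 1);
    t0.push_back(t);
    if (lambda[s] <= 0.0) {
      dw.push_back(duration - t);
      absorbed = true;
      break;
    }
    double d = R::exp_rand() / lambda[s];
    if (t + d >= duration) {
      dw.push_back(duration - t);
      break;
    }
    dw.push_back(d);
    t += d;
    double u = R::unif_rand();
    int j = 0;
    while (j < ncol - 1 && u > cum(s, j)) ++j;
    s = targets(s, j) - 1;
  }
  return List::create(_["state"] = wrap(st), _["start"] = wrap(t0),
                      _["dwell"] = wrap(dw), _["absorbed"] = absorbed);
}

// No-throw matrix exponential via scaling and squaring with a Taylor core
// (blocks are tiny; B is pre-shifted so its exponential is bounded).
static arma::mat expm_nothrow(const arma::mat& B) {
  double nrm = arma::norm(B, 1);
  int s = 0;
  if (nrm > 1.0) s = (int)std::ceil(std::log2(nrm));
  if (s > 60) s = 60;
  arma::mat A = B / std::pow(2.0, s);
  const int n = B.n_rows;
  arma::mat res = arma::eye(n, n), term = arma::eye(n, n);
  for (int k = 1; k <= 40; ++k) {
    term = term * A / (double)k;
    res += term;
    if (arma::abs(term).max() < 1e-17) break;
  }
  for (int i = 0; i < s; ++i) res = res * res;
  return res;
}

// Interval log-likelihood of an aggregated Markov model.
// Qblocks: list of k within-class generator blocks (already dead-time
// corrected upstream when requested); Amats: flattened k*k list (row-major)
// of coupling matrices for observed class transitions a->b (empty matrix
// where unused); cls: 1-based class index per dwell; dur: effective dwell
// durations (s); entry: row vector over the states of the first class.
// Propagation is rescaled each step; returns the total log-likelihood.
// [[Rcpp::export(name = ".mil_loglik")]]
double mil_loglik(List Qblocks, List Amats, IntegerVector cls,
                  NumericVector dur, NumericVector entry) {
  const int k = Qblocks.size();
  const int n = cls.size();
  std::vector<arma::mat> Q(k);
  for (int a = 0; a < k; ++a) Q[a] = as<arma::mat>(Qblocks[a]);
  std::vector<arma::mat> A(k * k);
  for (int i = 0; i < k * k; ++i) A[i] = as<arma::mat>(Amats[i]);
  // eigen-decompose each block once; fall back to expmat if ill-conditioned
  std::vector<arma::cx_mat> V(k), Vinv(k);
  std::vector<arma::cx_vec> ev(k);
  std::vector<bool> use_eig(k, false);
  for (int a = 0; a < k; ++a) {
    arma::cx_vec eval;
    arma::cx_mat evec;
    if (arma::eig_gen(eval, evec, Q[a])) {
      double rc = arma::rcond(evec);
      if (rc > 1e-8) {
        arma::cx_mat inv;
        if (arma::inv(inv, evec)) {
          // accept only if the decomposition reproduces the block closely
          arma::mat recon = arma::real(evec * arma::diagmat(eval) * inv);
          double scale = std::max(1.0, arma::abs(Q[a]).max());
          if (arma::abs(recon - Q[a]).max() < 1e-11 * scale) {
            V[a] = evec;
            Vinv[a] = inv;
            ev[a] = eval;
            use_eig[a] = true;
          }
        }
      }
    }
  }
  // dominant eigenvalue per block, factored out of the propagation so long
  // dwells or fast rates cannot underflow the rescaled vector
  std::vector<double> emax(k, 0.0);
  for (int a = 0; a < k; ++a) {
    if (use_eig[a]) emax[a] = arma::real(ev[a]).max();
    else emax[a] = Q[a].diag().max();
  }
  arma::rowvec v = as<arma::rowvec>(entry);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    const int a = cls[i] - 1;
    const double t = dur[i];
    if (use_eig[a]) {
      arma::cx_rowvec w = arma::conv_to<arma::cx_rowvec>::from(v) * V[a];
      w %= arma::exp((ev[a] - emax[a]) * t).st();
      v = arma::real(w * Vinv[a]);
    } else {
      arma::mat B = Q[a] * t;
      B.diag() -= emax[a] * t;
      arma::mat E = expm_nothrow(B);
      if (!E.is_finite()) return -1e300;
      v = v * E;
    }
    ll += emax[a] * t;
    v.transform([](double z) { return (z < 0.0 || !std::isfinite(z)) ? 0.0 : z; });
    double s = arma::accu(v);
    // a collapsed propagation means an (astronomically) unlikely parameter
    // region; floor its contribution so the surface stays finite and the
    // optimizer keeps gradient information
    if (!(s > 0.0)) {
      ll += -700.0;
      v.fill(1.0 / v.n_elem);
    } else {
      v /= s;
      ll += std::log(s);
    }
    if (i + 1 < n) {
      const int b = cls[i + 1] - 1;
      v = v * A[a * k + b];
      v.transform([](double z) { return (z < 0.0 || !std::isfinite(z)) ? 0.0 : z; });
      double s2 = arma::accu(v);
      if (!(s2 > 0.0)) {
        ll += -700.0;
        v.fill(1.0 / v.n_elem);
      } else {
        v /= s2;
        ll += std::log(s2);
      }
    }
  }
  if (!std::isfinite(ll)) return -1e300;
  return ll;
}
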