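#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for a STRUCTURE-like admixture model on binary dominant
// data. Each band is one haploid biallelic locus. Correlated-frequencies
// F-model: p_kl ~ Beta(pbar_l (1-F_k)/F_k, (1-pbar_l)(1-F_k)/F_k).
// q_i ~ Dirichlet(alpha); alpha shared, uniform(0,10) prior, Metropolis.
// Uses R's RNG so results are reproducible under set.seed().
//
// Initialisation runs several short independent chains and continues the
// best one (by current log-likelihood): the conjugate updates converge
// fast, so a chain headed for a poorly merged local mode is cheap to
// detect and discard before the main run.

static inline double clamp01(double x, double eps) {
  if (x < eps) return eps;
  if (x > 1.0 - eps) return 1.0 - eps;
  return x;
}

static inline double reflect(double x, double lo, double hi) {
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  return x;
}

struct State {
  std::vector<double> P;     // K x L cluster band frequencies
  std::vector<double> pbar;  // L ancestral frequencies
  std::vector<double> Fk;    // K drift parameters
  std::vector<double> q;     // N x K admixture proportions
  double alpha;
};

struct Model {
  const IntegerMatrix X;
  int N, L, K;
  std::vector<double> pooled;
  Model(const IntegerMatrix& X_, int K_)
      : X(X_), N(X_.nrow()), L(X_.ncol()), K(K_), pooled(L) {
    for (int l = 0; l < L; ++l) {
      double s = 0; int n = 0;
      for (int i = 0; i < N; ++i)
        if (X(i, l) != NA_INTEGER) { s += X(i, l); ++n; }
      pooled[l] = clamp01(n ? s / n : 0.5, 0.01);
    }
  }
};

static const double EPS = 1e-9;

static void initState(const Model& m, State& st) {
  st.P.assign(m.K * m.L, 0.0);
  st.pbar = m.pooled;
  st.Fk.assign(m.K, 0.1);
  st.q.assign(m.N * m.K, 1.0 / m.K);
  st.alpha = 1.0;
  for (int k = 0; k < m.K; ++k)
    for (int l = 0; l < m.L; ++l)
      st.P[k * m.L + l] = clamp01(m.pooled[l] + 0.2 * (unif_rand() - 0.5), EPS);
  if (m.K > 1) {
    for (int i = 0; i < m.N; ++i) {
      double tot = 0.0;
      for (int k = 0; k < m.K; ++k) {
        double g = R::rgamma(1.0, 1.0);
        st.q[i * m.K + k] = g; tot += g;
      }
      for (int k = 0; k < m.K; ++k) st.q[i * m.K + k] /= tot;
    }
  }
}

static double logLik(const Model& m, const State& st) {
  double ll = 0.0;
  for (int i = 0; i < m.N; ++i) {
    for (int l = 0; l < m.L; ++l) {
      int x = m.X(i, l);
      if (x == NA_INTEGER) continue;
      double s = 0.0;
      for (int k = 0; k < m.K; ++k) {
        double pr = st.P[k * m.L + l];
        s += st.q[i * m.K + k] * (x ? pr : 1.0 - pr);
      }
      ll += log(s);
    }
  }
  return ll;
}

static void sweep(const Model& m, State& st,
                  std::vector<double>& n1, std::vector<double>& n0,
                  std::vector<double>& cnt, std::vector<double>& wk) {
  const int N = m.N, L = m.L, K = m.K;
  std::fill(n1.begin(), n1.end(), 0.0);
  std::fill(n0.begin(), n0.end(), 0.0);
  std::fill(cnt.begin(), cnt.end(), 0.0);

  // cluster-of-origin indicators
  for (int i = 0; i < N; ++i) {
    for (int l = 0; l < L; ++l) {
      int x = m.X(i, l);
      if (x == NA_INTEGER) continue;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double pr = st.P[k * L + l];
        wk[k] = st.q[i * K + k] * (x ? pr : 1.0 - pr);
        tot += wk[k];
      }
      double u = unif_rand() * tot, c = 0.0;
      int z = K - 1;
      for (int k = 0; k < K; ++k) { c += wk[k]; if (u <= c) { z = k; break; } }
      if (x) n1[z * L + l] += 1.0; else n0[z * L + l] += 1.0;
      cnt[i * K + z] += 1.0;
    }
  }

  // band frequencies per cluster (conjugate Beta update)
  for (int k = 0; k < K; ++k) {
    double lam = (1.0 - st.Fk[k]) / st.Fk[k];
    for (int l = 0; l < L; ++l) {
      double a = st.pbar[l] * lam + n1[k * L + l];
      double b = (1.0 - st.pbar[l]) * lam + n0[k * L + l];
      st.P[k * L + l] = clamp01(R::rbeta(a, b), EPS);
    }
  }

  // ancestral frequencies: Metropolis, uniform prior
  for (int l = 0; l < L; ++l) {
    double prop = reflect(st.pbar[l] + 0.05 * (unif_rand() - 0.5), 0.001, 0.999);
    double lr = 0.0;
    for (int k = 0; k < K; ++k) {
      double lam = (1.0 - st.Fk[k]) / st.Fk[k];
      lr += R::dbeta(st.P[k * L + l], prop * lam, (1.0 - prop) * lam, 1) -
            R::dbeta(st.P[k * L + l], st.pbar[l] * lam,
                     (1.0 - st.pbar[l]) * lam, 1);
    }
    if (log(unif_rand()) < lr) st.pbar[l] = prop;
  }

  // drift parameters: Metropolis, uniform(0,1) prior
  for (int k = 0; k < K; ++k) {
    double prop = reflect(st.Fk[k] + 0.05 * (unif_rand() - 0.5), 1e-4, 0.99);
    double lamP = (1.0 - prop) / prop, lamC = (1.0 - st.Fk[k]) / st.Fk[k];
    double lr = 0.0;
    for (int l = 0; l < L; ++l) {
      lr += R::dbeta(st.P[k * L + l], st.pbar[l] * lamP,
                     (1.0 - st.pbar[l]) * lamP, 1) -
            R::dbeta(st.P[k * L + l], st.pbar[l] * lamC,
                     (1.0 - st.pbar[l]) * lamC, 1);
    }
    if (log(unif_rand()) < lr) st.Fk[k] = prop;
  }

  // admixture proportions and the shared alpha
  if (K > 1) {
    for (int i = 0; i < N; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(st.alpha + cnt[i * K + k], 1.0);
        st.q[i * K + k] = g; tot += g;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        st.q[i * K + k] = clamp01(st.q[i * K + k] / tot, EPS);
        s += st.q[i * K + k];
      }
      for (int k = 0; k < K; ++k) st.q[i * K + k] /= s;
    }
    double prop = reflect(st.alpha + 0.1 * norm_rand(), 0.01, 10.0);
    double sumlogq = 0.0;
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < K; ++k) sumlogq += log(st.q[i * K + k]);
    double lr = m.N * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) -
                m.N * (R::lgammafn(K * st.alpha) - K * R::lgammafn(st.alpha)) +
                (prop - st.alpha) * sumlogq;
    if (log(unif_rand()) < lr) st.alpha = prop;
  }
}

// [[Rcpp::export]]
List structure_gibbs_cpp(IntegerMatrix X, int K, int reps, int burnin,
                         int thin, int nInits, int initIters) {
  Model m(X, K);
  const int N = m.N, L = m.L;
  std::vector<double> n1(K * L), n0(K * L), cnt(N * K), wk(K);

  // short independent pilot chains; continue the best
  State st, best;
  double bestLl = R_NegInf;
  for (int s = 0; s < std::max(nInits, 1); ++s) {
    initState(m, st);
    for (int it = 0; it < initIters; ++it) sweep(m, st, n1, n0, cnt, wk);
    double ll = logLik(m, st);
    if (ll > bestLl) { bestLl = ll; best = st; }
  }
  st = best;

  NumericMatrix qsum(N, K);
  int nkept = 0;
  std::vector<double> lnTrace;
  for (int it = 1; it <= reps; ++it) {
    sweep(m, st, n1, n0, cnt, wk);
    if (it % thin == 0) lnTrace.push_back(logLik(m, st));
    if (it > burnin) {
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) qsum(i, k) += st.q[i * K + k];
      ++nkept;
    }
  }

  NumericMatrix qmean(N, K);
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { qmean(i, k) = qsum(i, k) / nkept; s += qmean(i, k); }
    for (int k = 0; k < K; ++k) qmean(i, k) /= s;
  }
  return List::create(_["q"] = qmean,
                      _["lnP"] = NumericVector(lnTrace.begin(), lnTrace.end()),
                      _["alpha"] = st.alpha,
                      _["F"] = NumericVector(st.Fk.begin(), st.Fk.end()));
}
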