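// Felsenstein pruning likelihood for small rooted trees under GTR + discrete
// Gamma, plus coordinate-wise Brent optimization of branch lengths. The
// eigen-decomposition of the (reversible) rate matrix is done once in R and
// passed in; here we only exponentiate it per branch and rate category.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double MIN_BL = 1e-8;
static const double MAX_BL = 10.0;

// P(t) = V diag(exp(lambda t)) Vinv, clamped to [0, inf)
static void pmat(double t, const double* V, const double* Vi,
                 const double* lam, double* P) {
  double E[4];
  for (int k = 0; k < 4; ++k) E[k] = std::exp(lam[k] * t);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      double s = 0.0;
      for (int k = 0; k < 4; ++k) s += V[i + 4 * k] * E[k] * Vi[k + 4 * j];
      P[4 * i + j] = s > 0.0 ? s : 0.0;
    }
}

struct Lik {
  int npat, nnode, root;
  const int* tips;          // npat x 5, column-major, states 0..3, -1 = N
  const double* w;
  std::vector<int> ep, ec;  // postorder edges (children before parents)
  const double* pi;
  const double* V;
  const double* Vi;
  const double* lam;
  std::vector<double> rates;

  double loglik(const double* len) const {
    int ne = (int)ep.size();
    int k = (int)rates.size();
    std::vector<double> siteL(npat, 0.0);
    std::vector<double> P(16 * ne);
    std::vector<double> part(4 * (nnode + 1));
    for (int r = 0; r < k; ++r) {
      for (int e = 0; e < ne; ++e)
        pmat(len[e] * rates[r], V, Vi, lam, &P[16 * e]);
      for (int p = 0; p < npat; ++p) {
        for (int i = 0; i <= nnode; ++i)
          part[4 * i] = part[4 * i + 1] = part[4 * i + 2] = part[4 * i + 3] = 1.0;
        for (int e = 0; e < ne; ++e) {
          int par = ep[e], ch = ec[e];
          const double* Pe = &P[16 * e];
          double contrib[4];
          if (ch <= 5) {                       // tip (1-based ids 1..5)
            int st = tips[p + npat * (ch - 1)];
            if (st < 0) { contrib[0] = contrib[1] = contrib[2] = contrib[3] = 1.0; }
            else for (int s = 0; s < 4; ++s) contrib[s] = Pe[4 * s + st];
          } else {
            const double* cp = &part[4 * ch];
            for (int s = 0; s < 4; ++s)
              contrib[s] = Pe[4 * s] * cp[0] + Pe[4 * s + 1] * cp[1] +
                           Pe[4 * s + 2] * cp[2] + Pe[4 * s + 3] * cp[3];
          }
          double* pp = &part[4 * par];
          for (int s = 0; s < 4; ++s) pp[s] *= contrib[s];
        }
        double sl = 0.0;
        const double* rp = &part[4 * root];
        for (int s = 0; s < 4; ++s) sl += pi[s] * rp[s];
        siteL[p] += sl;
      }
    }
    double ll = 0.0;
    for (int p = 0; p < npat; ++p) {
      double x = siteL[p] / k;
      ll += w[p] * std::log(x > 1e-300 ? x : 1e-300);
    }
    return ll;
  }
};

static Lik make_lik(const IntegerMatrix& tips, const NumericVector& w,
                    const IntegerVector& edge_parent,
                    const IntegerVector& edge_child, int root,
                    const NumericVector& pi, const NumericMatrix& V,
                    const NumericMatrix& Vinv, const NumericVector& lambda,
                    const NumericVector& rates) {
  Lik L;
  L.npat = tips.nrow();
  L.root = root;
  L.tips = tips.begin();
  L.w = w.begin();
  L.ep.assign(edge_parent.begin(), edge_parent.end());
  L.ec.assign(edge_child.begin(), edge_child.end());
  int mx = root;
  for (size_t i = 0; i < L.ep.size(); ++i) {
    if (L.ep[i] > mx) mx = L.ep[i];
    if (L.ec[i] > mx) mx = L.ec[i];
  }
  L.nnode = mx;
  L.pi = pi.begin();
  L.V = V.begin();
  L.Vi = Vinv.begin();
  L.lam = lambda.begin();
  L.rates.assign(rates.begin(), rates.end());
  return L;
}

// [[Rcpp::export]]
double cpp_loglik(IntegerMatrix tips, NumericVector weights,
                  IntegerVector edge_parent, IntegerVector edge_child,
                  NumericVector lengths, int root, NumericVector pi,
                  NumericMatrix V, NumericMatrix Vinv, NumericVector lambda,
                  NumericVector rates) {
  Lik L = make_lik(tips, weights, edge_parent, edge_child, root, pi, V, Vinv,
                   lambda, rates);
  return L.loglik(REAL(lengths));
}

// Brent's local minimizer (derivative-free) of f on [a, b]
template <class F>
static double brent_min(F f, double a, double b, double tol, double* fmin) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), wx = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int it = 0; it < 100; ++it) {
    double m = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0, q = 0, rr = 0;
    bool parab = false;
    if (std::fabs(e) > tol1) {
      rr = (x - wx) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - wx) * rr;
      q = 2.0 * (q - rr);
      if (q > 0) p = -p; else q = -q;
      if (std::fabs(p) < std::fabs(0.5 * q * e) && p > q * (a - x) &&
          p < q * (b - x)) {
        e = d; d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (m > x) ? tol1 : -tol1;
        parab = true;
      }
    }
    if (!parab) { e = (x < m) ? b - x : a - x; d = gold * e; }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = wx; fv = fw; wx = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || wx == x) { v = wx; fv = fw; wx = u; fw = fu; }
      else if (fu <= fv || v == x || v == wx) { v = u; fv = fu; }
    }
  }
  *fmin = fx;
  return x;
}

// [[Rcpp::export]]
List cpp_fit_branch_lengths(IntegerMatrix tips, NumericVector weights,
                            IntegerVector edge_parent, IntegerVector edge_child,
                            NumericVector init, int root, NumericVector pi,
                            NumericMatrix V, NumericMatrix Vinv,
                            NumericVector lambda, NumericVector rates,
                            double tol = 1e-6, int max_sweeps = 20,
                            double brent_tol = 1e-4) {
  Lik L = make_lik(tips, weights, edge_parent, edge_child, root, pi, V, Vinv,
                   lambda, rates);
  int ne = edge_parent.size();
  std::vector<double> len(init.begin(), init.end());
  for (int e = 0; e < ne; ++e) {
    if (len[e] < MIN_BL) len[e] = MIN_BL;
    if (len[e] > MAX_BL) len[e] = MAX_BL;
  }
  double ll = L.loglik(len.data());
  bool converged = false;
  int sweeps = 0;
  for (int s = 0; s < max_sweeps; ++s) {
    ++sweeps;
    double ll_old = ll;
    for (int e = 0; e < ne; ++e) {
      double save = len[e];
      auto f = [&](double x) { len[e] = x; return -L.loglik(len.data()); };
      double fmin;
      // optimize on log scale: branch lengths span orders of magnitude
      auto g = [&](double z) { return f(std::exp(z)); };
      double z = brent_min(g, std::log(MIN_BL), std::log(MAX_BL), brent_tol,
                           &fmin);
      double cand = std::exp(z);
      if (-fmin >= ll) { len[e] = cand; ll = -fmin; }
      else len[e] = save;
    }
    if (ll - ll_old < tol) { converged = true; break; }
  }
  return List::create(_["lengths"] = NumericVector(len.begin(), len.end()),
                      _["loglik"] = ll, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}

// Scan many topologies with shared data: coordinate-descent fit per topology.
// parents/children are ne x ntopo matrices of postorder edges; roots per
// topology. Returns per-topology log-likelihoods and fitted lengths.
// [[Rcpp::export]]
List cpp_fit_topologies(IntegerMatrix tips, NumericVector weights,
                        IntegerMatrix parents, IntegerMatrix childs,
                        IntegerVector roots, NumericVector init,
                        NumericVector pi, NumericMatrix V, NumericMatrix Vinv,
                        NumericVector lambda, NumericVector rates,
                        double tol = 1e-2, int max_sweeps = 4,
                        double brent_tol = 3e-3) {
  int ntopo = parents.ncol(), ne = parents.nrow();
  NumericVector lls(ntopo);
  NumericMatrix lens(ne, ntopo);
  LogicalVector conv(ntopo);
  for (int t = 0; t < ntopo; ++t) {
    IntegerVector ep = parents(_, t), ec = childs(_, t);
    Lik L = make_lik(tips, weights, ep, ec, roots[t], pi, V, Vinv, lambda,
                     rates);
    std::vector<double> len(init.begin(), init.end());
    double ll = L.loglik(len.data());
    bool converged = false;
    for (int s = 0; s < max_sweeps; ++s) {
      double ll_old = ll;
      for (int e = 0; e < ne; ++e) {
        double save = len[e];
        auto g = [&](double z) { len[e] = std::exp(z); return -L.loglik(len.data()); };
        double fmin;
        double lo = std::log(MIN_BL), hi = std::log(MAX_BL);
        if (s > 0) {   // after the first sweep, search near the current value
          double c = std::log(save);
          lo = std::max(lo, c - 2.5); hi = std::min(hi, c + 2.5);
        }
        double z = brent_min(g, lo, hi, brent_tol, &fmin);
        if (-fmin >= ll) { len[e] = std::exp(z); ll = -fmin; }
        else len[e] = save;
      }
      if (ll - ll_old < tol) { converged = true; break; }
    }
    lls[t] = ll;
    for (int e = 0; e < ne; ++e) lens(e, t) = len[e];
    conv[t] = converged;
  }
  return List::create(_["loglik"] = lls, _["lengths"] = lens,
                      _["converged"] = conv);
}
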