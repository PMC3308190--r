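// Symmetric 2-state (CFN) pruning kernel with discrete-gamma mixtures:
// per-column log-likelihoods and exact coordinate sweeps over branch
// lengths. Node ids are 1-based (ape convention); edges must be in
// postorder. Pseudo-site layout: index cat * ncol + col.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SCALE_LO = 1e-240;

struct Partials {
  int nid, ncol, k, M;
  std::vector<double> L0, L1, lsc;
  Partials(int nid_, int ncol_, int k_)
      : nid(nid_), ncol(ncol_), k(k_), M(ncol_ * k_),
        L0(nid_ * M, 1.0), L1(nid_ * M, 1.0), lsc(nid_ * M, 0.0) {}
  double* p0(int v) { return &L0[(v - 1) * M]; }
  double* p1(int v) { return &L1[(v - 1) * M]; }
  double* ps(int v) { return &lsc[(v - 1) * M]; }
};

static void init_tips(Partials& P, const IntegerMatrix& tips) {
  int ntip = tips.nrow(), ncol = tips.ncol();
  for (int i = 0; i < ntip; ++i) {
    double* a0 = P.p0(i + 1);
    double* a1 = P.p1(i + 1);
    for (int c = 0; c < P.k; ++c) {
      for (int j = 0; j < ncol; ++j) {
        int s = tips(i, j);
        int idx = c * ncol + j;
        if (s == NA_INTEGER) continue;
        if (s == 0) a1[idx] = 0.0; else a0[idx] = 0.0;
      }
    }
  }
}

// multiply parent partial by the message from child across length t
static void absorb_child(Partials& P, int p, int ch, double t,
                         const NumericVector& rates) {
  double* q0 = P.p0(p); double* q1 = P.p1(p); double* qs = P.ps(p);
  double* a0 = P.p0(ch); double* a1 = P.p1(ch); double* as = P.ps(ch);
  int ncol = P.ncol;
  for (int c = 0; c < P.k; ++c) {
    double e = std::exp(-2.0 * t * rates[c]);
    double ps = 0.5 * (1.0 + e), pd = 0.5 * (1.0 - e);
    for (int j = 0; j < ncol; ++j) {
      int idx = c * ncol + j;
      double m0 = ps * a0[idx] + pd * a1[idx];
      double m1 = pd * a0[idx] + ps * a1[idx];
      q0[idx] *= m0; q1[idx] *= m1;
      qs[idx] += as[idx];
      double mx = q0[idx] > q1[idx] ? q0[idx] : q1[idx];
      if (mx < SCALE_LO && mx > 0.0) {
        q0[idx] /= mx; q1[idx] /= mx; qs[idx] += std::log(mx);
      }
    }
  }
}

static void down_pass(Partials& P, const IntegerMatrix& edge,
                      const NumericVector& elen,
                      const NumericVector& rates) {
  for (int i = 0; i < edge.nrow(); ++i) {
    absorb_child(P, edge(i, 0), edge(i, 1), elen[i], rates);
  }
}

// column log-likelihoods from a root partial (gamma mixture, weights 1/k)
static NumericVector mix_ll(const double* R0, const double* R1,
                            const double* ls, int ncol, int k) {
  NumericVector out(ncol);
  for (int j = 0; j < ncol; ++j) {
    double mx = R_NegInf;
    std::vector<double> lg(k);
    for (int c = 0; c < k; ++c) {
      int idx = c * ncol + j;
      double site = 0.5 * (R0[idx] + R1[idx]);
      lg[c] = (site > 0.0 ? std::log(site) : R_NegInf) + ls[idx];
      if (lg[c] > mx) mx = lg[c];
    }
    if (!R_finite(mx)) { out[j] = R_NegInf; continue; }
    double s = 0.0;
    for (int c = 0; c < k; ++c) s += std::exp(lg[c] - mx);
    out[j] = mx + std::log(s / k);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cfn_col_loglik(IntegerMatrix edge, NumericVector elen,
                             int ntip, int nnode, IntegerMatrix tips,
                             NumericVector rates) {
  int nid = ntip + nnode;
  Partials P(nid, tips.ncol(), rates.size());
  init_tips(P, tips);
  down_pass(P, edge, elen, rates);
  int root = ntip + 1;
  return mix_ll(P.p0(root), P.p1(root), P.ps(root), P.ncol, P.k);
}

// local objective for one edge: O = outer partial at the parent side,
// D = subtree partial below the child
static double edge_ll(const std::vector<double>& O0,
                      const std::vector<double>& O1,
                      const std::vector<double>& Os,
                      const double* D0, const double* D1, const double* Ds,
                      double t, const NumericVector& rates, int ncol) {
  int k = rates.size();
  double total = 0.0;
  std::vector<double> lg(k), psv(k), pdv(k);
  for (int c = 0; c < k; ++c) {
    double e = std::exp(-2.0 * t * rates[c]);
    psv[c] = 0.5 * (1.0 + e);
    pdv[c] = 0.5 * (1.0 - e);
  }
  std::vector<double> site(k);
  for (int j = 0; j < ncol; ++j) {
    bool unscaled = true;
    for (int c = 0; c < k; ++c) {
      int idx = c * ncol + j;
      double m0 = psv[c] * D0[idx] + pdv[c] * D1[idx];
      double m1 = pdv[c] * D0[idx] + psv[c] * D1[idx];
      site[c] = 0.5 * (O0[idx] * m0 + O1[idx] * m1);
      if (Os[idx] != 0.0 || Ds[idx] != 0.0) unscaled = false;
    }
    if (unscaled) {
      // common case: no rescaling anywhere below or above this edge
      double s = 0.0;
      for (int c = 0; c < k; ++c) s += site[c];
      if (s <= 0.0) return R_NegInf;
      total += std::log(s / k);
    } else {
      double mx = R_NegInf;
      for (int c = 0; c < k; ++c) {
        int idx = c * ncol + j;
        lg[c] = (site[c] > 0.0 ? std::log(site[c]) : R_NegInf) +
                Os[idx] + Ds[idx];
        if (lg[c] > mx) mx = lg[c];
      }
      if (!R_finite(mx)) return R_NegInf;
      double s = 0.0;
      for (int c = 0; c < k; ++c) s += std::exp(lg[c] - mx);
      total += mx + std::log(s / k);
    }
  }
  return total;
}

// golden-section maximization of the per-edge objective
static double golden_max(const std::vector<double>& O0,
                         const std::vector<double>& O1,
                         const std::vector<double>& Os,
                         const double* D0, const double* D1, const double* Ds,
                         double lo, double hi, const NumericVector& rates,
                         int ncol, double* best_ll) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = edge_ll(O0, O1, Os, D0, D1, Ds, x1, rates, ncol);
  double f2 = edge_ll(O0, O1, Os, D0, D1, Ds, x2, rates, ncol);
  for (int it = 0; it < 60 && (b - a) > 1e-7; ++it) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = edge_ll(O0, O1, Os, D0, D1, Ds, x2, rates, ncol);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = edge_ll(O0, O1, Os, D0, D1, Ds, x1, rates, ncol);
    }
  }
  double xm = 0.5 * (a + b);
  *best_ll = edge_ll(O0, O1, Os, D0, D1, Ds, xm, rates, ncol);
  return xm;
}

// Exact coordinate sweeps over branch lengths. Down partials are computed
// once per sweep; a root-down traversal maintains up partials using the
// already-updated lengths above, so each univariate optimization sees the
// exact likelihood. Returns optimized lengths and the final log-likelihood.
// [[Rcpp::export]]
List cfn_opt_bl(IntegerMatrix edge, NumericVector elen, int ntip, int nnode,
                IntegerMatrix tips, NumericVector rates, double min_bl,
                double max_bl, double tol, int max_sweeps) {
  int nid = ntip + nnode, ncol = tips.ncol(), k = rates.size(), M = ncol * k;
  int root = ntip + 1, ne = edge.nrow();
  NumericVector len = clone(elen);

  // children rows per node
  std::vector<std::vector<int> > kids(nid + 1);
  for (int i = 0; i < ne; ++i) kids[edge(i, 0)].push_back(i);

  double ll_prev = R_NegInf, ll = R_NegInf;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    Partials D(nid, ncol, k);
    init_tips(D, tips);
    down_pass(D, edge, len, rates);

    // up partials, stored per node
    std::vector<double> U0(static_cast<size_t>(nid) * M, 1.0),
        U1(static_cast<size_t>(nid) * M, 1.0),
        Us(static_cast<size_t>(nid) * M, 0.0);

    // iterative root-down traversal
    std::vector<int> stack;
    stack.push_back(root);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      const std::vector<int>& rows = kids[p];
      if (rows.empty()) continue;
      int nc = rows.size();
      // messages from each child at current lengths
      std::vector<std::vector<double> > m0(nc, std::vector<double>(M)),
          m1(nc, std::vector<double>(M));
      for (int a = 0; a < nc; ++a) {
        int ch = edge(rows[a], 1);
        double* d0 = D.p0(ch); double* d1 = D.p1(ch);
        for (int c = 0; c < k; ++c) {
          double e = std::exp(-2.0 * len[rows[a]] * rates[c]);
          double ps = 0.5 * (1.0 + e), pd = 0.5 * (1.0 - e);
          for (int j = 0; j < ncol; ++j) {
            int idx = c * ncol + j;
            m0[a][idx] = ps * d0[idx] + pd * d1[idx];
            m1[a][idx] = pd * d0[idx] + ps * d1[idx];
          }
        }
      }
      std::vector<double> O0(M), O1(M), Os(M);
      for (int a = 0; a < nc; ++a) {
        int row = rows[a], ch = edge(row, 1);
        // outer partial: up(p) times siblings' messages
        double* u0 = &U0[(p - 1) * static_cast<size_t>(M)];
        double* u1 = &U1[(p - 1) * static_cast<size_t>(M)];
        double* us = &Us[(p - 1) * static_cast<size_t>(M)];
        for (int idx = 0; idx < M; ++idx) {
          O0[idx] = u0[idx]; O1[idx] = u1[idx]; Os[idx] = us[idx];
        }
        for (int b = 0; b < nc; ++b) {
          if (b == a) continue;
          int sib = edge(rows[b], 1);
          double* ss = D.ps(sib);
          for (int idx = 0; idx < M; ++idx) {
            O0[idx] *= m0[b][idx]; O1[idx] *= m1[b][idx]; Os[idx] += ss[idx];
            double mx = O0[idx] > O1[idx] ? O0[idx] : O1[idx];
            if (mx < SCALE_LO && mx > 0.0) {
              O0[idx] /= mx; O1[idx] /= mx; Os[idx] += std::log(mx);
            }
          }
        }
        double cur = edge_ll(O0, O1, Os, D.p0(ch), D.p1(ch), D.ps(ch),
                             len[row], rates, ncol);
        // bracket around the current length, expanding while the optimum
        // sits on a bracket end
        double lo = std::max(min_bl, 0.2 * len[row]);
        double hi = std::min(max_bl, 5.0 * len[row] + 1e-4);
        double cand_ll, cand;
        for (int expand = 0; expand < 3; ++expand) {
          cand = golden_max(O0, O1, Os, D.p0(ch), D.p1(ch), D.ps(ch),
                            lo, hi, rates, ncol, &cand_ll);
          bool at_lo = (cand - lo) < 0.05 * (hi - lo) && lo > min_bl;
          bool at_hi = (hi - cand) < 0.05 * (hi - lo) && hi < max_bl;
          // the optimum sits on the bracket: widen to the hard bound once
          if (at_lo) { hi = lo * 1.5; lo = min_bl; }
          else if (at_hi) { lo = hi * 0.67; hi = max_bl; }
          else break;
        }
        if (cand_ll > cur) {
          len[row] = cand;
          // refresh this child's message for the remaining siblings
          double* d0 = D.p0(ch); double* d1 = D.p1(ch);
          for (int c = 0; c < k; ++c) {
            double e = std::exp(-2.0 * len[row] * rates[c]);
            double ps = 0.5 * (1.0 + e), pd = 0.5 * (1.0 - e);
            for (int j = 0; j < ncol; ++j) {
              int idx = c * ncol + j;
              m0[a][idx] = ps * d0[idx] + pd * d1[idx];
              m1[a][idx] = pd * d0[idx] + ps * d1[idx];
            }
          }
        }
        // child's up partial: outer messaged across the (updated) edge
        double* v0 = &U0[(ch - 1) * static_cast<size_t>(M)];
        double* v1 = &U1[(ch - 1) * static_cast<size_t>(M)];
        double* vs = &Us[(ch - 1) * static_cast<size_t>(M)];
        for (int c = 0; c < k; ++c) {
          double e = std::exp(-2.0 * len[row] * rates[c]);
          double ps = 0.5 * (1.0 + e), pd = 0.5 * (1.0 - e);
          for (int j = 0; j < ncol; ++j) {
            int idx = c * ncol + j;
            v0[idx] = ps * O0[idx] + pd * O1[idx];
            v1[idx] = pd * O0[idx] + ps * O1[idx];
            vs[idx] = Os[idx];
            double mx = v0[idx] > v1[idx] ? v0[idx] : v1[idx];
            if (mx < SCALE_LO && mx > 0.0) {
              v0[idx] /= mx; v1[idx] /= mx; vs[idx] += std::log(mx);
            }
          }
        }
        stack.push_back(ch);
      }
    }
    // sweep log-likelihood
    Partials F(nid, ncol, k);
    init_tips(F, tips);
    down_pass(F, edge, len, rates);
    NumericVector cl = mix_ll(F.p0(root), F.p1(root), F.ps(root), ncol, k);
    ll = 0.0;
    for (int j = 0; j < ncol; ++j) ll += cl[j];
    if (sweep > 0 && ll - ll_prev < tol) break;
    ll_prev = ll;
  }
  return List::create(_["elen"] = len, _["loglik"] = ll);
}
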