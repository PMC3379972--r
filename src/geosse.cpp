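// GeoSSE likelihood backend: the six coupled ODEs (E_A, E_B, E_AB, D_A,
// D_B, D_AB) integrated along branches with an adaptive embedded
// Cash-Karp Runge-Kutta 4(5) scheme, plus the full post-order pruning
// pass. D partials are renormalized per branch with an accumulated log
// scaler to prevent underflow.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// pars: sA, sB, sAB, xA, xB, dA, dB
static inline void geosse_rhs(const double* y, double* dy, const double* p) {
  const double sA = p[0], sB = p[1], sAB = p[2];
  const double xA = p[3], xB = p[4], dA = p[5], dB = p[6];
  const double EA = y[0], EB = y[1], EAB = y[2];
  const double DA = y[3], DB = y[4], DAB = y[5];
  dy[0] = xA - (sA + dA + xA) * EA + dA * EAB + sA * EA * EA;
  dy[1] = xB - (sB + dB + xB) * EB + dB * EAB + sB * EB * EB;
  dy[2] = -(sA + sB + sAB + xA + xB) * EAB + xA * EB + xB * EA
          + sA * EA * EAB + sB * EB * EAB + sAB * EA * EB;
  dy[3] = -(sA + dA + xA) * DA + dA * DAB + 2.0 * sA * DA * EA;
  dy[4] = -(sB + dB + xB) * DB + dB * DAB + 2.0 * sB * DB * EB;
  dy[5] = -(sA + sB + sAB + xA + xB) * DAB + xA * DB + xB * DA
          + sA * (DA * EAB + DAB * EA) + sB * (DB * EAB + DAB * EB)
          + sAB * (DA * EB + DB * EA);
}

// Cash-Karp tableau
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0 / 5, 0, 0, 0, 0},
  {3.0 / 40, 9.0 / 40, 0, 0, 0},
  {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
  {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
  {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592,
   253.0 / 4096}};
static const double CK_C5[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0,
                                512.0 / 1771};
static const double CK_C4[6] = {2825.0 / 27648, 0, 18575.0 / 48384,
                                13525.0 / 55296, 277.0 / 14336, 1.0 / 4};

// integrate y over [0, len]; returns 0 on success, 1 on failure
static int integrate_branch(double* y, double len, const double* p,
                            double rtol, double atol) {
  if (len <= 0.0) return 0;
  double t = 0.0;
  double h = len;
  if (h > 0.1) h = 0.1;
  double k[6][6], ytmp[6], y5[6], y4[6];
  int iter = 0;
  while (t < len) {
    if (++iter > 1000000) return 1;
    if (t + h > len) h = len - t;
    geosse_rhs(y, k[0], p);
    for (int s = 1; s < 6; ++s) {
      for (int j = 0; j < 6; ++j) {
        double acc = y[j];
        for (int q = 0; q < s; ++q) acc += h * CK_B[s][q] * k[q][j];
        ytmp[j] = acc;
      }
      geosse_rhs(ytmp, k[s], p);
    }
    double errmax = 0.0;
    for (int j = 0; j < 6; ++j) {
      double a5 = y[j], a4 = y[j];
      for (int s = 0; s < 6; ++s) {
        a5 += h * CK_C5[s] * k[s][j];
        a4 += h * CK_C4[s] * k[s][j];
      }
      y5[j] = a5; y4[j] = a4;
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(a5));
      double e = std::fabs(a5 - a4) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0) {
      t += h;
      for (int j = 0; j < 6; ++j) y[j] = y5[j];
      // numerical guards: E in [0,1], D >= 0 (tolerate tiny undershoot)
      for (int j = 0; j < 3; ++j) {
        if (y[j] < 0.0) y[j] = 0.0;
        if (y[j] > 1.0) y[j] = 1.0;
      }
      for (int j = 3; j < 6; ++j) {
        if (y[j] < 0.0) {
          if (y[j] < -1e-6) return 1;
          y[j] = 0.0;
        }
      }
      double fac = 0.9 * std::pow(std::max(errmax, 1e-16), -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < 1e-14) return 1;
    }
  }
  return 0;
}

// [[Rcpp::export]]
NumericVector geosse_integrate_cpp(NumericVector y0, double len,
                                   NumericVector pars,
                                   double rtol = 1e-8, double atol = 1e-12) {
  double y[6];
  for (int j = 0; j < 6; ++j) y[j] = y0[j];
  int status = integrate_branch(y, len, REAL(pars), rtol, atol);
  if (status != 0) stop("GeoSSE ODE integration failure");
  NumericVector out(6);
  for (int j = 0; j < 6; ++j) out[j] = y[j];
  return out;
}

// children: (ntot x 2), 0 for tips; po_nodes: postorder node ids (1-based,
// root last); plen: branch length above each node (ignored for root);
// tip_state: 1=A, 2=B, 3=AB for tips, 0 otherwise; f: sampling fractions.
// root_mode: 0 = observed weights (D-weighted), 1 = flat.
// [[Rcpp::export]]
List geosse_prune_cpp(IntegerMatrix children, IntegerVector po_nodes,
                      NumericVector plen, IntegerVector tip_state,
                      NumericVector f, NumericVector pars, int root_node,
                      int root_mode, double rtol = 1e-8,
                      double atol = 1e-12) {
  const int ntot = children.nrow();
  std::vector<double> E(3 * ntot, 0.0), D(3 * ntot, 0.0);
  double logcomp = 0.0;
  const double* p = REAL(pars);
  for (int i = 0; i < po_nodes.size(); ++i) {
    int v = po_nodes[i] - 1;
    double y[6];
    if (children(v, 0) == 0) { // tip
      for (int j = 0; j < 3; ++j) {
        y[j] = 1.0 - f[j];
        y[3 + j] = (tip_state[v] == j + 1) ? f[j] : 0.0;
      }
    } else {
      int c1 = children(v, 0) - 1, c2 = children(v, 1) - 1;
      double DA1 = D[3 * c1], DB1 = D[3 * c1 + 1], DAB1 = D[3 * c1 + 2];
      double DA2 = D[3 * c2], DB2 = D[3 * c2 + 1], DAB2 = D[3 * c2 + 2];
      const double sA = p[0], sB = p[1], sAB = p[2];
      y[0] = E[3 * c1]; y[1] = E[3 * c1 + 1]; y[2] = E[3 * c1 + 2];
      y[3] = sA * DA1 * DA2;
      y[4] = sB * DB1 * DB2;
      y[5] = 0.5 * (sA * (DA1 * DAB2 + DAB1 * DA2)
                    + sB * (DB1 * DAB2 + DAB1 * DB2)
                    + sAB * (DA1 * DB2 + DB1 * DA2));
    }
    double s = y[3] + y[4] + y[5];
    if (s <= 0.0 && children(v, 0) != 0) {
      return List::create(_["loglik"] = R_NegInf,
                          _["rootD"] = NumericVector(3),
                          _["rootE"] = NumericVector(3));
    }
    if (v != root_node - 1) {
      // renormalize D before propagating to keep magnitudes O(1)
      if (s > 0.0) {
        for (int j = 3; j < 6; ++j) y[j] /= s;
        logcomp += std::log(s);
      }
      int status = integrate_branch(y, plen[v], p, rtol, atol);
      if (status != 0) stop("GeoSSE ODE integration failure on branch above node %d",
                            v + 1);
      double s2 = y[3] + y[4] + y[5];
      if (s2 > 0.0) {
        for (int j = 3; j < 6; ++j) y[j] /= s2;
        logcomp += std::log(s2);
      }
    }
    for (int j = 0; j < 3; ++j) {
      E[3 * v + j] = y[j];
      D[3 * v + j] = y[3 + j];
    }
  }
  int r = root_node - 1;
  double DA = D[3 * r], DB = D[3 * r + 1], DAB = D[3 * r + 2];
  double tot = DA + DB + DAB;
  double L;
  if (tot <= 0.0) {
    return List::create(_["loglik"] = R_NegInf,
                        _["rootD"] = NumericVector(3),
                        _["rootE"] = NumericVector(3));
  }
  if (root_mode == 0) {
    L = (DA * DA + DB * DB + DAB * DAB) / tot; // observed weights
  } else {
    L = tot / 3.0;
  }
  NumericVector rootD = NumericVector::create(DA, DB, DAB);
  NumericVector rootE = NumericVector::create(E[3 * r], E[3 * r + 1],
                                              E[3 * r + 2]);
  return List::create(_["loglik"] = std::log(L) + logcomp,
                      _["rootD"] = rootD, _["rootE"] = rootE);
}
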