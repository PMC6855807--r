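// Delta-scored Metropolis Monte Carlo core for the coarse-grained docking
// sampler. All randomness is drawn from R's RNG stream so runs are
// reproducible under set.seed(). Scores are the three coordinate-dependent
// components of the negative log posterior: cross-link negative log
// likelihood, excluded-volume penalty, sequence-connectivity penalty.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Par {
  double d0, alpha, kEv, kC, dConn;
  double maxTrans, maxRot, maxTransBead, psiSigma, psiMin, psiMax;
  int bodyRepeats;  // rigid-body proposals per body per sweep
};

struct Sys {
  int n;
  std::vector<double> x, y, z, radii;
  std::vector<int> comp, res, body;          // body 0 = flexible
  std::vector<std::vector<int>> bodyBeads;   // 0-based
  std::vector<int> flexBeads;                // 0-based
  std::vector<int> ci, cj;                   // connectivity pairs, 0-based
  std::vector<int> xi, xj, xcls;             // cross-links, 0-based class
  std::vector<double> xd0;                   // per-link switching distance
  int nClass;
  std::vector<std::vector<int>> connOf, xlOf; // per-bead incidence
  std::vector<std::vector<int>> xlOfClass;
};

inline double dist(const Sys& S, int i, int j) {
  double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// excluded volume applies to pairs in different rigid units that are not
// sequence-adjacent; same-rigid-body pairs are internally fixed
inline bool evAllowed(const Sys& S, int i, int j) {
  if (S.body[i] > 0 && S.body[i] == S.body[j]) return false;
  if (S.comp[i] == S.comp[j] && std::abs(S.res[i] - S.res[j]) == 1) return false;
  return true;
}

inline double evTerm(const Sys& S, const Par& P, int i, int j) {
  double s = S.radii[i] + S.radii[j];
  double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
  double d2 = dx * dx + dy * dy + dz * dz;
  if (d2 >= s * s) return 0.0;  // sqrt only for overlapping pairs
  double o = s - std::sqrt(d2);
  return P.kEv * o * o;
}

inline double connTerm(const Sys& S, const Par& P, int p) {
  int i = S.ci[p], j = S.cj[p];
  double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
  double d2 = dx * dx + dy * dy + dz * dz;
  if (d2 <= P.dConn * P.dConn) return 0.0;
  double o = std::sqrt(d2) - P.dConn;
  return P.kC * o * o;
}

inline double xlTerm(const Sys& S, const Par& P, const std::vector<double>& psi,
                     int k) {
  double d = dist(S, S.xi[k], S.xj[k]);
  double f = 1.0 / (1.0 + std::exp(P.alpha * (d - S.xd0[k])));
  double ps = psi[S.xcls[k]];
  double p = ps + (1.0 - 2.0 * ps) * f;
  return -std::log(p);
}

double evFull(const Sys& S, const Par& P) {
  double e = 0.0;
  for (int i = 0; i < S.n; ++i)
    for (int j = i + 1; j < S.n; ++j)
      if (evAllowed(S, i, j)) e += evTerm(S, P, i, j);
  return e;
}

double connFull(const Sys& S, const Par& P) {
  double e = 0.0;
  for (size_t p = 0; p < S.ci.size(); ++p) e += connTerm(S, P, (int)p);
  return e;
}

double xlFull(const Sys& S, const Par& P, const std::vector<double>& psi) {
  double e = 0.0;
  for (size_t k = 0; k < S.xi.size(); ++k) e += xlTerm(S, P, psi, (int)k);
  return e;
}

// partial energies involving a moved bead set (flagged in inS); pairs fully
// inside the set are rigid-invariant and skipped (or counted once, which
// cancels in the before/after difference)
double evPartial(const Sys& S, const Par& P, const std::vector<int>& set,
                 const std::vector<char>& inS) {
  double e = 0.0;
  for (int i : set)
    for (int j = 0; j < S.n; ++j)
      if (!inS[j] && evAllowed(S, i, j)) e += evTerm(S, P, i, j);
  return e;
}

double connPartial(const Sys& S, const Par& P, const std::vector<int>& set,
                   const std::vector<char>& inS) {
  double e = 0.0;
  for (int i : set)
    for (int p : S.connOf[i]) {
      int o = (S.ci[p] == i) ? S.cj[p] : S.ci[p];
      if (!inS[o] || o > i) e += connTerm(S, P, p);
    }
  return e;
}

double xlPartial(const Sys& S, const Par& P, const std::vector<double>& psi,
                 const std::vector<int>& set, const std::vector<char>& inS) {
  double e = 0.0;
  for (int i : set)
    for (int k : S.xlOf[i]) {
      int o = (S.xi[k] == i) ? S.xj[k] : S.xi[k];
      if (!inS[o] || o > i) e += xlTerm(S, P, psi, k);
    }
  return e;
}

void ballVector(double rmax, double* v) {
  double u[3];
  double nrm = 0.0;
  for (int d = 0; d < 3; ++d) { u[d] = norm_rand(); nrm += u[d] * u[d]; }
  nrm = std::sqrt(nrm);
  double r = rmax * std::cbrt(unif_rand());
  for (int d = 0; d < 3; ++d) v[d] = r * u[d] / nrm;
}

void rotationMatrix(double maxRot, double R[3][3]) {
  double a[3];
  double nrm = 0.0;
  for (int d = 0; d < 3; ++d) { a[d] = norm_rand(); nrm += a[d] * a[d]; }
  nrm = std::sqrt(nrm);
  for (int d = 0; d < 3; ++d) a[d] /= nrm;
  double th = unif_rand() * maxRot;
  double c = std::cos(th), s = std::sin(th), t = 1.0 - c;
  R[0][0] = c + a[0] * a[0] * t;
  R[0][1] = a[0] * a[1] * t - a[2] * s;
  R[0][2] = a[0] * a[2] * t + a[1] * s;
  R[1][0] = a[0] * a[1] * t + a[2] * s;
  R[1][1] = c + a[1] * a[1] * t;
  R[1][2] = a[1] * a[2] * t - a[0] * s;
  R[2][0] = a[0] * a[2] * t - a[1] * s;
  R[2][1] = a[1] * a[2] * t + a[0] * s;
  R[2][2] = c + a[2] * a[2] * t;
}

inline bool accept(double dS, double temperature) {
  if (!std::isfinite(dS)) return false;
  if (dS <= 0.0) return true;
  return unif_rand() < std::exp(-dS / temperature);
}

inline double reflectPsi(double v, double lo, double hi) {
  // reflecting boundaries keep the Gaussian proposal symmetric
  double w = hi - lo;
  for (int it = 0; it < 64 && (v < lo || v > hi); ++it) {
    if (v < lo) v = 2.0 * lo - v;
    if (v > hi) v = 2.0 * hi - v;
  }
  if (v < lo || v > hi) v = lo + 0.5 * w;
  return v;
}

Sys buildSys(NumericMatrix coords, NumericVector radii, IntegerVector comp,
             IntegerVector resid, IntegerVector body, List bodyBeads,
             IntegerVector flexBeads, IntegerMatrix connPairs,
             IntegerMatrix xlPairs, IntegerVector xlClass,
             NumericVector xlD0, int nClass) {
  Sys S;
  S.n = coords.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = coords(i, 0); S.y[i] = coords(i, 1); S.z[i] = coords(i, 2);
  }
  S.radii = as<std::vector<double>>(radii);
  S.comp = as<std::vector<int>>(comp);
  S.res = as<std::vector<int>>(resid);
  S.body = as<std::vector<int>>(body);
  for (int b = 0; b < bodyBeads.size(); ++b) {
    IntegerVector v = bodyBeads[b];
    std::vector<int> w(v.size());
    for (int i = 0; i < v.size(); ++i) w[i] = v[i] - 1;
    S.bodyBeads.push_back(w);
  }
  for (int i = 0; i < flexBeads.size(); ++i)
    S.flexBeads.push_back(flexBeads[i] - 1);
  for (int p = 0; p < connPairs.nrow(); ++p) {
    S.ci.push_back(connPairs(p, 0) - 1);
    S.cj.push_back(connPairs(p, 1) - 1);
  }
  for (int k = 0; k < xlPairs.nrow(); ++k) {
    S.xi.push_back(xlPairs(k, 0) - 1);
    S.xj.push_back(xlPairs(k, 1) - 1);
    S.xcls.push_back(xlClass[k] - 1);
    S.xd0.push_back(xlD0[k]);
  }
  S.nClass = nClass;
  S.connOf.assign(S.n, {});
  S.xlOf.assign(S.n, {});
  S.xlOfClass.assign(nClass, {});
  for (size_t p = 0; p < S.ci.size(); ++p) {
    S.connOf[S.ci[p]].push_back((int)p);
    S.connOf[S.cj[p]].push_back((int)p);
  }
  for (size_t k = 0; k < S.xi.size(); ++k) {
    S.xlOf[S.xi[k]].push_back((int)k);
    if (S.xj[k] != S.xi[k]) S.xlOf[S.xj[k]].push_back((int)k);
    S.xlOfClass[S.xcls[k]].push_back((int)k);
  }
  return S;
}

Par buildPar(List par) {
  Par P;
  P.d0 = par["d0"]; P.alpha = par["alpha"]; P.kEv = par["kEv"];
  P.kC = par["kC"]; P.dConn = par["dConn"];
  P.maxTrans = par["maxTrans"]; P.maxRot = par["maxRot"];
  P.maxTransBead = par["maxTransBead"]; P.psiSigma = par["psiSigma"];
  P.psiMin = par["psiMin"]; P.psiMax = par["psiMax"];
  P.bodyRepeats = par.containsElementNamed("bodyRepeats")
                      ? (int)as<int>(par["bodyRepeats"]) : 1;
  return P;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_score_full(NumericMatrix coords, NumericVector radii,
                             IntegerVector comp, IntegerVector resid,
                             IntegerVector body, List bodyBeads,
                             IntegerVector flexBeads, IntegerMatrix connPairs,
                             IntegerMatrix xlPairs, IntegerVector xlClass,
                             NumericVector xlD0, NumericVector psi, List par) {
  Sys S = buildSys(coords, radii, comp, resid, body, bodyBeads, flexBeads,
                   connPairs, xlPairs, xlClass, xlD0, psi.size());
  Par P = buildPar(par);
  std::vector<double> ps = as<std::vector<double>>(psi);
  return NumericVector::create(_["xl_negloglik"] = xlFull(S, P, ps),
                               _["excluded_volume"] = evFull(S, P),
                               _["connectivity"] = connFull(S, P));
}

// [[Rcpp::export]]
List cpp_mc_sweeps(NumericMatrix coords, NumericVector radii,
                   IntegerVector comp, IntegerVector resid, IntegerVector body,
                   List bodyBeads, IntegerVector flexBeads,
                   IntegerMatrix connPairs, IntegerMatrix xlPairs,
                   IntegerVector xlClass, NumericVector xlD0,
                   NumericVector psi, double temperature, int nSweeps,
                   List par, bool save) {
  RNGScope rngScope;
  Sys S = buildSys(coords, radii, comp, resid, body, bodyBeads, flexBeads,
                   connPairs, xlPairs, xlClass, xlD0, psi.size());
  Par P = buildPar(par);
  std::vector<double> ps = as<std::vector<double>>(psi);

  double evTot = evFull(S, P);
  double connTot = connFull(S, P);
  double xlTot = xlFull(S, P, ps);

  std::vector<char> inS(S.n, 0);
  std::vector<double> ox(S.n), oy(S.n), oz(S.n);

  NumericMatrix scores(save ? nSweeps : 0, 4);
  NumericMatrix psiTrace(save ? nSweeps : 0, S.nClass);
  NumericVector savedCoords(save ? (R_xlen_t)S.n * 3 * nSweeps : 0);

  long bodyAtt = 0, bodyAcc = 0, beadAtt = 0, beadAcc = 0;
  long psiAtt = 0, psiAcc = 0;

  for (int sw = 0; sw < nSweeps; ++sw) {
    // rigid-body moves: coupled random translation (<= maxTrans) and
    // rotation about the body centroid (<= maxRot); bodies are the critical
    // degrees of freedom, so each gets bodyRepeats proposals per sweep
    for (int rep = 0; rep < P.bodyRepeats; ++rep)
    for (size_t b = 0; b < S.bodyBeads.size(); ++b) {
      const std::vector<int>& set = S.bodyBeads[b];
      for (int i : set) inS[i] = 1;
      double oEv = evPartial(S, P, set, inS), oCo = connPartial(S, P, set, inS),
             oXl = xlPartial(S, P, ps, set, inS);
      double cx = 0, cy = 0, cz = 0;
      for (int i : set) { cx += S.x[i]; cy += S.y[i]; cz += S.z[i]; }
      cx /= set.size(); cy /= set.size(); cz /= set.size();
      double R[3][3], tv[3];
      rotationMatrix(P.maxRot, R);
      ballVector(P.maxTrans, tv);
      for (int i : set) {
        ox[i] = S.x[i]; oy[i] = S.y[i]; oz[i] = S.z[i];
        double px = S.x[i] - cx, py = S.y[i] - cy, pz = S.z[i] - cz;
        S.x[i] = R[0][0] * px + R[0][1] * py + R[0][2] * pz + cx + tv[0];
        S.y[i] = R[1][0] * px + R[1][1] * py + R[1][2] * pz + cy + tv[1];
        S.z[i] = R[2][0] * px + R[2][1] * py + R[2][2] * pz + cz + tv[2];
      }
      double nEv = evPartial(S, P, set, inS), nCo = connPartial(S, P, set, inS),
             nXl = xlPartial(S, P, ps, set, inS);
      ++bodyAtt;
      if (accept((nEv - oEv) + (nCo - oCo) + (nXl - oXl), temperature)) {
        ++bodyAcc;
        evTot += nEv - oEv; connTot += nCo - oCo; xlTot += nXl - oXl;
      } else {
        for (int i : set) { S.x[i] = ox[i]; S.y[i] = oy[i]; S.z[i] = oz[i]; }
      }
      for (int i : set) inS[i] = 0;
    }

    // flexible-bead moves: random translation (<= maxTransBead)
    for (int i : S.flexBeads) {
      std::vector<int> set = {i};
      inS[i] = 1;
      double oEv = evPartial(S, P, set, inS), oCo = connPartial(S, P, set, inS),
             oXl = xlPartial(S, P, ps, set, inS);
      double tv[3];
      ballVector(P.maxTransBead, tv);
      ox[i] = S.x[i]; oy[i] = S.y[i]; oz[i] = S.z[i];
      S.x[i] += tv[0]; S.y[i] += tv[1]; S.z[i] += tv[2];
      double nEv = evPartial(S, P, set, inS), nCo = connPartial(S, P, set, inS),
             nXl = xlPartial(S, P, ps, set, inS);
      ++beadAtt;
      if (accept((nEv - oEv) + (nCo - oCo) + (nXl - oXl), temperature)) {
        ++beadAcc;
        evTot += nEv - oEv; connTot += nCo - oCo; xlTot += nXl - oXl;
      } else {
        S.x[i] = ox[i]; S.y[i] = oy[i]; S.z[i] = oz[i];
      }
      inS[i] = 0;
    }

    // psi moves: Gaussian perturbation with reflecting boundaries
    for (int c = 0; c < S.nClass; ++c) {
      double oldV = ps[c];
      double oldE = 0.0;
      for (int k : S.xlOfClass[c]) oldE += xlTerm(S, P, ps, k);
      ps[c] = reflectPsi(oldV + P.psiSigma * norm_rand(), P.psiMin, P.psiMax);
      double newE = 0.0;
      for (int k : S.xlOfClass[c]) newE += xlTerm(S, P, ps, k);
      ++psiAtt;
      if (accept(newE - oldE, temperature)) {
        ++psiAcc;
        xlTot += newE - oldE;
      } else {
        ps[c] = oldV;
      }
    }

    if (save) {
      scores(sw, 0) = xlTot; scores(sw, 1) = evTot; scores(sw, 2) = connTot;
      scores(sw, 3) = xlTot + evTot + connTot;
      for (int c = 0; c < S.nClass; ++c) psiTrace(sw, c) = ps[c];
      R_xlen_t off = (R_xlen_t)sw * S.n * 3;
      for (int i = 0; i < S.n; ++i) {
        savedCoords[off + i] = S.x[i];
        savedCoords[off + S.n + i] = S.y[i];
        savedCoords[off + 2 * S.n + i] = S.z[i];
      }
    }
  }

  NumericMatrix outCoords(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    outCoords(i, 0) = S.x[i]; outCoords(i, 1) = S.y[i]; outCoords(i, 2) = S.z[i];
  }
  return List::create(
      _["coords"] = outCoords, _["psi"] = NumericVector(ps.begin(), ps.end()),
      _["score"] = NumericVector::create(_["xl_negloglik"] = xlTot,
                                         _["excluded_volume"] = evTot,
                                         _["connectivity"] = connTot),
      _["scores"] = scores, _["psiTrace"] = psiTrace,
      _["savedCoords"] = savedCoords,
      _["accept"] = NumericVector::create(
          _["body_att"] = (double)bodyAtt, _["body_acc"] = (double)bodyAcc,
          _["bead_att"] = (double)beadAtt, _["bead_acc"] = (double)beadAcc,
          _["psi_att"] = (double)psiAtt, _["psi_acc"] = (double)psiAcc));
}
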