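// Compiled core for the avoidance Q-learning model: teacher-forced
// likelihood evaluation over parameter lattices, a per-point likelihood
// evaluator, and the generative simulator.
//
// Outcome codes: 0 win, 1 lose, 2 none, 3 skip (reward trial),
// 4 skip (punishment trial). Response codes: 0 A, 1 B, 2 skip.
// Stimulus codes 0..3; valence codes 0 reward, 1 punishment.
//
// The grid fitter exploits two exact factorizations of the teacher-forced
// likelihood: (i) the Q trajectory does not depend on the temperature, so
// one trajectory serves every temperature value; (ii) expectancy rows of
// different stimuli never interact, so the negLLE splits into a
// reward-stimulus part that depends on (LR+, LR-, R0, RSrew) and a
// punishment-stimulus part that depends on (LR+, LR-, R0, RSpun). Both are
// pure reorganizations of the exhaustive sweep: argmin-equivalence against
// a naive per-trial loop is asserted in the test suite.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace {

const double TIE_EPS = 1e-12;

// -log Pr(chosen | q, T); T == 0 is the argmax limit with uniform ties.
inline double trial_negll(const double* q, int chosen, double T) {
  double m = q[0];
  if (q[1] > m) m = q[1];
  if (q[2] > m) m = q[2];
  if (T <= 0.0) {
    if (q[chosen] < m - TIE_EPS) return R_PosInf;
    int nt = 0;
    for (int j = 0; j < 3; ++j)
      if (q[j] >= m - TIE_EPS) ++nt;
    return std::log((double)nt);
  }
  double s = std::exp((q[0] - m) / T) + std::exp((q[1] - m) / T) +
             std::exp((q[2] - m) / T);
  return std::log(s) - (q[chosen] - m) / T;
}

inline void choice_probs(const double* q, double T, double* p) {
  double m = q[0];
  if (q[1] > m) m = q[1];
  if (q[2] > m) m = q[2];
  if (T <= 0.0) {
    int nt = 0;
    for (int j = 0; j < 3; ++j)
      if (q[j] >= m - TIE_EPS) ++nt;
    for (int j = 0; j < 3; ++j)
      p[j] = (q[j] >= m - TIE_EPS) ? 1.0 / nt : 0.0;
  } else {
    double s = 0.0;
    for (int j = 0; j < 3; ++j) {
      p[j] = std::exp((q[j] - m) / T);
      s += p[j];
    }
    for (int j = 0; j < 3; ++j) p[j] /= s;
  }
}

inline double reinf(int outc, double r0, double rsr, double rsp) {
  switch (outc) {
    case 0: return 1.0;
    case 1: return -1.0;
    case 2: return r0;
    case 3: return rsr;
    default: return rsp;
  }
}

// Teacher-forced trajectory over the trials in idx; stores the Q row of
// the presented stimulus (before updating) and the chosen response.
void trajectory(const int* stim, const int* resp, const int* outc,
                const std::vector<int>& idx, double lrp, double lrm,
                double r0, double rsr, double rsp, double* qrows,
                int* chosen) {
  double Q[4][3];
  std::memset(Q, 0, sizeof(Q));
  for (size_t i = 0; i < idx.size(); ++i) {
    int t = idx[i], s = stim[t], r = resp[t];
    qrows[3 * i] = Q[s][0];
    qrows[3 * i + 1] = Q[s][1];
    qrows[3 * i + 2] = Q[s][2];
    chosen[i] = r;
    double pe = reinf(outc[t], r0, rsr, rsp) - Q[s][r];
    if (pe > 0)
      Q[s][r] += pe * lrp;
    else if (pe < 0)
      Q[s][r] += pe * lrm;
  }
}

// negLLE table over (lr pair, r0, rs, T) for one trial subset.
// Layout: ((a * n_r0 + b) * n_rs + c) * n_T + ti.
void build_table(const int* stim, const int* resp, const int* outc,
                 const std::vector<int>& idx, const NumericMatrix& lr,
                 const NumericVector& r0v, const NumericVector& rsv,
                 bool rs_is_reward, const NumericVector& Tv,
                 std::vector<double>& out) {
  int nlr = lr.nrow(), nr0 = r0v.size(), nrs = rsv.size(), nT = Tv.size();
  int ntr = (int)idx.size();
  std::vector<double> qrows(3 * (ntr > 0 ? ntr : 1));
  std::vector<int> chosen(ntr > 0 ? ntr : 1);
  size_t pos = 0;
  for (int a = 0; a < nlr; ++a) {
    for (int b = 0; b < nr0; ++b) {
      for (int c = 0; c < nrs; ++c) {
        double rsr = rs_is_reward ? rsv[c] : 0.0;
        double rsp = rs_is_reward ? 0.0 : rsv[c];
        trajectory(stim, resp, outc, idx, lr(a, 0), lr(a, 1), r0v[b], rsr,
                   rsp, qrows.data(), chosen.data());
        for (int ti = 0; ti < nT; ++ti, ++pos) {
          double T = Tv[ti], acc = 0.0;
          for (int i = 0; i < ntr; ++i)
            acc += trial_negll(&qrows[3 * i], chosen[i], T);
          out[pos] = acc;
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
}

inline size_t tidx(int a, int b, int c, int ti, int nr0, int nrs, int nT) {
  return (((size_t)a * nr0 + b) * nrs + c) * nT + ti;
}

}  // namespace

// Exhaustive grid-search MLE for one session. lr_pairs holds one row per
// admissible (LR+, LR-) combination (the diagonal for the tied-LR model).
// tie_rs forces RSrew == RSpun (their value lists must then be identical).
// Returns the minimum negLLE and the set of lattice points attaining it
// within tol, capped at max_argmin rows.
// [[Rcpp::export]]
List fit_grid_cpp(IntegerVector stim, IntegerVector resp,
                  IntegerVector outc, IntegerVector valence,
                  NumericMatrix lr_pairs, NumericVector r0_vals,
                  NumericVector rs_rew_vals, NumericVector rs_pun_vals,
                  NumericVector T_vals, bool tie_rs, double tol,
                  int max_argmin) {
  int n = stim.size();
  std::vector<int> idxR, idxP;
  for (int t = 0; t < n; ++t)
    (valence[t] == 0 ? idxR : idxP).push_back(t);
  int nlr = lr_pairs.nrow(), nr0 = r0_vals.size(), nT = T_vals.size();
  int nrsr = rs_rew_vals.size(), nrsp = rs_pun_vals.size();
  if (nlr < 1 || nr0 < 1 || nT < 1 || nrsr < 1 || nrsp < 1)
    stop("empty parameter value list");
  if (tie_rs && nrsr != nrsp)
    stop("tied RS parameters require identical value lists");

  std::vector<double> A((size_t)nlr * nr0 * nrsr * nT);
  std::vector<double> B((size_t)nlr * nr0 * nrsp * nT);
  build_table(stim.begin(), resp.begin(), outc.begin(), idxR, lr_pairs,
              r0_vals, rs_rew_vals, true, T_vals, A);
  build_table(stim.begin(), resp.begin(), outc.begin(), idxP, lr_pairs,
              r0_vals, rs_pun_vals, false, T_vals, B);

  double best = R_PosInf;
  for (int a = 0; a < nlr; ++a)
    for (int b = 0; b < nr0; ++b)
      for (int ti = 0; ti < nT; ++ti) {
        if (tie_rs) {
          for (int c = 0; c < nrsr; ++c) {
            double v = A[tidx(a, b, c, ti, nr0, nrsr, nT)] +
                       B[tidx(a, b, c, ti, nr0, nrsp, nT)];
            if (v < best) best = v;
          }
        } else {
          double mA = R_PosInf, mB = R_PosInf;
          for (int c = 0; c < nrsr; ++c) {
            double v = A[tidx(a, b, c, ti, nr0, nrsr, nT)];
            if (v < mA) mA = v;
          }
          for (int c = 0; c < nrsp; ++c) {
            double v = B[tidx(a, b, c, ti, nr0, nrsp, nT)];
            if (v < mB) mB = v;
          }
          double v = mA + mB;
          if (v < best) best = v;
        }
      }

  // Second pass: collect the argmin set.
  std::vector<double> rows;  // 6 doubles per point
  long long n_argmin = 0;
  bool truncated = false;
  double cut = best + tol;
  for (int a = 0; a < nlr; ++a)
    for (int b = 0; b < nr0; ++b)
      for (int ti = 0; ti < nT; ++ti) {
        if (tie_rs) {
          for (int c = 0; c < nrsr; ++c) {
            double v = A[tidx(a, b, c, ti, nr0, nrsr, nT)] +
                       B[tidx(a, b, c, ti, nr0, nrsp, nT)];
            if (v <= cut || (!R_FINITE(best) && !R_FINITE(v))) {
              ++n_argmin;
              if ((long long)rows.size() / 6 < max_argmin) {
                rows.push_back(lr_pairs(a, 0));
                rows.push_back(lr_pairs(a, 1));
                rows.push_back(T_vals[ti]);
                rows.push_back(r0_vals[b]);
                rows.push_back(rs_rew_vals[c]);
                rows.push_back(rs_pun_vals[c]);
              } else {
                truncated = true;
              }
            }
          }
        } else {
          for (int c1 = 0; c1 < nrsr; ++c1) {
            double va = A[tidx(a, b, c1, ti, nr0, nrsr, nT)];
            if (va > cut && R_FINITE(best)) continue;
            for (int c2 = 0; c2 < nrsp; ++c2) {
              double v = va + B[tidx(a, b, c2, ti, nr0, nrsp, nT)];
              if (v <= cut || (!R_FINITE(best) && !R_FINITE(v))) {
                ++n_argmin;
                if ((long long)rows.size() / 6 < max_argmin) {
                  rows.push_back(lr_pairs(a, 0));
                  rows.push_back(lr_pairs(a, 1));
                  rows.push_back(T_vals[ti]);
                  rows.push_back(r0_vals[b]);
                  rows.push_back(rs_rew_vals[c1]);
                  rows.push_back(rs_pun_vals[c2]);
                }
              }
            }
          }
        }
      }
  if (n_argmin > (long long)rows.size() / 6) truncated = true;

  int kept = (int)(rows.size() / 6);
  NumericMatrix argmin(kept, 6);
  for (int i = 0; i < kept; ++i)
    for (int j = 0; j < 6; ++j) argmin(i, j) = rows[6 * i + j];
  colnames(argmin) = CharacterVector::create(
      "lr_plus", "lr_minus", "temperature", "r0", "rs_rew", "rs_pun");

  double n_grid = (double)nlr * nr0 * nT *
                  (tie_rs ? (double)nrsr : (double)nrsr * nrsp);
  return List::create(_["neg_lle"] = best, _["argmin"] = argmin,
                      _["n_argmin"] = (double)n_argmin,
                      _["truncated"] = truncated,
                      _["n_grid_points"] = n_grid);
}

// Teacher-forced negLLE at arbitrary parameter points (columns: LR+, LR-,
// T, R0, RSrew, RSpun). Shares trial_negll/trajectory with the fitter.
// [[Rcpp::export]]
NumericVector negll_points_cpp(IntegerVector stim, IntegerVector resp,
                               IntegerVector outc, NumericMatrix params) {
  int n = stim.size(), m = params.nrow();
  std::vector<int> idx(n);
  for (int t = 0; t < n; ++t) idx[t] = t;
  std::vector<double> qrows(3 * (n > 0 ? n : 1));
  std::vector<int> chosen(n > 0 ? n : 1);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    trajectory(stim.begin(), resp.begin(), outc.begin(), idx, params(i, 0),
               params(i, 1), params(i, 3), params(i, 4), params(i, 5),
               qrows.data(), chosen.data());
    double T = params(i, 2), acc = 0.0;
    for (int t = 0; t < n; ++t)
      acc += trial_negll(&qrows[3 * t], chosen[t], T);
    out[i] = acc;
  }
  return out;
}

// Generative simulation of one session; uses R's RNG (one uniform draw
// per trial) so results are reproducible under set.seed().
// [[Rcpp::export]]
List simulate_cpp(IntegerVector stim, IntegerVector valence,
                  IntegerVector correct_cat, double lr_plus,
                  double lr_minus, double temperature, double r0,
                  double rs_rew, double rs_pun) {
  RNGScope scope;
  int n = stim.size();
  IntegerVector resp(n), outc(n);
  double Q[4][3];
  std::memset(Q, 0, sizeof(Q));
  double p[3];
  for (int t = 0; t < n; ++t) {
    int s = stim[t];
    choice_probs(Q[s], temperature, p);
    double u = unif_rand();
    int r = (u < p[0]) ? 0 : (u < p[0] + p[1] ? 1 : 2);
    int oc;
    if (r == 2)
      oc = (valence[t] == 0) ? 3 : 4;
    else if (valence[t] == 0)
      oc = (r == correct_cat[t]) ? 0 : 2;
    else
      oc = (r != correct_cat[t]) ? 1 : 2;
    resp[t] = r;
    outc[t] = oc;
    double pe = reinf(oc, r0, rs_rew, rs_pun) - Q[s][r];
    if (pe > 0)
      Q[s][r] += pe * lr_plus;
    else if (pe < 0)
      Q[s][r] += pe * lr_minus;
  }
  return List::create(_["response"] = resp, _["outcome"] = outc);
}
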