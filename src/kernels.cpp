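// Dynamic-programming kernels: profile-HMM Viterbi/Forward/Backward and
// covariance-model CYK/Inside (banded and scanning variants).
//
// All scores are log-odds in bits (log base 2). Two log-sum modes are
// provided: an exact mode (log1p/exp2, used by oracle-equivalence tests)
// and a fast approximation (table-driven in the scalar paths, polynomial
// in the vector paths) used by the scanning pipeline and calibration.
// The combine operation is a template policy so the hot loops inline;
// the float fill has an AVX2 build (accum_avx2.cpp) dispatched at run
// time.

#include <Rcpp.h>
#include "cm_kernel.h"
using namespace Rcpp;

double covmod_ls_tbl[LS_MAXD * LS_SCALE + 2];
static bool ls_ready = false;

static void ls_init() {
  if (ls_ready) return;
  for (int i = 0; i < LS_MAXD * LS_SCALE + 2; ++i) {
    double x = (double)i / LS_SCALE;
    covmod_ls_tbl[i] = std::log1p(std::exp2(-x)) / M_LN2;
  }
  ls_ready = true;
}

long long covmod_fill_fast_float_avx2(const CMView& cm, const int* x,
                                      int L, const int* ilo,
                                      const int* ihi, const int* jlo,
                                      const int* jhi,
                                      std::vector<float>& alpha, bool init);
long long covmod_fill_max_float_avx2(const CMView& cm, const int* x, int L,
                                     const int* ilo, const int* ihi,
                                     const int* jlo, const int* jhi,
                                     std::vector<float>& alpha, bool init);

static inline bool have_avx2() {
#if defined(__x86_64__) && defined(__GNUC__)
  static const bool v = __builtin_cpu_supports("avx2") &&
                        __builtin_cpu_supports("fma");
  return v;
#else
  return false;
#endif
}

static long long fill_fast_float(const CMView& cm, const int* x, int L,
                                 const int* ilo, const int* ihi,
                                 const int* jlo, const int* jhi,
                                 std::vector<float>& alpha, bool init) {
  if (have_avx2())
    return covmod_fill_fast_float_avx2(cm, x, L, ilo, ihi, jlo, jhi, alpha,
                                       init);
  return cm_fill_t<OpFast, float>(cm, x, L, ilo, ihi, jlo, jhi, alpha,
                                  init);
}

static long long fill_max_float(const CMView& cm, const int* x, int L,
                                const int* ilo, const int* ihi,
                                const int* jlo, const int* jhi,
                                std::vector<float>& alpha, bool init) {
  if (have_avx2())
    return covmod_fill_max_float_avx2(cm, x, L, ilo, ihi, jlo, jhi, alpha,
                                      init);
  return cm_fill_t<OpMax, float>(cm, x, L, ilo, ihi, jlo, jhi, alpha,
                                 init);
}

// ------------------------------------------------------------- HMM engine

// Match positions 1..M, inserts 1..M-1, deletes 1..M. trans: (M+1) x 9
// matrix of bit scores out of position k (row 0 = begin). Columns:
// MM MI MD IM II ID DM DI DD.
enum { TMM, TMI, TMD, TIM, TII, TID, TDM, TDI, TDD };

struct HmmDP {
  std::vector<double> FM, FI, FD, J;
  int W;
  double& fm(int k, int i) { return FM[k * W + i]; }
  double& fi(int k, int i) { return FI[k * W + i]; }
  double& fd(int k, int i) { return FD[k * W + i]; }
};

// Local summed (Forward) scoring is multi-hit: after a hit ends, the
// model may re-enter downstream through a free "joining" segment (the
// J array accumulates completed-hit mass per boundary). Local Viterbi
// stays single-hit (the classical best alignment); glocal is single-pass
// by construction.
template <class OP>
static double hmm_fill(const int* seq, int L, int M,
                       const NumericMatrix& mesc,
                       const NumericMatrix& trans, bool local,
                       bool multihit, HmmDP& dp) {
  const int W = L + 1;
  dp.W = W;
  dp.FM.assign((M + 1) * W, NEGINF);
  dp.FI.assign((M + 1) * W, NEGINF);
  dp.FD.assign((M + 1) * W, NEGINF);
  dp.J.assign(W, NEGINF);
  const double lbsc = local ? -std::log2((double)M) : NEGINF;
  for (int i = 0; i <= L; ++i) {
    for (int k = 1; k <= M; ++k) {
      double d = NEGINF;
      if (k == 1) {
        if (!local) d = trans(0, TMD);  // glocal entry into D1
      } else {
        d = OP::comb(d, dp.fm(k - 1, i) + trans(k - 1, TMD));
        d = OP::comb(d, dp.fi(k - 1, i) + trans(k - 1, TID));
        d = OP::comb(d, dp.fd(k - 1, i) + trans(k - 1, TDD));
      }
      dp.fd(k, i) = d;
      if (i >= 1) {
        int x = seq[i - 1] - 1;
        double entry = lbsc;
        if (local && multihit)
          entry = lbsc + OP::comb(0.0, dp.J[i - 1]);  // fresh or re-entry
        double m = local ? entry : (k == 1 ? trans(0, TMM) : NEGINF);
        if (k > 1) {
          m = OP::comb(m, dp.fm(k - 1, i - 1) + trans(k - 1, TMM));
          m = OP::comb(m, dp.fi(k - 1, i - 1) + trans(k - 1, TIM));
          m = OP::comb(m, dp.fd(k - 1, i - 1) + trans(k - 1, TDM));
        }
        dp.fm(k, i) = mesc(k - 1, x) + m;
        if (k < M) {
          double v = NEGINF;
          v = OP::comb(v, dp.fm(k, i - 1) + trans(k, TMI));
          v = OP::comb(v, dp.fi(k, i - 1) + trans(k, TII));
          v = OP::comb(v, dp.fd(k, i - 1) + trans(k, TDI));
          dp.fi(k, i) = v;  // insert emissions score 0 (null)
        }
      }
    }
    if (local && i >= 1) {
      double etot = NEGINF;
      for (int k = 1; k <= M; ++k) etot = OP::comb(etot, dp.fm(k, i));
      dp.J[i] = OP::comb(dp.J[i - 1], etot + lbsc);  // uniform exit cost
    }
  }
  double total = NEGINF;
  if (local) {
    if (multihit) {
      total = dp.J[L];
    } else {
      for (int i = 1; i <= L; ++i)
        for (int k = 1; k <= M; ++k) total = OP::comb(total, dp.fm(k, i));
      total = total + lbsc;  // uniform exit cost, once per (single) hit
    }
  } else {
    // glocal: end at M_M or D_M anywhere (trailing flank is free); the
    // all-delete path is reached through the FD chain, including L == 0
    for (int i = 0; i <= L; ++i) {
      total = OP::comb(total, dp.fm(M, i));
      total = OP::comb(total, dp.fd(M, i));
    }
  }
  return total;
}

// [[Rcpp::export]]
List hmm_engine_cpp(IntegerVector seq, int M, NumericMatrix mesc,
                    NumericMatrix trans, bool local, bool forward,
                    bool posterior, bool exact) {
  ls_init();
  const int L = seq.size();
  const int W = L + 1;
  std::vector<int> x(L);
  for (int i = 0; i < L; ++i) x[i] = seq[i];
  HmmDP dp;
  double total;
  bool multihit = local;  // summed local scoring is multi-hit
  if (!forward) {
    total = hmm_fill<OpMax>(x.data(), L, M, mesc, trans, local, false, dp);
  } else if (exact || posterior) {
    total = hmm_fill<OpExact>(x.data(), L, M, mesc, trans, local,
                              multihit, dp);
  } else {
    total = hmm_fill<OpFast>(x.data(), L, M, mesc, trans, local, multihit,
                             dp);
  }
  List out = List::create(Named("score") = total);
  if (!posterior) return out;

  // Backward (exact arithmetic, forward semantics). In local mode a hit
  // end leads to BJ(i): either finish or re-enter downstream.
  std::vector<double> BM((M + 1) * W, NEGINF), BI((M + 1) * W, NEGINF),
      BD((M + 1) * W, NEGINF), BJ(W, NEGINF);
  auto at = [W](std::vector<double>& A, int k, int i) -> double& {
    return A[k * W + i];
  };
  const double lbsc = local ? -std::log2((double)M) : NEGINF;
  for (int i = L; i >= 0; --i) {
    if (local) {
      // BJ(i): after a hit ends at boundary i, either finish (free
      // trailing flank, the 0 carried from BJ(L)) or re-enter at some
      // later position
      if (i == L) {
        BJ[i] = 0.0;
      } else {
        int xi = x[i] - 1;
        double entry = NEGINF;
        for (int k = 1; k <= M; ++k) {
          entry = OpExact::comb(entry,
                                mesc(k - 1, xi) + at(BM, k, i + 1));
        }
        BJ[i] = OpExact::comb(BJ[i + 1], lbsc + entry);
      }
    }
    for (int k = M; k >= 1; --k) {
      double endm = local ? lbsc + BJ[i] : (k == M ? 0.0 : NEGINF);
      double endd = local ? NEGINF : (k == M ? 0.0 : NEGINF);
      double bm = endm, bd = endd, bi = NEGINF;
      if (k < M) {
        if (i < L) {
          int xi = x[i] - 1;
          double mnext = mesc(k, xi) + at(BM, k + 1, i + 1);
          bm = OpExact::comb(bm, trans(k, TMM) + mnext);
          bi = OpExact::comb(bi, trans(k, TIM) + mnext);
          bd = OpExact::comb(bd, trans(k, TDM) + mnext);
          bm = OpExact::comb(bm, trans(k, TMI) + at(BI, k, i + 1));
          bi = OpExact::comb(bi, trans(k, TII) + at(BI, k, i + 1));
          bd = OpExact::comb(bd, trans(k, TDI) + at(BI, k, i + 1));
        }
        bm = OpExact::comb(bm, trans(k, TMD) + at(BD, k + 1, i));
        bi = OpExact::comb(bi, trans(k, TID) + at(BD, k + 1, i));
        bd = OpExact::comb(bd, trans(k, TDD) + at(BD, k + 1, i));
      }
      at(BM, k, i) = bm;
      at(BI, k, i) = bi;
      at(BD, k, i) = bd;
    }
  }
  NumericMatrix pm(M, L);
  NumericVector pin(L);
  for (int i = 1; i <= L; ++i) {
    double s = 0;
    for (int k = 1; k <= M; ++k) {
      double vm = dp.fm(k, i) + at(BM, k, i) - total;
      double p = (vm <= NEGHALF) ? 0.0 : std::exp2(vm);
      pm(k - 1, i - 1) = p;
      s += p;
      if (k < M) {
        double vi = dp.fi(k, i) + at(BI, k, i) - total;
        if (vi > NEGHALF) s += std::exp2(vi);
      }
    }
    pin[i - 1] = std::min(1.0, s);
  }
  out["match_posterior"] = pm;
  out["in_model_posterior"] = pin;
  return out;
}

// Tile one strand into windows and score each with the HMM (Viterbi or
// Forward, fast log-sum). The C++ window loop avoids per-window call
// overhead during whole-database scans.
// [[Rcpp::export]]
NumericMatrix hmm_scan_cpp(IntegerVector seq, int M, NumericMatrix mesc,
                           NumericMatrix trans, bool local, bool forward,
                           int window_len, int stride) {
  ls_init();
  const int L = seq.size();
  std::vector<int> x(L);
  for (int i = 0; i < L; ++i) x[i] = seq[i];
  std::vector<int> starts;
  if (L <= window_len) {
    starts.push_back(1);
  } else {
    for (int s = 1; s + window_len - 1 <= L; s += stride) starts.push_back(s);
    if (starts.back() + window_len - 1 < L)
      starts.push_back(L - window_len + 1);
  }
  NumericMatrix out(starts.size(), 3);
  HmmDP dp;
  for (size_t w = 0; w < starts.size(); ++w) {
    int s = starts[w];
    int wl = std::min(window_len, L - s + 1);
    double sc;
    if (!forward) {
      sc = hmm_fill<OpMax>(x.data() + (s - 1), wl, M, mesc, trans, local,
                           false, dp);
    } else {
      sc = hmm_fill<OpFast>(x.data() + (s - 1), wl, M, mesc, trans, local,
                            local, dp);
    }
    out(w, 0) = s;
    out(w, 1) = s + wl - 1;
    out(w, 2) = sc;
  }
  return out;
}

// -------------------------------------------------------------- CM engine

static long long cm_fill(const CMView& cm, const int* x, int L,
                         const int* ilo, const int* ihi, const int* jlo,
                         const int* jhi, bool inside, bool exact,
                         std::vector<double>& alpha, bool init) {
  ls_init();
  if (!inside)
    return cm_fill_t<OpMax>(cm, x, L, ilo, ihi, jlo, jhi, alpha, init);
  if (exact)
    return cm_fill_t<OpExact>(cm, x, L, ilo, ihi, jlo, jhi, alpha, init);
  return cm_fill_t<OpFast>(cm, x, L, ilo, ihi, jlo, jhi, alpha, init);
}

static CMView unpack_cm(const List& pack, IntegerVector& stype,
                        IntegerVector& child, IntegerVector& child_off,
                        NumericVector& tsc, NumericMatrix& esc1,
                        NumericMatrix& esc2, IntegerVector& bstate) {
  CMView cm;
  stype = pack["stype"];
  child = pack["child"];
  child_off = pack["child_off"];
  tsc = pack["tsc"];
  esc1 = as<NumericMatrix>(pack["esc1"]);
  esc2 = as<NumericMatrix>(pack["esc2"]);
  bstate = pack["begin_states"];
  cm.ns = stype.size();
  cm.stype = INTEGER(stype);
  cm.child = INTEGER(child);
  cm.child_off = INTEGER(child_off);
  cm.tsc = REAL(tsc);
  cm.esc1 = REAL(esc1);
  cm.esc2 = REAL(esc2);
  cm.bstate = INTEGER(bstate);
  cm.nbegin = bstate.size();
  cm.begin_sc = as<double>(pack["begin_sc"]);
  cm.end_sc = as<double>(pack["end_sc"]);
  cm.local = as<bool>(pack["local"]);
  cm.esc1f.assign(cm.esc1, cm.esc1 + (size_t)cm.ns * 15);
  cm.esc2f.assign(cm.esc2, cm.esc2 + (size_t)cm.ns * 225);
  return cm;
}

// CYK traceback by candidate re-evaluation. Deterministic preferences:
// children in listed (ascending-index) order, then local begins in listed
// order, then the local-end (EL) candidate. For bifurcations the smaller
// left-child interval wins ties.
static void cm_traceback(const CMView& cm, const int* x, int L,
                         const std::vector<double>& alpha, int j0, int d0,
                         std::vector<int>& tv, std::vector<int>& ti,
                         std::vector<int>& tj) {
  const size_t plane = TRI(L + 1);
  struct Cell { int v, j, d; };
  std::vector<Cell> stack;
  stack.push_back({0, j0, d0});
  while (!stack.empty()) {
    Cell c = stack.back();
    stack.pop_back();
    int v = c.v, j = c.j, d = c.d, i = j - d + 1;
    if (v == -1) {  // EL: emits its interval at the null
      tv.push_back(-1); ti.push_back(i); tj.push_back(j);
      continue;
    }
    tv.push_back(v); ti.push_back(i); tj.push_back(j);
    const int ty = cm.stype[v];
    const double stored = alpha[(size_t)v * plane + TRI(j) + d];
    if (ty == ST_E) continue;
    if (stored <= NEGHALF) stop("traceback entered an impossible cell");
    if (ty == ST_B) {
      const int l = cm.child[cm.child_off[v]];
      const int r = cm.child[cm.child_off[v] + 1];
      const double* al = &alpha[(size_t)l * plane];
      const double* ar = &alpha[(size_t)r * plane];
      bool found = false;
      for (int k = d; k >= 0 && !found; --k) {
        double cv = al[TRI(j - k) + (d - k)] + ar[TRI(j) + k];
        if (cv == stored) {
          stack.push_back({r, j, k});
          stack.push_back({l, j - k, d - k});
          found = true;
        }
      }
      if (!found) stop("bifurcation traceback failed");
      continue;
    }
    const int demit = (ty == ST_MP) ? 2
                      : (ty == ST_S || ty == ST_D) ? 0 : 1;
    const bool remit = (ty == ST_MR || ty == ST_IR || ty == ST_MP);
    const int jc = remit ? j - 1 : j;
    double esc = 0.0;
    if (ty == ST_MP) esc = e2<double>(cm, v, x[i - 1], x[j - 1]);
    else if (ty == ST_ML || ty == ST_IL) esc = e1<double>(cm, v, x[i - 1]);
    else if (ty == ST_MR || ty == ST_IR) esc = e1<double>(cm, v, x[j - 1]);
    bool found = false;
    for (int cdx = cm.child_off[v]; cdx < cm.child_off[v + 1] && !found;
         ++cdx) {
      const int y = cm.child[cdx];
      double cv = esc + (cm.tsc[cdx] +
                         alpha[(size_t)y * plane + TRI(jc) + (d - demit)]);
      if (cv == stored) {
        stack.push_back({y, jc, d - demit});
        found = true;
      }
    }
    if (!found && v == 0 && cm.local) {
      for (int b = 0; b < cm.nbegin && !found; ++b) {
        int y = cm.bstate[b];
        double cv = cm.begin_sc + alpha[(size_t)y * plane + TRI(j) + d];
        if (cv == stored) {
          stack.push_back({y, j, d});
          found = true;
        }
      }
    }
    if (!found && cm.local &&
        (ty == ST_MP || ty == ST_ML || ty == ST_MR)) {
      double cv = esc + cm.end_sc;
      if (cv == stored) {
        int eli = (ty == ST_MR) ? i : i + 1;
        int elj = remit ? j - 1 : j;
        stack.push_back({-1, elj, elj - eli + 1});
        found = true;
      }
    }
    if (!found) stop("traceback failed at state ", v);
  }
}

// [[Rcpp::export]]
List cm_engine_cpp(IntegerVector seq, List pack, bool inside, bool scan,
                   bool exact, IntegerVector ilo, IntegerVector ihi,
                   IntegerVector jlo, IntegerVector jhi, bool traceback) {
  ls_init();
  IntegerVector stype, child, child_off, bstate;
  NumericVector tsc;
  NumericMatrix esc1, esc2;
  CMView cm = unpack_cm(pack, stype, child, child_off, tsc, esc1, esc2,
                        bstate);
  const int L = seq.size();
  std::vector<int> x(L);
  for (int i = 0; i < L; ++i) x[i] = seq[i] - 1;
  double score;
  long long cells;
  int bj = L, bd = L;
  std::vector<double> alpha;
  if (inside && !exact) {
    // approximate summed scoring runs in the float path (same kernel as
    // the strand scanner, so calibration and search scores agree)
    std::vector<float> alphaf;
    cells = fill_fast_float(cm, x.data(), L, INTEGER(ilo), INTEGER(ihi),
                            INTEGER(jlo), INTEGER(jhi), alphaf, true);
    if (scan) {
      score = NEGINF;
      for (int j = 1; j <= L; ++j)
        for (int d = 1; d <= j; ++d)
          score = OpFast::comb(score, (double)alphaf[TRI(j) + d]);
    } else {
      score = alphaf[TRI(L) + L];
    }
  } else {
    cells = cm_fill(cm, x.data(), L, INTEGER(ilo), INTEGER(ihi),
                    INTEGER(jlo), INTEGER(jhi), inside, exact, alpha, true);
    if (scan) {
      score = NEGINF;
      for (int j = 1; j <= L; ++j) {
        for (int d = 1; d <= j; ++d) {
          double vsc = alpha[TRI(j) + d];
          if (!inside) {
            if (vsc > score) { score = vsc; bj = j; bd = d; }
          } else {
            score = OpExact::comb(score, vsc);
          }
        }
      }
    } else {
      score = alpha[TRI(L) + L];
    }
  }
  List out = List::create(Named("score") = score,
                          Named("cells") = (double)cells,
                          Named("i") = bj - bd + 1, Named("j") = bj);
  if (traceback && !inside && score > NEGHALF) {
    std::vector<int> tv, ti, tj;
    cm_traceback(cm, x.data(), L, alpha, bj, bd, tv, ti, tj);
    IntegerMatrix tree(tv.size(), 3);
    for (size_t k = 0; k < tv.size(); ++k) {
      tree(k, 0) = tv[k] + 1;  // 1-based; EL becomes 0
      tree(k, 1) = ti[k];
      tree(k, 2) = tj[k];
    }
    out["tree"] = tree;
  }
  return out;
}

// Scans one strand: tiles [1..L] into windows of length window_len with
// the given stride and returns the scan-mode score per window (local
// Inside or CYK, fast float path). Buffers are reused across windows.
// [[Rcpp::export]]
List cm_scan_cpp(IntegerVector seq, List pack, int window_len, int stride,
                 bool inside) {
  ls_init();
  IntegerVector stype, child, child_off, bstate;
  NumericVector tsc;
  NumericMatrix esc1, esc2;
  CMView cm = unpack_cm(pack, stype, child, child_off, tsc, esc1, esc2,
                        bstate);
  const int L = seq.size();
  std::vector<int> x(L);
  for (int i = 0; i < L; ++i) x[i] = seq[i] - 1;
  std::vector<int> starts;
  if (L <= window_len) {
    starts.push_back(1);
  } else {
    for (int s = 1; s + window_len - 1 <= L; s += stride) starts.push_back(s);
    if (starts.back() + window_len - 1 < L) starts.push_back(L - window_len + 1);
  }
  const int nw = starts.size();
  NumericVector scores(nw);
  IntegerVector ws(nw), we(nw);
  std::vector<float> alpha;
  std::vector<int> ilo(cm.ns), ihi(cm.ns), jlo(cm.ns), jhi(cm.ns);
  double total_cells = 0;
  for (int w = 0; w < nw; ++w) {
    int s = starts[w];
    int wl = std::min(window_len, L - s + 1);
    for (int v = 0; v < cm.ns; ++v) {
      ilo[v] = 1; ihi[v] = wl + 1; jlo[v] = 0; jhi[v] = wl;
    }
    if (inside) {
      total_cells += (double)fill_fast_float(
          cm, x.data() + (s - 1), wl, ilo.data(), ihi.data(), jlo.data(),
          jhi.data(), alpha, false);
    } else {
      total_cells += (double)fill_max_float(
          cm, x.data() + (s - 1), wl, ilo.data(), ihi.data(), jlo.data(),
          jhi.data(), alpha, false);
    }
    double sc = NEGINF;
    for (int j = 1; j <= wl; ++j) {
      const float* aj = &alpha[TRI(j)];
      for (int d = 1; d <= j; ++d) {
        double vsc = aj[d];
        sc = inside ? OpFast::comb(sc, vsc) : OpMax::comb(sc, vsc);
      }
    }
    scores[w] = sc;
    ws[w] = s;
    we[w] = s + wl - 1;
  }
  return List::create(Named("start") = ws, Named("end") = we,
                      Named("score") = scores,
                      Named("cells") = total_cells);
}
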