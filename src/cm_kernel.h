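// Shared CM dynamic-programming kernel: score-combination policies and
// the templated triangular fill. Included by kernels.cpp (generic/SSE2
// build) and by accum_avx2.cpp (AVX2+FMA build, COVMOD_AVX2_TU defined);
// entry points dispatch between the two at run time.
#ifndef COVMOD_CM_KERNEL_H
#define COVMOD_CM_KERNEL_H

#include <cmath>
#include <vector>
#include <algorithm>

static const double NEGINF = -1e30;
static const double NEGHALF = -5e29;  // "is -inf" test threshold

// table for log2(1 + 2^-x): resolution 1/256, range [0, 24]
#define LS_SCALE 256
#define LS_MAXD 24
extern double covmod_ls_tbl[LS_MAXD * LS_SCALE + 2];

struct OpMax {
  static inline double comb(double a, double b) { return a > b ? a : b; }
  static inline float comb(float a, float b) { return a > b ? a : b; }
};
struct OpFast {
  // branchless: the table's tail entries are ~0, so clamping the index
  // covers both the large-difference and the -inf cases (the ~9e-8 bit
  // error this adds is far below the table's own resolution)
  static inline double comb(double a, double b) {
    double mx = std::max(a, b), mn = std::min(a, b);
    double idx = std::min((mx - mn) * LS_SCALE,
                          (double)(LS_MAXD * LS_SCALE));
    return mx + covmod_ls_tbl[(int)idx];
  }
  static inline float comb(float a, float b) {
    float mx = std::max(a, b), mn = std::min(a, b);
    float idx = std::min((mx - mn) * (float)LS_SCALE,
                         (float)(LS_MAXD * LS_SCALE));
    return mx + (float)covmod_ls_tbl[(int)idx];
  }
};
struct OpExact {
  static inline double comb(double a, double b) {
    if (a < b) std::swap(a, b);
    if (b <= NEGHALF) return a;
    return a + std::log1p(std::exp2(b - a)) / M_LN2;
  }
};

// State type codes (must match the R side)
enum { ST_S = 0, ST_MP, ST_ML, ST_MR, ST_D, ST_IL, ST_IR, ST_B, ST_E };

struct CMView {
  int ns;
  const int* stype;
  const int* child;      // 0-based, concatenated
  const int* child_off;  // length ns+1
  const double* tsc;     // parallel to child
  const double* esc1;    // ns x 15, column-major from R
  const double* esc2;    // ns x 225
  const int* bstate;     // local begin targets, 0-based
  int nbegin;
  double begin_sc, end_sc;
  bool local;
  std::vector<float> esc1f, esc2f;  // float copies for the float path
};

// emission lookups in the matrix element type
template <class T>
static inline T e1(const CMView& cm, int v, int x) {
  return (T)cm.esc1[x * cm.ns + v];
}
template <>
inline float e1<float>(const CMView& cm, int v, int x) {
  return cm.esc1f[x * cm.ns + v];
}
template <class T>
static inline T e2(const CMView& cm, int v, int xi, int xj) {
  return (T)cm.esc2[(xi * 15 + xj) * cm.ns + v];
}
template <>
inline float e2<float>(const CMView& cm, int v, int xi, int xj) {
  return cm.esc2f[(xi * 15 + xj) * cm.ns + v];
}

// Triangular DP storage: row j holds cells d = 0..j, so a state's plane
// has (L+1)(L+2)/2 entries and row bases TRI(j) = j(j+1)/2. Rows stay
// d-contiguous, which the inner loops rely on.
static inline size_t TRI(int j) { return (size_t)j * (j + 1) / 2; }

// acc[d] = comb(acc[d], t + src[d]) over a row segment: the single hot
// operation of the CM DP (children accumulation, bifurcation splits and
// local begins all reduce to it). Arithmetic stays in the element type.
template <class OP, class T>
static inline void accum_row(T* acc, const T* src, double t, int dlo,
                             int dhi) {
  const T tt = (T)t;
  for (int d = dlo; d <= dhi; ++d)
    acc[d] = OP::comb(acc[d], (T)(tt + src[d]));
}

#ifdef COVMOD_AVX2_TU
#include <immintrin.h>

// 2^(-d) for d in [0, 30], 8 lanes
static inline __m256 covmod_exp2neg8(__m256 d) {
  __m256 e = _mm256_sub_ps(_mm256_setzero_ps(), d);
  __m256 fl = _mm256_floor_ps(e);
  __m256 f = _mm256_sub_ps(e, fl);  // [0, 1)
  __m256 p = _mm256_set1_ps(1.3697664e-2f);
  p = _mm256_fmadd_ps(p, f, _mm256_set1_ps(5.1690358e-2f));
  p = _mm256_fmadd_ps(p, f, _mm256_set1_ps(2.4163845e-1f));
  p = _mm256_fmadd_ps(p, f, _mm256_set1_ps(6.9296674e-1f));
  p = _mm256_fmadd_ps(p, f, _mm256_set1_ps(1.0f));
  __m256i ii = _mm256_cvtps_epi32(fl);
  __m256i sc =
      _mm256_slli_epi32(_mm256_add_epi32(ii, _mm256_set1_epi32(127)), 23);
  return _mm256_mul_ps(p, _mm256_castsi256_ps(sc));
}

// log2(1+z) for z in [0, 1] via the atanh series in s = z/(2+z)
static inline __m256 covmod_log2p1_8(__m256 z) {
  __m256 y = _mm256_add_ps(z, _mm256_set1_ps(2.0f));
  __m256 r = _mm256_rcp_ps(y);
  r = _mm256_mul_ps(r, _mm256_fnmadd_ps(y, r, _mm256_set1_ps(2.0f)));
  __m256 s = _mm256_mul_ps(z, r);
  __m256 s2 = _mm256_mul_ps(s, s);
  __m256 p = _mm256_set1_ps(0.14285715f);
  p = _mm256_fmadd_ps(p, s2, _mm256_set1_ps(0.2f));
  p = _mm256_fmadd_ps(p, s2, _mm256_set1_ps(0.33333334f));
  p = _mm256_fmadd_ps(p, s2, _mm256_set1_ps(1.0f));
  return _mm256_mul_ps(_mm256_mul_ps(s, p),
                       _mm256_set1_ps(2.8853900817779268f));  // 2/ln 2
}

static inline __m256 covmod_comb8(__m256 a, __m256 b) {
  __m256 mx = _mm256_max_ps(a, b);
  __m256 mn = _mm256_min_ps(a, b);
  __m256 d = _mm256_min_ps(_mm256_sub_ps(mx, mn), _mm256_set1_ps(24.0f));
  return _mm256_add_ps(mx, covmod_log2p1_8(covmod_exp2neg8(d)));
}

// AVX2 build of the float fast path (same accuracy class as the table)
template <>
inline void accum_row<OpFast, float>(float* acc, const float* src,
                                     double t, int dlo, int dhi) {
  int d = dlo;
  const __m256 tv = _mm256_set1_ps((float)t);
  for (; d + 7 <= dhi; d += 8) {
    __m256 a = _mm256_loadu_ps(acc + d);
    __m256 b = _mm256_add_ps(tv, _mm256_loadu_ps(src + d));
    _mm256_storeu_ps(acc + d, covmod_comb8(a, b));
  }
  for (; d <= dhi; ++d)
    acc[d] = OpFast::comb(acc[d], (float)((float)t + src[d]));
}

#elif defined(__SSE2__)
#include <emmintrin.h>

// 2^(-d) for d in [0, 30], 4 lanes
static inline __m128 covmod_exp2neg4(__m128 d) {
  __m128 e = _mm_sub_ps(_mm_setzero_ps(), d);
  __m128i ti = _mm_cvttps_epi32(e);
  __m128 tf = _mm_cvtepi32_ps(ti);
  __m128i ii = _mm_add_epi32(
      ti, _mm_castps_si128(_mm_cmpgt_ps(tf, e)));  // floor via -1 mask
  __m128 f = _mm_sub_ps(e, _mm_cvtepi32_ps(ii));   // f in [0, 1)
  __m128 p = _mm_set1_ps(1.3697664e-2f);
  p = _mm_add_ps(_mm_mul_ps(p, f), _mm_set1_ps(5.1690358e-2f));
  p = _mm_add_ps(_mm_mul_ps(p, f), _mm_set1_ps(2.4163845e-1f));
  p = _mm_add_ps(_mm_mul_ps(p, f), _mm_set1_ps(6.9296674e-1f));
  p = _mm_add_ps(_mm_mul_ps(p, f), _mm_set1_ps(1.0f));
  __m128i sc = _mm_slli_epi32(_mm_add_epi32(ii, _mm_set1_epi32(127)), 23);
  return _mm_mul_ps(p, _mm_castsi128_ps(sc));
}

// log2(1+z) for z in [0, 1], atanh series in s = z/(2+z)
static inline __m128 covmod_log2p1_4(__m128 z) {
  __m128 s = _mm_div_ps(z, _mm_add_ps(z, _mm_set1_ps(2.0f)));
  __m128 s2 = _mm_mul_ps(s, s);
  __m128 p = _mm_set1_ps(0.14285715f);
  p = _mm_add_ps(_mm_mul_ps(p, s2), _mm_set1_ps(0.2f));
  p = _mm_add_ps(_mm_mul_ps(p, s2), _mm_set1_ps(0.33333334f));
  p = _mm_add_ps(_mm_mul_ps(p, s2), _mm_set1_ps(1.0f));
  return _mm_mul_ps(_mm_mul_ps(s, p),
                    _mm_set1_ps(2.8853900817779268f));  // 2/ln(2)
}

static inline __m128 covmod_comb4(__m128 a, __m128 b) {
  __m128 mx = _mm_max_ps(a, b);
  __m128 mn = _mm_min_ps(a, b);
  __m128 d = _mm_min_ps(_mm_sub_ps(mx, mn), _mm_set1_ps(24.0f));
  return _mm_add_ps(mx, covmod_log2p1_4(covmod_exp2neg4(d)));
}

// SSE2 build of the float fast path
template <>
inline void accum_row<OpFast, float>(float* acc, const float* src,
                                     double t, int dlo, int dhi) {
  int d = dlo;
  const __m128 tv = _mm_set1_ps((float)t);
  for (; d + 3 <= dhi; d += 4) {
    __m128 a = _mm_loadu_ps(acc + d);
    __m128 b = _mm_add_ps(tv, _mm_loadu_ps(src + d));
    _mm_storeu_ps(acc + d, covmod_comb4(a, b));
  }
  for (; d <= dhi; ++d)
    acc[d] = OpFast::comb(acc[d], (float)((float)t + src[d]));
}
#endif

// Fill the inside (or CYK) matrix for one sequence. When init=true all
// cells start at -inf (required whenever bands leave cells uncomputed).
// T is the cell storage type: double for exact work and traceback,
// float for the bandwidth-bound scanning path. Returns cells evaluated.
template <class OP, class T>
static long long cm_fill_t(const CMView& cm, const int* x, int L,
                           const int* ilo, const int* ihi, const int* jlo,
                           const int* jhi, std::vector<T>& alpha,
                           bool init) {
  const size_t plane = TRI(L + 1);
  if (alpha.size() < (size_t)cm.ns * plane)
    alpha.resize((size_t)cm.ns * plane);
  if (init) std::fill(alpha.begin(), alpha.begin() + (size_t)cm.ns * plane,
                      (T)NEGINF);
  long long cells = 0;
  std::vector<T> acc(L + 1);
  std::vector<T> ev(L + 1);  // per-state emission row (gathers hoisted)

  for (int v = cm.ns - 1; v >= 0; --v) {
    const int ty = cm.stype[v];
    T* av = &alpha[(size_t)v * plane];
    const int jl = std::max(0, jlo[v]), jh = std::min(L, jhi[v]);
    if (ty == ST_E) {
      for (int j = jl; j <= jh; ++j) {
        if (!init)  // cells d >= 1 may be read by parents; keep them -inf
          for (int d = 1; d <= j; ++d) av[TRI(j) + d] = (T)NEGINF;
        if (ilo[v] <= j + 1 && j + 1 <= ihi[v]) {
          av[TRI(j)] = 0.0;
          ++cells;
        } else if (!init) {
          av[TRI(j)] = (T)NEGINF;
        }
      }
      continue;
    }
    if (ty == ST_B) {
      // split loop arranged k-outer so the d sweep is contiguous in both
      // children; right-child cells at -inf skip their whole row
      const int l = cm.child[cm.child_off[v]];
      const int r = cm.child[cm.child_off[v] + 1];
      const T* al = &alpha[(size_t)l * plane];
      const T* ar = &alpha[(size_t)r * plane];
      for (int j = jl; j <= jh; ++j) {
        int dlo = std::max(0, j - ihi[v] + 1);
        int dhi = std::min(j, j - ilo[v] + 1);
        if (dhi < dlo) continue;
        T* avj = av + TRI(j);
        for (int d = dlo; d <= dhi; ++d) avj[d] = (T)NEGINF;
        const T* arj = ar + TRI(j);
        for (int k = 0; k <= dhi; ++k) {
          double t = (double)arj[k];
          if (t <= NEGHALF) continue;
          const T* alr = al + TRI(j - k) - k;  // left-child row, d-indexed
          accum_row<OP, T>(avj, alr, t, std::max(dlo, k), dhi);
        }
        cells += dhi - dlo + 1;
      }
      continue;
    }
    // emitting / S / D states
    const int co = cm.child_off[v], ce = cm.child_off[v + 1];
    const int demit = (ty == ST_MP) ? 2
                      : (ty == ST_S || ty == ST_D) ? 0 : 1;
    const bool lemit = (ty == ST_ML || ty == ST_IL || ty == ST_MP);
    const bool remit = (ty == ST_MR || ty == ST_IR || ty == ST_MP);
    const bool cons = (ty == ST_MP || ty == ST_ML || ty == ST_MR);
    if (lemit && ty != ST_MP) {  // e1 row reused across j (reversed in d)
      for (int i = 1; i <= L; ++i) ev[i] = e1<T>(cm, v, x[i - 1]);
    }
    // an IL state's self-loop reads its own row j at d-1
    bool self_loop = false;
    for (int c = co; c < ce; ++c)
      if (cm.child[c] == v && !remit) self_loop = true;
    for (int j = jl; j <= jh; ++j) {
      int dlo = std::max(demit, j - ihi[v] + 1);
      int dhi = std::min(j, j - ilo[v] + 1);
      if (!init)  // keep sub-demit cells -inf for parents to read
        for (int d = 0; d < demit && d <= j; ++d)
          av[TRI(j) + d] = (T)NEGINF;
      if (dhi < dlo) continue;
      const int jc = remit ? j - 1 : j;
      const double endterm = (cm.local && cons) ? cm.end_sc : NEGINF;
      if (self_loop) {
        // IL self-loop: vector-accumulate the other children, then fold
        // the self term in one scalar d-ascending pass (its reference to
        // row j at d-1 is this state's own just-written cell)
        T* accp = acc.data();
        for (int d = dlo; d <= dhi; ++d) accp[d] = (T)endterm;
        T tself = 0;
        for (int c = co; c < ce; ++c) {
          if (cm.child[c] == v) { tself = (T)cm.tsc[c]; continue; }
          const T* ay = &alpha[(size_t)cm.child[c] * plane + TRI(jc)] -
                        demit;
          accum_row<OP, T>(accp, ay, cm.tsc[c], dlo, dhi);
        }
        T* avj = av + TRI(j);
        for (int d = dlo; d <= dhi; ++d) {
          T a = OP::comb(accp[d], (T)(tself + avj[d - 1]));
          avj[d] = (T)(ev[j - d + 1] + a);
        }
        cells += dhi - dlo + 1;
        continue;
      }
      T* accp = acc.data();
      for (int d = dlo; d <= dhi; ++d) accp[d] = (T)endterm;
      for (int c = co; c < ce; ++c) {
        const T* ay = &alpha[(size_t)cm.child[c] * plane + TRI(jc)] - demit;
        accum_row<OP, T>(accp, ay, cm.tsc[c], dlo, dhi);
      }
      T* avj = av + TRI(j);
      if (ty == ST_MP) {
        const int xj = x[j - 1];
        for (int d = dlo; d <= dhi; ++d) {
          int i = j - d + 1;
          avj[d] = (T)(e2<T>(cm, v, x[i - 1], xj) + accp[d]);
        }
      } else if (lemit) {
        const T* evp = ev.data();
        for (int d = dlo; d <= dhi; ++d)
          avj[d] = (T)(evp[j - d + 1] + accp[d]);
      } else if (remit) {
        const T ej = e1<T>(cm, v, x[j - 1]);
        for (int d = dlo; d <= dhi; ++d)
          avj[d] = (T)(ej + accp[d]);
      } else {
        for (int d = dlo; d <= dhi; ++d) avj[d] = accp[d];
      }
      cells += dhi - dlo + 1;
    }
    // local begins fold extra start candidates into the root state
    if (v == 0 && cm.local && cm.nbegin > 0) {
      for (int b = 0; b < cm.nbegin; ++b) {
        const T* ab = &alpha[(size_t)cm.bstate[b] * plane];
        for (int j = jl; j <= jh; ++j) {
          int dlo = std::max(0, j - ihi[v] + 1);
          int dhi = std::min(j, j - ilo[v] + 1);
          if (dhi < dlo) continue;
          accum_row<OP, T>(av + TRI(j), ab + TRI(j), cm.begin_sc, dlo,
                           dhi);
        }
      }
    }
  }
  return cells;
}

#endif  // COVMOD_CM_KERNEL_H
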