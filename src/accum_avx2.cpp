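// AVX2+FMA instantiation of the float CM fill (see cm_kernel.h). This
// translation unit is compiled with -mavx2 -mfma (Makevars rule); the
// entry points in kernels.cpp dispatch here when the cpu supports it.

#if defined(__x86_64__) || defined(_M_X64)
#define COVMOD_AVX2_TU 1
#endif

#include "cm_kernel.h"

long long covmod_fill_fast_float_avx2(const CMView& cm, const int* x,
                                      int L, const int* ilo,
                                      const int* ihi, const int* jlo,
                                      const int* jhi,
                                      std::vector<float>& alpha,
                                      bool init) {
  return cm_fill_t<OpFast, float>(cm, x, L, ilo, ihi, jlo, jhi, alpha,
                                  init);
}

long long covmod_fill_max_float_avx2(const CMView& cm, const int* x,
                                     int L, const int* ilo, const int* ihi,
                                     const int* jlo, const int* jhi,
                                     std::vector<float>& alpha,
                                     bool init) {
  return cm_fill_t<OpMax, float>(cm, x, L, ilo, ihi, jlo, jhi, alpha,
                                 init);
}
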