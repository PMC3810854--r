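PKG_CXXFLAGS = -O3 -funroll-loops

all: $(SHLIB)

# accum_avx2.cpp holds only the AVX2/FMA build of the hot accumulate op;
# callers dispatch on cpu features at run time (SSE2 fallback elsewhere)
accum_avx2.o: accum_avx2.cpp
	$(CXX) $(ALL_CPPFLAGS) $(ALL_CXXFLAGS) -mavx2 -mfma -c accum_avx2.cpp -o accum_avx2.o
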