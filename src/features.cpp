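// Structural feature kernels.
//
// Sequences arrive as integer codes: A=1, C=2, G=3, U=4, N(or other)=0.
// `adm` is a 4x4 0/1 admissibility matrix over coded bases; code 0 never
// pairs.  The minimum hairpin loop h means (i,j) can pair only when
// j - i > h (0-based positions).

#include <Rcpp.h>
using namespace Rcpp;

static inline bool adm_ok(const IntegerMatrix& adm, int a, int b) {
  if (a == 0 || b == 0) return false;
  return adm(a - 1, b - 1) != 0;
}

// Nussinov maximum-matching DP: entry (i,j) is the maximum number of
// non-crossing admissible pairs formable inside fragment [i..j].
// [[Rcpp::export(rng = false)]]
NumericMatrix lpss_cpp(IntegerVector codes, IntegerMatrix adm, int h) {
  const int L = codes.size();
  NumericMatrix out(L, L);
  if (L < 2) return out;
  // dp over increasing fragment length
  std::vector<int> dp((size_t)L * L, 0);
  for (int len = 2; len <= L; ++len) {
    for (int i = 0; i + len - 1 < L; ++i) {
      int j = i + len - 1;
      int best = dp[(size_t)(i + 1) * L + j];            // i unpaired
      // i paired with some k in (i, j]
      for (int k = i + h + 1; k <= j; ++k) {
        if (!adm_ok(adm, codes[i], codes[k])) continue;
        int left  = (k - i > 1) ? dp[(size_t)(i + 1) * L + (k - 1)] : 0;
        int right = (k < j)     ? dp[(size_t)(k + 1) * L + j]       : 0;
        int cand = 1 + left + right;
        if (cand > best) best = cand;
      }
      dp[(size_t)i * L + j] = best;
    }
  }
  for (int i = 0; i < L; ++i)
    for (int j = i + 1; j < L; ++j) {
      out(i, j) = dp[(size_t)i * L + j];
      out(j, i) = out(i, j);
    }
  return out;
}

// Interval partner-count maps.  For each interval [i..j] and each base
// channel (A,U,C,G order), count positions p in [i..j] of that base whose
// number of admissible partners inside [i..j] reaches `threshold`.
// Used with threshold 2 for the pairing-ambiguity (SRS) maps and
// threshold 1 (with an A-U-only admissibility matrix) for the BMS maps.
// Returns an L x L x 4 array.
// [[Rcpp::export(rng = false)]]
NumericVector partner_count_maps_cpp(IntegerVector codes, IntegerMatrix adm,
                                     int h, int threshold) {
  const int L = codes.size();
  NumericVector out(Dimension(L, L, 4));
  // channel index by coded base: A->0, U->1, C->2, G->3
  auto chan_of = [](int code) {
    switch (code) { case 1: return 0; case 4: return 1;
                    case 2: return 2; case 3: return 3; }
    return -1;
  };
  std::vector<int> cnt(L);
  for (int i = 0; i < L; ++i) {
    std::fill(cnt.begin() + i, cnt.end(), 0);
    int tally[4] = {0, 0, 0, 0};
    for (int j = i; j < L; ++j) {
      // position j enters the interval: update pair counts against [i..j-1]
      for (int q = i; q < j; ++q) {
        if (j - q <= h) break;  // closer q only get closer; stop early
        if (!adm_ok(adm, codes[q], codes[j])) continue;
        if (++cnt[q] == threshold) { int c = chan_of(codes[q]); if (c >= 0) tally[c]++; }
        if (++cnt[j] == threshold) { int c = chan_of(codes[j]); if (c >= 0) tally[c]++; }
      }
      if (j > i) {
        for (int c = 0; c < 4; ++c) {
          out[(size_t)c * L * L + (size_t)j * L + i] = tally[c];
          out[(size_t)c * L * L + (size_t)i * L + j] = tally[c];
        }
      }
    }
  }
  return out;
}

// Gaussian-decayed stacking propensity matrix (CDPfold-style).  For an
// admissible (i,j): sum exp(-t^2/(2 sigma^2)) * w(i-t, j+t) outward from
// t = 0 while positions stay in range and admissible, plus the same
// accumulation inward over (i+t, j-t) for t >= 1; stop each direction at
// the first failure.
// [[Rcpp::export(rng = false)]]
NumericMatrix rcm_cpp(IntegerVector codes, IntegerMatrix adm, int h,
                      NumericMatrix w, double sigma) {
  const int L = codes.size();
  NumericMatrix out(L, L);
  const double s2 = 2.0 * sigma * sigma;
  for (int i = 0; i < L; ++i) {
    for (int j = i + h + 1; j < L; ++j) {
      if (!adm_ok(adm, codes[i], codes[j])) continue;
      double acc = 0.0;
      for (int t = 0;; ++t) {
        int a = i - t, b = j + t;
        if (a < 0 || b >= L || !adm_ok(adm, codes[a], codes[b]) || b - a <= h) break;
        acc += std::exp(-(double)t * t / s2) * w(codes[a] - 1, codes[b] - 1);
      }
      for (int t = 1;; ++t) {
        int a = i + t, b = j - t;
        if (a >= b || !adm_ok(adm, codes[a], codes[b]) || b - a <= h) break;
        acc += std::exp(-(double)t * t / s2) * w(codes[a] - 1, codes[b] - 1);
      }
      out(i, j) = acc;
      out(j, i) = acc;
    }
  }
  return out;
}
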