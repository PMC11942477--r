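// Batched scaled-dot-product attention over equal-sized blocks.
//
// Q is (B*nq) x C, K and V are (B*nk) x C, rows grouped block-major
// (block b owns rows [b*nq, (b+1)*nq)).  C = heads * dk; head t owns the
// column range [t*dk, (t+1)*dk).  Every (block, head) pair attends
// independently: softmax(Q K' / sqrt(dk) + mask) V.  `mask` is an
// nq x nk x nmask array of additive biases (0 or -1e9) and `mask_idx`
// selects one slice per block (empty = no mask); this carries the
// shifted-window cross-boundary masks of the vision encoder.
//
// The slices are small (a window times a handful of head dimensions), so
// the kernels are hand-rolled over contiguous per-slice buffers rather
// than delegated to BLAS.  The full weight cube is only materialised on
// request (attention diagnostics); the backward recomputes each slice's
// weights from Q and K, which is cheaper than storing them.

#include <Rcpp.h>
using namespace Rcpp;

// copy rows [r0, r0+n) and columns [c0, c0+dk) of the column-major N x C
// matrix src into dst as a dk x n column-major buffer (one token per column)
static inline void load_block(const double* src, int N, int r0, int c0,
                              int n, int dk, double* dst) {
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dk; ++d)
      dst[(size_t)i * dk + d] = src[(size_t)(c0 + d) * N + r0 + i];
}

static inline void store_block(double* dst, int N, int r0, int c0,
                               int n, int dk, const double* src) {
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dk; ++d)
      dst[(size_t)(c0 + d) * N + r0 + i] = src[(size_t)i * dk + d];
}

// [[Rcpp::export(rng = false)]]
List attn_fwd_cpp(NumericMatrix Q, NumericMatrix K, NumericMatrix V,
                  int nq, int nk, int heads,
                  NumericVector mask, IntegerVector mask_idx,
                  bool want_A = false) {
  const int C = Q.ncol();
  const int Nq = Q.nrow(), Nk = K.nrow();
  const int B = Nq / nq;
  const int dk = C / heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  const bool has_mask = mask.size() > 0 && mask_idx.size() == B;

  NumericMatrix O(Nq, C);
  // the weights are only materialised when the caller wants diagnostics;
  // the backward pass recomputes them slice by slice instead
  NumericVector A(want_A ? Dimension(nq, nk, B * heads) : Dimension(0, 0, 0));
  double* pA = A.begin();
  const double* pQ = Q.begin();
  const double* pK = K.begin();
  const double* pV = V.begin();
  const double* pM = mask.begin();
  double* pO = O.begin();

  std::vector<double> qb((size_t)nq * dk), kb((size_t)nk * dk),
      vb((size_t)nk * dk), ob((size_t)nq * dk), S((size_t)nq * nk);

  for (int b = 0; b < B; ++b) {
    const int q0 = b * nq, k0 = b * nk;
    const double* msl = has_mask ?
      pM + (size_t)(mask_idx[b] - 1) * nq * nk : nullptr;
    for (int t = 0; t < heads; ++t) {
      const int c0 = t * dk;
      load_block(pQ, Nq, q0, c0, nq, dk, qb.data());
      load_block(pK, Nk, k0, c0, nk, dk, kb.data());
      load_block(pV, Nk, k0, c0, nk, dk, vb.data());
      for (int i = 0; i < nq; ++i) {
        double* Si = S.data() + (size_t)i * nk;
        const double* qi = qb.data() + (size_t)i * dk;
        double mx = -1e300;
        for (int j = 0; j < nk; ++j) {
          const double* kj = kb.data() + (size_t)j * dk;
          double acc = 0.0;
          for (int d = 0; d < dk; ++d) acc += qi[d] * kj[d];
          acc *= scale;
          if (msl) acc += msl[(size_t)j * nq + i];   // mask is nq x nk col-major
          Si[j] = acc;
          if (acc > mx) mx = acc;
        }
        double z = 0.0;
        for (int j = 0; j < nk; ++j) { Si[j] = std::exp(Si[j] - mx); z += Si[j]; }
        double* oi = ob.data() + (size_t)i * dk;
        for (int d = 0; d < dk; ++d) oi[d] = 0.0;
        for (int j = 0; j < nk; ++j) {
          Si[j] /= z;
          const double w = Si[j];
          const double* vj = vb.data() + (size_t)j * dk;
          for (int d = 0; d < dk; ++d) oi[d] += w * vj[d];
        }
      }
      store_block(pO, Nq, q0, c0, nq, dk, ob.data());
      if (want_A) {
        // S is row-per-query in the buffer; the slice is column-major
        double* asl = pA + (size_t)(b * heads + t) * nq * nk;
        for (int i = 0; i < nq; ++i)
          for (int j = 0; j < nk; ++j)
            asl[(size_t)j * nq + i] = S[(size_t)i * nk + j];
      }
    }
  }
  return List::create(_["O"] = O, _["A"] = A);
}

// [[Rcpp::export(rng = false)]]
List attn_bwd_cpp(NumericMatrix Q, NumericMatrix K, NumericMatrix V,
                  NumericMatrix dO, int nq, int nk, int heads,
                  NumericVector mask, IntegerVector mask_idx) {
  const int C = Q.ncol();
  const int Nq = Q.nrow(), Nk = K.nrow();
  const int B = Nq / nq;
  const int dk = C / heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  const bool has_mask = mask.size() > 0 && mask_idx.size() == B;
  const double* pM = mask.begin();

  NumericMatrix dQ(Nq, C), dK(Nk, C), dV(Nk, C);

  std::vector<double> qb((size_t)nq * dk), kb((size_t)nk * dk),
      vb((size_t)nk * dk), dob((size_t)nq * dk), dqb((size_t)nq * dk),
      dkb((size_t)nk * dk), dvb((size_t)nk * dk), dS((size_t)nq * nk),
      Ar((size_t)nq * nk);

  for (int b = 0; b < B; ++b) {
    const int q0 = b * nq, k0 = b * nk;
    const double* msl = has_mask ?
      pM + (size_t)(mask_idx[b] - 1) * nq * nk : nullptr;
    for (int t = 0; t < heads; ++t) {
      const int c0 = t * dk;
      load_block(Q.begin(), Nq, q0, c0, nq, dk, qb.data());
      load_block(K.begin(), Nk, k0, c0, nk, dk, kb.data());
      load_block(V.begin(), Nk, k0, c0, nk, dk, vb.data());
      load_block(dO.begin(), Nq, q0, c0, nq, dk, dob.data());
      std::fill(dkb.begin(), dkb.end(), 0.0);
      std::fill(dvb.begin(), dvb.end(), 0.0);
      // recompute the attention weights for this slice
      for (int i = 0; i < nq; ++i) {
        double* Ai = Ar.data() + (size_t)i * nk;
        const double* qi = qb.data() + (size_t)i * dk;
        double mx = -1e300;
        for (int j = 0; j < nk; ++j) {
          const double* kj = kb.data() + (size_t)j * dk;
          double acc = 0.0;
          for (int d = 0; d < dk; ++d) acc += qi[d] * kj[d];
          acc *= scale;
          if (msl) acc += msl[(size_t)j * nq + i];
          Ai[j] = acc;
          if (acc > mx) mx = acc;
        }
        double z = 0.0;
        for (int j = 0; j < nk; ++j) { Ai[j] = std::exp(Ai[j] - mx); z += Ai[j]; }
        for (int j = 0; j < nk; ++j) Ai[j] /= z;
      }
      for (int i = 0; i < nq; ++i) {
        const double* doi = dob.data() + (size_t)i * dk;
        double* dSi = dS.data() + (size_t)i * nk;
        const double* Ai = Ar.data() + (size_t)i * nk;
        double dot = 0.0;
        for (int j = 0; j < nk; ++j) {
          const double a = Ai[j];
          const double* vj = vb.data() + (size_t)j * dk;
          double da = 0.0;
          for (int d = 0; d < dk; ++d) {
            da += doi[d] * vj[d];
            dvb[(size_t)j * dk + d] += a * doi[d];
          }
          dSi[j] = da;
          dot += da * a;
        }
        double* dqi = dqb.data() + (size_t)i * dk;
        for (int d = 0; d < dk; ++d) dqi[d] = 0.0;
        for (int j = 0; j < nk; ++j) {
          const double a = Ai[j];
          const double ds = a * (dSi[j] - dot) * scale;
          const double* kj = kb.data() + (size_t)j * dk;
          const double* qi = qb.data() + (size_t)i * dk;
          double* dkj = dkb.data() + (size_t)j * dk;
          for (int d = 0; d < dk; ++d) {
            dqi[d] += ds * kj[d];
            dkj[d] += ds * qi[d];
          }
        }
      }
      store_block(dQ.begin(), Nq, q0, c0, nq, dk, dqb.data());
      store_block(dK.begin(), Nk, k0, c0, nk, dk, dkb.data());
      store_block(dV.begin(), Nk, k0, c0, nk, dk, dvb.data());
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
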