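#include <Rcpp.h>
using namespace Rcpp;

// Max-pool over annotation slots with argmax tracking.
// I: n x t0 integer matrix of term indices (0 = padding, trailing only).
// E: V x d embedding matrix (row i = vector of term index i).
// Returns P (n x d pooled values) and A (n x d winning slot, 1-based).
// Padding slots hold pad_value and never win while a real slot exists;
// ties keep the earliest slot.
// [[Rcpp::export(name = ".pool_max_cpp")]]
List pool_max_cpp(IntegerMatrix I, NumericMatrix E, double pad_value) {
  const int n = I.nrow(), t0 = I.ncol(), d = E.ncol(), V = E.nrow();
  NumericMatrix P(n, d);
  IntegerMatrix A(n, d);
  for (int i = 0; i < n; ++i) {
    if (I(i, 0) == 0)
      stop("A gene with no real annotations reached the network.");
  }
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) {
      double best = pad_value;
      int slot = 1;
      for (int l = 0; l < t0; ++l) {
        int idx = I(i, l);
        if (idx == 0) break; // padding is trailing by contract
        if (idx < 1 || idx > V) stop("Annotation index outside the lookup table.");
        double v = E(idx - 1, j);
        if (v > best) { best = v; slot = l + 1; }
      }
      P(i, j) = best;
      A(i, j) = slot;
    }
  }
  return List::create(Named("P") = P, Named("A") = A);
}

// Scatter-add pooled gradients back into the embedding table.
// I: n x t0 indices; A: n x d winning slots from pool_max_cpp;
// G: n x d gradient wrt the pooled values. Returns V x d dense gradient.
// [[Rcpp::export(name = ".emb_scatter_cpp")]]
NumericMatrix emb_scatter_cpp(IntegerMatrix I, IntegerMatrix A, NumericMatrix G,
                              int V) {
  const int n = I.nrow(), d = A.ncol();
  NumericMatrix out(V, d);
  for (int j = 0; j < d; ++j) {
    for (int i = 0; i < n; ++i) {
      int idx = I(i, A(i, j) - 1);
      if (idx > 0) out(idx - 1, j) += G(i, j);
    }
  }
  return out;
}
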