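#include <Rcpp.h>
using namespace Rcpp;

// For each taxon i and sample k, the minimum patristic distance from i to
// any taxon present in sample k (0 when i itself is present in k). D may be
// passed with permuted taxon indexing to realise the tip-shuffle null.
// [[Rcpp::export]]
NumericMatrix min_dist_to_sample(NumericMatrix D, LogicalMatrix P) {
  const int nt = D.nrow(), ns = P.ncol();
  if (P.nrow() != nt) stop("dimension mismatch between D and P");
  NumericMatrix M(nt, ns);
  for (int k = 0; k < ns; ++k) {
    double *mk = &M(0, k);
    for (int i = 0; i < nt; ++i) mk[i] = R_PosInf;
    bool any = false;
    // sweep the distance matrix column-wise (cache friendly)
    for (int c = 0; c < nt; ++c) {
      if (!P(c, k)) continue;
      any = true;
      const double *dc = &D(0, c);
      for (int i = 0; i < nt; ++i)
        if (dc[i] < mk[i]) mk[i] = dc[i];
    }
    if (!any) stop("sample with no present taxa");
  }
  return M;
}
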