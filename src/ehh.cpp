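#include <Rcpp.h>
using namespace Rcpp;

// Extended haplotype homozygosity computed site-by-site outward from a core.
//
// haps: haplotype x site 0/1 matrix. core: 0-based site index. allele: 0/1
// conditions on carriers of that allele at the core (EHH(0) = 1); allele = -1
// uses all haplotypes with the core site itself included in the identity
// span (EHH(0) = core-site homozygosity), the pooled curve used for
// cross-population iHH. direction: +1 right, -1 left. Stops at the
// chromosome end, when EHH reaches 0, when EHH drops below min_ehh (the
// crossing value is included), or after max_steps flanking sites (-1 =
// unlimited). Element 1 of the result is EHH at distance 0.
// [[Rcpp::export]]
NumericVector ehh_steps_cpp(const IntegerMatrix& haps, int core, int allele,
                            int direction, double min_ehh = 0.0,
                            int max_steps = -1) {
  const int n = haps.nrow(), m = haps.ncol();
  if (core < 0 || core >= m) stop("core index out of range");
  std::vector<int> idx;
  idx.reserve(n);
  std::vector<int> bnd;
  bnd.push_back(0);
  if (allele < 0) {
    // pooled: partition by core allele, identity includes the core site
    for (int i = 0; i < n; ++i) if (haps(i, core) == 0) idx.push_back(i);
    const int z = (int)idx.size();
    for (int i = 0; i < n; ++i) if (haps(i, core) != 0) idx.push_back(i);
    if (z > 0 && z < n) bnd.push_back(z);
    bnd.push_back(n);
  } else {
    for (int i = 0; i < n; ++i) if (haps(i, core) == allele) idx.push_back(i);
    bnd.push_back((int)idx.size());
  }
  const int c = (int)idx.size();
  if (c < 2) return NumericVector(0);
  const double tot = 0.5 * (double)c * (c - 1);

  std::vector<double> out;
  double h0 = 0.0;
  for (size_t g = 0; g + 1 < bnd.size(); ++g) {
    double sz = bnd[g + 1] - bnd[g];
    h0 += 0.5 * sz * (sz - 1);
  }
  h0 /= tot;
  out.push_back(h0);

  // drop singleton groups as they form: they can never contribute a pair,
  // so only haplotypes still in groups of size >= 2 need scanning
  {
    std::vector<int> fidx, fbnd;
    fbnd.push_back(0);
    for (size_t g = 0; g + 1 < bnd.size(); ++g) {
      if (bnd[g + 1] - bnd[g] >= 2) {
        for (int t = bnd[g]; t < bnd[g + 1]; ++t) fidx.push_back(idx[t]);
        fbnd.push_back((int)fidx.size());
      }
    }
    idx.swap(fidx);
    bnd.swap(fbnd);
  }

  std::vector<int> buf, nb;
  buf.reserve(c);
  int steps = 0;
  if (h0 > 0.0 && h0 >= min_ehh && idx.size() >= 2) {
    for (int site = core + direction; site >= 0 && site < m;
         site += direction) {
      if (max_steps >= 0 && steps >= max_steps) break;
      const int* col = &haps(0, site);
      nb.clear();
      nb.push_back(0);
      buf.clear();
      double hom = 0.0;
      for (size_t g = 0; g + 1 < bnd.size(); ++g) {
        const int a = bnd[g], b = bnd[g + 1];
        int z = 0, o = 0;
        for (int t = a; t < b; ++t) z += (col[idx[t]] == 0);
        o = b - a - z;
        if (z >= 2) {
          for (int t = a; t < b; ++t)
            if (col[idx[t]] == 0) buf.push_back(idx[t]);
          nb.push_back((int)buf.size());
          hom += 0.5 * (double)z * (z - 1);
        }
        if (o >= 2) {
          for (int t = a; t < b; ++t)
            if (col[idx[t]] != 0) buf.push_back(idx[t]);
          nb.push_back((int)buf.size());
          hom += 0.5 * (double)o * (o - 1);
        }
      }
      idx.swap(buf);
      bnd.swap(nb);
      const double e = hom / tot;
      out.push_back(e);
      ++steps;
      if (e <= 0.0 || e < min_ehh || idx.size() < 2) break;
    }
  }
  return NumericVector(out.begin(), out.end());
}
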