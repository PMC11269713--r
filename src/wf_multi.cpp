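#include <Rcpp.h>
using namespace Rcpp;

// Multi-population Wright-Fisher evolution on a shared site list, with
// joint pruning (sites lost in all populations or fixed in all
// populations are dropped every prune_every generations; a designated
// sweep site is always kept and its index is tracked through pruning).
// Selection acts multiplicatively, (1+s_pop) per derived copy at
// sweep_site, with a per-population coefficient. Uses R's RNG.

static inline int pick_parent(const std::vector<double>& cumw) {
  const double u = unif_rand() * cumw.back();
  return (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

typedef std::vector<std::vector<unsigned char> > PopHaps;

static void meiosis2(const PopHaps& pool, int parent,
                     const std::vector<double>& pos, double rho, double L,
                     std::vector<unsigned char>& child) {
  const std::vector<unsigned char>& a = pool[2 * parent];
  const std::vector<unsigned char>& b = pool[2 * parent + 1];
  const int m = (int)pos.size();
  child.resize(m);
  const int k = (int)R::rpois(rho * L);
  const bool start_a = unif_rand() < 0.5;
  if (k == 0) {
    const std::vector<unsigned char>& src = start_a ? a : b;
    std::copy(src.begin(), src.end(), child.begin());
    return;
  }
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  for (int j = 0; j < m; ++j) {
    const int cross =
        (int)(std::upper_bound(bp.begin(), bp.end(), pos[j]) - bp.begin());
    const bool from_a = ((cross % 2) == 0) == start_a;
    child[j] = from_a ? a[j] : b[j];
  }
}

// [[Rcpp::export]]
List wf_multi_cpp(const List& haps_list, const NumericVector& pos, int gens,
                  double mu, double rho, double L, const NumericVector& s,
                  int sweep_site, int prune_every = 5) {
  const int P = haps_list.size();
  if ((int)s.size() != P) stop("s must have one entry per population");
  std::vector<PopHaps> cur(P), nxt(P);
  std::vector<int> H(P), N(P);
  size_t m = pos.size();
  for (int p = 0; p < P; ++p) {
    IntegerMatrix hm = haps_list[p];
    if ((size_t)hm.ncol() != m) stop("site-count mismatch across populations");
    H[p] = hm.nrow();
    if (H[p] % 2 != 0) stop("haplotype count must be even");
    N[p] = H[p] / 2;
    cur[p].resize(H[p]);
    nxt[p].resize(H[p]);
    for (int i = 0; i < H[p]; ++i) {
      cur[p][i].resize(m);
      for (size_t j = 0; j < m; ++j) cur[p][i][j] = (unsigned char)hm(i, j);
      nxt[p][i].reserve(m + 256);
    }
  }
  std::vector<double> ps(pos.begin(), pos.end());
  int ss = sweep_site;

  for (int g = 0; g < gens; ++g) {
    for (int p = 0; p < P; ++p) {
      std::vector<double> cumw(N[p]);
      if (s[p] != 0.0 && ss >= 0 && ss < (int)ps.size()) {
        double acc = 0.0;
        for (int i = 0; i < N[p]; ++i) {
          const int d = cur[p][2 * i][ss] + cur[p][2 * i + 1][ss];
          acc += std::pow(1.0 + s[p], (double)d);
          cumw[i] = acc;
        }
      } else {
        for (int i = 0; i < N[p]; ++i) cumw[i] = (double)(i + 1);
      }
      for (int i = 0; i < N[p]; ++i) {
        meiosis2(cur[p], pick_parent(cumw), ps, rho, L, nxt[p][2 * i]);
        meiosis2(cur[p], pick_parent(cumw), ps, rho, L, nxt[p][2 * i + 1]);
      }
      cur[p].swap(nxt[p]);
    }
    // mutations per population; each new site is a column in every
    // population, zero outside the mutated haplotype
    for (int p = 0; p < P; ++p) {
      const int nmut = (int)R::rpois(2.0 * N[p] * mu * L);
      if (nmut == 0) continue;
      const size_t oldm = ps.size();
      for (int q = 0; q < P; ++q)
        for (int i = 0; i < H[q]; ++i) cur[q][i].resize(oldm + nmut, 0);
      for (int t = 0; t < nmut; ++t) {
        ps.push_back(unif_rand() * L);
        const int hap = (int)(unif_rand() * H[p]);
        cur[p][hap][oldm + t] = 1;
      }
    }
    if (prune_every > 0 && (g + 1) % prune_every == 0) {
      const size_t mm = ps.size();
      int tot_h = 0;
      for (int p = 0; p < P; ++p) tot_h += H[p];
      std::vector<int> cnt(mm, 0);
      for (int p = 0; p < P; ++p)
        for (int i = 0; i < H[p]; ++i) {
          const std::vector<unsigned char>& row = cur[p][i];
          for (size_t j = 0; j < mm; ++j) cnt[j] += row[j];
        }
      std::vector<int> keep;
      keep.reserve(mm);
      int new_ss = -1;
      for (size_t j = 0; j < mm; ++j) {
        if ((cnt[j] > 0 && cnt[j] < tot_h) || (int)j == ss) {
          if ((int)j == ss) new_ss = (int)keep.size();
          keep.push_back((int)j);
        }
      }
      if (keep.size() < mm) {
        std::vector<double> np;
        np.reserve(keep.size());
        for (size_t k = 0; k < keep.size(); ++k) np.push_back(ps[keep[k]]);
        for (int p = 0; p < P; ++p)
          for (int i = 0; i < H[p]; ++i) {
            std::vector<unsigned char> row;
            row.reserve(keep.size() + 256);
            for (size_t k = 0; k < keep.size(); ++k)
              row.push_back(cur[p][i][keep[k]]);
            cur[p][i].swap(row);
          }
        ps.swap(np);
        ss = new_ss;
      }
    }
  }

  m = ps.size();
  List out_h(P);
  for (int p = 0; p < P; ++p) {
    IntegerMatrix hm(H[p], (int)m);
    for (int i = 0; i < H[p]; ++i)
      for (size_t j = 0; j < m; ++j) hm(i, j) = cur[p][i][j];
    out_h[p] = hm;
  }
  return List::create(_["haps"] = out_h,
                      _["pos"] = NumericVector(ps.begin(), ps.end()),
                      _["sweep_site"] = ss + 1);  // 1-based, 0 if none
}
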