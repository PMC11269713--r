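#include <Rcpp.h>
using namespace Rcpp;

// Discrete-generation Wright-Fisher evolution of one diploid population with
// recombination, infinite-sites-style mutation on a continuous [0, L) axis,
// and optional multiplicative selection (1+s per copy) on one site.
//
// haps: 2N x m 0/1 matrix (rows = haplotypes, consecutive pairs = diploids);
// pos: site coordinates (double bp, need not be sorted; new mutations are
// appended). sweep_site: 0-based column index under selection, -1 for none.
// Uses R's RNG, so results are reproducible under set.seed(). Returns the
// evolved matrix and positions; no site pruning is done here (the R driver
// prunes jointly across populations).

static inline int sample_parent(const std::vector<double>& cumw) {
  const double u = unif_rand() * cumw.back();
  return (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

static void meiosis(const std::vector<std::vector<unsigned char> >& pool,
                    int parent, const std::vector<double>& pos, double rho,
                    double L, std::vector<unsigned char>& child) {
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

// prune_every > 0 drops sites lost or fixed in this population every that
// many generations -- only safe while no other population shares the site
// list (i.e. during the single-population burn-in).
// [[Rcpp::export]]
List wf_evolve_cpp(const IntegerMatrix& haps, const NumericVector& pos,
                   int gens, double mu, double rho, double L, double s,
                   int sweep_site, int prune_every = 0) {
  const int H = haps.nrow();
  if (H % 2 != 0) stop("haplotype count must be even");
  if (prune_every > 0 && sweep_site >= 0)
    stop("prune_every cannot be combined with a sweep site (indices shift)");
  const int N = H / 2;
  int m = haps.ncol();
  if ((int)pos.size() != m) stop("pos length != site count");

  std::vector<std::vector<unsigned char> > cur(H), nxt(H);
  for (int i = 0; i < H; ++i) {
    cur[i].resize(m);
    for (int j = 0; j < m; ++j) cur[i][j] = (unsigned char)haps(i, j);
    nxt[i].reserve(m + 64);
  }
  std::vector<double> p(pos.begin(), pos.end());
  std::vector<double> cumw(N);

  for (int g = 0; g < gens; ++g) {
    // parent sampling weights
    if (s != 0.0 && sweep_site >= 0 && sweep_site < (int)p.size()) {
      double acc = 0.0;
      for (int i = 0; i < N; ++i) {
        const int d = cur[2 * i][sweep_site] + cur[2 * i + 1][sweep_site];
        acc += std::pow(1.0 + s, (double)d);
        cumw[i] = acc;
      }
    } else {
      for (int i = 0; i < N; ++i) cumw[i] = (double)(i + 1);
    }
    for (int i = 0; i < N; ++i) {
      const int p1 = sample_parent(cumw);
      const int p2 = sample_parent(cumw);
      meiosis(cur, p1, p, rho, L, nxt[2 * i]);
      meiosis(cur, p2, p, rho, L, nxt[2 * i + 1]);
    }
    cur.swap(nxt);
    // new mutations: each creates a fresh site carried by one haplotype;
    // rows are extended once per generation, not once per mutation
    const int nmut = (int)R::rpois(2.0 * N * mu * L);
    if (nmut > 0) {
      const size_t oldm = p.size();
      for (int i = 0; i < H; ++i) cur[i].resize(oldm + nmut, 0);
      for (int t = 0; t < nmut; ++t) {
        const double newpos = unif_rand() * L;
        const int hap = (int)(unif_rand() * H);
        cur[hap][oldm + t] = 1;
        p.push_back(newpos);
      }
    }
    if (prune_every > 0 && (g + 1) % prune_every == 0) {
      const int mm = (int)p.size();
      std::vector<int> keep;
      keep.reserve(mm);
      for (int j = 0; j < mm; ++j) {
        int cnt = 0;
        for (int i = 0; i < H; ++i) cnt += cur[i][j];
        if (cnt > 0 && cnt < H) keep.push_back(j);
      }
      if ((int)keep.size() < mm) {
        std::vector<double> np;
        np.reserve(keep.size());
        for (size_t k = 0; k < keep.size(); ++k) np.push_back(p[keep[k]]);
        for (int i = 0; i < H; ++i) {
          std::vector<unsigned char> row;
          row.reserve(keep.size() + 64);
          for (size_t k = 0; k < keep.size(); ++k)
            row.push_back(cur[i][keep[k]]);
          cur[i].swap(row);
        }
        p.swap(np);
      }
    }
  }

  m = (int)p.size();
  IntegerMatrix out(H, m);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < m; ++j) out(i, j) = cur[i][j];
  return List::create(_["haps"] = out,
                      _["pos"] = NumericVector(p.begin(), p.end()));
}
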