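#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cmath>
#include <queue>
#include <set>
#include <vector>
using namespace Rcpp;

// reflect an out-of-range index back into [0, n-1] (mirror without repeat)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable convolution with a symmetric 1-D kernel, reflective boundaries.
// Applied along rows (depth) first, then columns (lateral).
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(NumericMatrix img, NumericVector kern) {
  const int H = img.nrow(), W = img.ncol();
  const int r = (kern.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int rr = 0; rr < H; ++rr) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t)
        s += kern[t + r] * img(reflect_idx(rr + t, H), c);
      tmp(rr, c) = s;
    }
  for (int rr = 0; rr < H; ++rr)
    for (int c = 0; c < W; ++c) {
      double s = 0.0;
      for (int t = -r; t <= r; ++t)
        s += kern[t + r] * tmp(rr, reflect_idx(c + t, W));
      out(rr, c) = s;
    }
  return out;
}

// w x w median filter on a double matrix, reflective boundaries (w odd).
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int w) {
  const int H = x.nrow(), W = x.ncol(), r = w / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf;
  buf.reserve((size_t)w * w);
  for (int c = 0; c < W; ++c)
    for (int rr = 0; rr < H; ++rr) {
      buf.clear();
      for (int dc = -r; dc <= r; ++dc)
        for (int dr = -r; dr <= r; ++dr)
          buf.push_back(x(reflect_idx(rr + dr, H), reflect_idx(c + dc, W)));
      const size_t mid = buf.size() / 2;  // w*w odd -> exact middle
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(rr, c) = buf[mid];
    }
  return out;
}

// Deterministic grayscale SLIC. Seeds on a regular ny x nx grid with
// ny*nx <= K, perturbed to the lowest-gradient spot in a 3x3 window;
// `iters` rounds of windowed assignment (D = sqrt(dI^2 + (dxy/S)^2 m^2),
// ties -> lowest center index) followed by mean updates. Labels 1..K'.
// [[Rcpp::export]]
IntegerMatrix cpp_slic(NumericMatrix img, int K, int iters, double m) {
  const int H = img.nrow(), W = img.ncol();
  const long N = (long)H * W;
  if (K < 1 || K > N) stop("n_superpixels must be in 1..(pixel count)");
  const double S = std::sqrt((double)N / K);

  int ny = std::max(1, (int)std::floor(std::sqrt((double)K * H / W)));
  int nx = std::max(1, K / ny);
  const int nc = ny * nx;

  std::vector<double> cr(nc), cc(nc), ci(nc);
  {
    int idx = 0;
    for (int i = 0; i < ny; ++i)
      for (int j = 0; j < nx; ++j, ++idx) {
        int sr = (int)std::floor((i + 0.5) * H / ny);
        int sc = (int)std::floor((j + 0.5) * W / nx);
        if (sr >= H) sr = H - 1;
        if (sc >= W) sc = W - 1;
        // move to lowest gradient in 3x3; strict improvement keeps center on ties
        auto grad = [&](int a, int b) {
          double gx = img(a, reflect_idx(b + 1, W)) - img(a, reflect_idx(b - 1, W));
          double gy = img(reflect_idx(a + 1, H), b) - img(reflect_idx(a - 1, H), b);
          return std::fabs(gx) + std::fabs(gy);
        };
        double best = grad(sr, sc);
        int br = sr, bc = sc;
        for (int da = -1; da <= 1; ++da)
          for (int db = -1; db <= 1; ++db) {
            int a = sr + da, b = sc + db;
            if (a < 0 || a >= H || b < 0 || b >= W) continue;
            double g = grad(a, b);
            if (g < best) { best = g; br = a; bc = b; }
          }
        cr[idx] = br; cc[idx] = bc; ci[idx] = img(br, bc);
      }
  }

  std::vector<int> lab((size_t)N, -1);
  std::vector<double> dist((size_t)N);
  const double S2 = S * S, m2 = m * m;

  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(lab.begin(), lab.end(), -1);
    for (int k = 0; k < nc; ++k) {
      int rlo = std::max(0, (int)std::floor(cr[k] - S));
      int rhi = std::min(H - 1, (int)std::ceil(cr[k] + S));
      int clo = std::max(0, (int)std::floor(cc[k] - S));
      int chi = std::min(W - 1, (int)std::ceil(cc[k] + S));
      for (int c = clo; c <= chi; ++c)
        for (int rr = rlo; rr <= rhi; ++rr) {
          double dI = img(rr, c) - ci[k];
          double dr = rr - cr[k], dc = c - cc[k];
          double D = std::sqrt(dI * dI + (dr * dr + dc * dc) / S2 * m2);
          size_t p = (size_t)c * H + rr;
          if (D < dist[p]) { dist[p] = D; lab[p] = k; }
        }
    }
    // safety net: pixels outside every window get a full scan
    for (size_t p = 0; p < (size_t)N; ++p)
      if (lab[p] < 0) {
        int rr = (int)(p % H), c = (int)(p / H);
        double bd = R_PosInf; int bk = 0;
        for (int k = 0; k < nc; ++k) {
          double dI = img(rr, c) - ci[k];
          double dr = rr - cr[k], dc = c - cc[k];
          double D = std::sqrt(dI * dI + (dr * dr + dc * dc) / S2 * m2);
          if (D < bd) { bd = D; bk = k; }
        }
        lab[p] = bk;
      }
    // update centers as cluster means; empty clusters keep their center
    // (long double accumulation: matches R's summation precision so the
    // brute-force oracle reproduces the same centers bit for bit)
    std::vector<long double> sr(nc, 0), sc(nc, 0), si(nc, 0);
    std::vector<long> cnt(nc, 0);
    for (size_t p = 0; p < (size_t)N; ++p) {
      int k = lab[p];
      sr[k] += (double)(p % H);
      sc[k] += (double)(p / H);
      si[k] += img((int)(p % H), (int)(p / H));
      cnt[k]++;
    }
    for (int k = 0; k < nc; ++k)
      if (cnt[k] > 0) {
        cr[k] = (double)sr[k] / cnt[k];
        cc[k] = (double)sc[k] / cnt[k];
        ci[k] = (double)si[k] / cnt[k];
      }
  }

  // relabel surviving clusters to 1..K' preserving center order
  std::vector<int> remap(nc, 0);
  int next = 0;
  for (size_t p = 0; p < (size_t)N; ++p)
    if (remap[lab[p]] == 0) remap[lab[p]] = -1;
  for (int k = 0; k < nc; ++k)
    if (remap[k] == -1) remap[k] = ++next;

  IntegerMatrix out(H, W);
  for (size_t p = 0; p < (size_t)N; ++p)
    out[(R_xlen_t)p] = remap[lab[p]];
  return out;
}

// 4-connected component labelling of an integer label raster (components are
// maximal 4-connected sets of equal label). Component ids 1..C in order of
// first appearance under column-major scan.
// [[Rcpp::export]]
IntegerMatrix cpp_components(IntegerMatrix lab) {
  const int H = lab.nrow(), W = lab.ncol();
  const long N = (long)H * W;
  IntegerMatrix comp(H, W);
  std::fill(comp.begin(), comp.end(), 0);
  int next = 0;
  std::queue<long> q;
  for (long p0 = 0; p0 < N; ++p0) {
    if (comp[p0] != 0) continue;
    const int target = lab[p0];
    comp[p0] = ++next;
    q.push(p0);
    while (!q.empty()) {
      long p = q.front(); q.pop();
      int rr = (int)(p % H), c = (int)(p / H);
      const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
      for (int d = 0; d < 4; ++d) {
        int a = rr + dr[d], b = c + dc[d];
        if (a < 0 || a >= H || b < 0 || b >= W) continue;
        long pq = (long)b * H + a;
        if (comp[pq] == 0 && lab[pq] == target) {
          comp[pq] = next;
          q.push(pq);
        }
      }
    }
  }
  return comp;
}

struct DSU {
  std::vector<int> parent;
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

// Merge every 4-connected component smaller than min_size into its largest
// 4-adjacent neighbour (ties -> lowest component id), the merged region
// taking the neighbour's label; repeat until no undersized mergeable
// component remains, then renumber labels consecutively from 1 by
// ascending original label. Implemented over a component union-find so
// the cost is near-linear in the pixel count.
// [[Rcpp::export]]
IntegerMatrix cpp_enforce_connectivity(IntegerMatrix lab0, double min_size) {
  IntegerMatrix lab = clone(lab0);
  const int H = lab.nrow(), W = lab.ncol();
  const long N = (long)H * W;

  // split: every 4-connected component becomes its own region, so the
  // output invariant (one 4-connected region per label) holds regardless
  // of how fragmented the input labels were
  IntegerMatrix comp = cpp_components(lab);
  int C = 0;
  for (long p = 0; p < N; ++p) C = std::max(C, comp[p]);

  std::vector<long> size(C + 1, 0);
  for (long p = 0; p < N; ++p) size[comp[p]]++;

  // component adjacency (4-neighbour)
  std::vector<std::set<int> > adj(C + 1);
  for (long p = 0; p < N; ++p) {
    int rr = (int)(p % H), c = (int)(p / H);
    int k = comp[p];
    if (rr + 1 < H) {
      int nk = comp[p + 1];
      if (nk != k) { adj[k].insert(nk); adj[nk].insert(k); }
    }
    if (c + 1 < W) {
      int nk = comp[p + H];
      if (nk != k) { adj[k].insert(nk); adj[nk].insert(k); }
    }
  }

  DSU dsu;
  dsu.parent.resize(C + 1);
  for (int k = 0; k <= C; ++k) dsu.parent[k] = k;

  bool changed = true;
  while (changed) {
    changed = false;
    for (int k = 1; k <= C; ++k) {
      int r = dsu.find(k);
      if (r != k) continue;                  // only roots
      if (size[r] >= (long)min_size) continue;
      // largest adjacent merged component (ties -> lowest root id)
      int best = 0;
      long bestsize = -1;
      for (std::set<int>::iterator it = adj[r].begin(); it != adj[r].end(); ++it) {
        int rn = dsu.find(*it);
        if (rn == r) continue;
        if (size[rn] > bestsize || (size[rn] == bestsize && rn < best))
          { bestsize = size[rn]; best = rn; }
      }
      if (best == 0) continue;               // single component image
      // merge r into best: result keeps best's label
      dsu.parent[r] = best;
      size[best] += size[r];
      if (adj[r].size() > adj[best].size()) adj[r].swap(adj[best]);
      adj[best].insert(adj[r].begin(), adj[r].end());
      std::set<int>().swap(adj[r]);
      changed = true;
    }
  }

  // final label = merged component root, renumbered consecutively from 1
  // by ascending root id (scan order of first appearance)
  std::vector<int> remap(C + 1, 0);
  int next = 0;
  for (long p = 0; p < N; ++p) {
    int r = dsu.find(comp[p]);
    if (remap[r] == 0) remap[r] = ++next;
    lab[p] = remap[r];
  }
  return lab;
}
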