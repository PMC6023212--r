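#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// Label connected foreground components of a logical matrix.
// connectivity: 4 or 8. Labels are assigned in row-major order of each
// component's first pixel, starting at 1; background is 0.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  // first pass: column-major storage but we scan row-major so that label
  // order matches the documented "first pixel in row-major order" rule
  std::vector<int> tmp((size_t)nr * nc, -1);
  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      size_t idx = (size_t)r * nc + c;
      int lbl = -1;
      // neighbours already visited in row-major scan
      const int dr4[2] = {0, -1}, dc4[2] = {-1, 0};
      const int dr8[4] = {0, -1, -1, -1}, dc8[4] = {-1, -1, 0, 1};
      int nn = (connectivity == 8) ? 4 : 2;
      const int* dr = (connectivity == 8) ? dr8 : dr4;
      const int* dc = (connectivity == 8) ? dc8 : dc4;
      for (int k = 0; k < nn; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || cc < 0 || cc >= nc) continue;
        if (!mask(rr, cc)) continue;
        int nl = tmp[(size_t)rr * nc + cc];
        if (lbl < 0) lbl = nl; else uf_union(parent, lbl, nl);
      }
      if (lbl < 0) {
        lbl = next++;
        parent.push_back(lbl);
      }
      tmp[idx] = uf_find(parent, lbl);
    }
  }
  // second pass: resolve and renumber in row-major order of first pixel
  std::vector<int> newlab(parent.size(), 0);
  int out = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      size_t idx = (size_t)r * nc + c;
      if (tmp[idx] < 0) continue;
      int root = uf_find(parent, tmp[idx]);
      if (newlab[root] == 0) newlab[root] = ++out;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}

// Accumulate circular Hough votes. Edge pixel coordinates are 1-based
// (row, col); votes are cast on circles of every integer radius in
// [rmin, rmax] around each edge pixel. Returns the accumulator matrix.
// [[Rcpp::export(name = ".hough_vote")]]
NumericMatrix hough_vote(IntegerVector rows, IntegerVector cols,
                         int nr, int nc, int rmin, int rmax) {
  NumericMatrix acc(nr, nc);
  if (rmin < 1 || rmax < rmin) stop("invalid radius range");
  // precompute circle offsets per radius
  std::vector< std::vector<int> > dro(rmax - rmin + 1), dco(rmax - rmin + 1);
  for (int r = rmin; r <= rmax; ++r) {
    int n = (int)std::ceil(2.0 * M_PI * r);
    std::vector<int>& drr = dro[r - rmin];
    std::vector<int>& dcc = dco[r - rmin];
    drr.reserve(n); dcc.reserve(n);
    int lastdr = INT_MIN, lastdc = INT_MIN;
    for (int k = 0; k < n; ++k) {
      double a = 2.0 * M_PI * k / n;
      int dr = (int)std::lround(r * std::sin(a));
      int dc = (int)std::lround(r * std::cos(a));
      if (dr == lastdr && dc == lastdc) continue;  // skip immediate repeats
      drr.push_back(dr); dcc.push_back(dc);
      lastdr = dr; lastdc = dc;
    }
  }
  int ne = rows.size();
  for (int i = 0; i < ne; ++i) {
    int r0 = rows[i] - 1, c0 = cols[i] - 1;
    for (int r = rmin; r <= rmax; ++r) {
      const std::vector<int>& drr = dro[r - rmin];
      const std::vector<int>& dcc = dco[r - rmin];
      for (size_t k = 0; k < drr.size(); ++k) {
        int rr = r0 + drr[k], cc = c0 + dcc[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) acc(rr, cc) += 1.0;
      }
    }
  }
  return acc;
}

// Histogram of rounded distances from a point to edge pixels, for radius
// bins rmin..rmax (stage-2 radius estimation of the circular Hough).
// [[Rcpp::export(name = ".radial_hist")]]
IntegerVector radial_hist(IntegerVector rows, IntegerVector cols,
                          double cy, double cx, int rmin, int rmax) {
  IntegerVector h(rmax - rmin + 1);
  int ne = rows.size();
  for (int i = 0; i < ne; ++i) {
    double dy = rows[i] - cy, dx = cols[i] - cx;
    int d = (int)std::lround(std::sqrt(dy * dy + dx * dx));
    if (d >= rmin && d <= rmax) h[d - rmin] += 1;
  }
  return h;
}

// CRC-32 (ISO 3309, as used by PNG chunks) of a raw vector.
// [[Rcpp::export(name = ".crc32")]]
double crc32_raw(RawVector data, double init) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    have_table = true;
  }
  uint32_t c = ((uint32_t)init) ^ 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}

// Adler-32 checksum (zlib trailer).
// [[Rcpp::export(name = ".adler32")]]
double adler32_raw(RawVector data) {
  uint32_t a = 1, b = 0;
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    a = (a + data[i]) % 65521u;
    b = (b + a) % 65521u;
  }
  return (double)((b << 16) | a);
}
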