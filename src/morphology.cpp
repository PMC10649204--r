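#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// Binary image utilities for marker detection and lesion segmentation.
// Masks are logical matrices in R's column-major layout; connectivity is
// 4-neighbour throughout (keeps noise speckle fragmented).

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> qs;
  qs.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      qs.clear();
      qs.push_back(r + c * nr);
      lab(r, c) = next;
      while (!qs.empty()) {
        int idx = qs.back();
        qs.pop_back();
        int rr = idx % nr, cc = idx / nr;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            qs.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

static std::vector<std::pair<int,int>> disc_offsets(double radius) {
  std::vector<std::pair<int,int>> off;
  int ir = (int)std::floor(radius);
  for (int dr = -ir; dr <= ir; ++dr)
    for (int dc = -ir; dc <= ir; ++dc)
      if ((double)dr * dr + (double)dc * dc <= radius * radius)
        off.push_back(std::make_pair(dr, dc));
  return off;
}

// Dilation of a set by a disc equals the set plus discs stamped at its
// boundary pixels only, which is much cheaper for large radii.
// [[Rcpp::export(name = ".binary_dilate")]]
LogicalMatrix binary_dilate(const LogicalMatrix& mask, double radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<std::pair<int,int>> off = disc_offsets(radius);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      out(r, c) = true;
      bool boundary =
        r == 0 || r == nr - 1 || c == 0 || c == nc - 1 ||
        !mask(r - 1, c) || !mask(r + 1, c) ||
        !mask(r, c - 1) || !mask(r, c + 1);
      if (!boundary) continue;
      for (size_t k = 0; k < off.size(); ++k) {
        int r2 = r + off[k].first, c2 = c + off[k].second;
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) out(r2, c2) = true;
      }
    }
  return out;
}

// [[Rcpp::export(name = ".binary_erode")]]
LogicalMatrix binary_erode(const LogicalMatrix& mask, double radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<std::pair<int,int>> off = disc_offsets(radius);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      bool keep = true;
      for (size_t k = 0; k < off.size() && keep; ++k) {
        int r2 = r + off[k].first, c2 = c + off[k].second;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || !mask(r2, c2))
          keep = false;
      }
      out(r, c) = keep;
    }
  return out;
}

// Holes = background pixels not reachable from outside the mask's
// bounding box (padded by one), which bounds the flood fill to the
// component's neighbourhood.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  int r0 = nr, r1 = -1, c0 = nc, c1 = -1;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c)) {
        if (r < r0) r0 = r;
        if (r > r1) r1 = r;
        if (c < c0) c0 = c;
        if (c > c1) c1 = c;
      }
  LogicalMatrix out = clone(mask);
  if (r1 < 0) return out;
  r0 = std::max(0, r0 - 1); r1 = std::min(nr - 1, r1 + 1);
  c0 = std::max(0, c0 - 1); c1 = std::min(nc - 1, c1 + 1);
  const int bnr = r1 - r0 + 1, bnc = c1 - c0 + 1;
  std::vector<char> outside((size_t)bnr * bnc, 0);
  std::queue<int> q;
  auto seed = [&](int br, int bc) {
    if (!mask(r0 + br, c0 + bc) && !outside[br + (size_t)bc * bnr]) {
      outside[br + (size_t)bc * bnr] = 1;
      q.push(br + bc * bnr);
    }
  };
  for (int br = 0; br < bnr; ++br) { seed(br, 0); seed(br, bnc - 1); }
  for (int bc = 0; bc < bnc; ++bc) { seed(0, bc); seed(bnr - 1, bc); }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int br = idx % bnr, bc = idx / bnr;
    for (int k = 0; k < 4; ++k) {
      int r2 = br + dr[k], c2 = bc + dc[k];
      if (r2 < 0 || r2 >= bnr || c2 < 0 || c2 >= bnc) continue;
      if (!mask(r0 + r2, c0 + c2) && !outside[r2 + (size_t)c2 * bnr]) {
        outside[r2 + (size_t)c2 * bnr] = 1;
        q.push(r2 + c2 * bnr);
      }
    }
  }
  for (int bc = 0; bc < bnc; ++bc)
    for (int br = 0; br < bnr; ++br)
      if (!outside[br + (size_t)bc * bnr]) out(r0 + br, c0 + bc) = true;
  return out;
}

// CRC-32 (PNG chunk checksums) and Adler-32 (zlib trailer) for the
// in-package 16-bit PNG writer.
// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(const RawVector& data, double init) {
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
  uint32_t crc = (uint32_t)init ^ 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}

// [[Rcpp::export(name = ".adler32_raw")]]
double adler32_raw(const RawVector& data) {
  const uint32_t MOD = 65521u;
  uint32_t a = 1, b = 0;
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    a += data[i];
    if (a >= MOD) a -= MOD;
    b += a;
    if (b >= MOD) b -= MOD;
  }
  return (double)((b << 16) | a);
}
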