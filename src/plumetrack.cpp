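#include <Rcpp.h>
using namespace Rcpp;

// Label connected foreground components of a binary image.
// Returns an integer matrix: 0 = background, 1..k = component id.
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  const int ndir = (connectivity == 8) ? 8 : 4;
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < ndir; ++k) {
          const int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// CRC-32 (IEEE 802.3 polynomial) of a byte vector, returned as 4 bytes
// big-endian, as stored in PNG chunk trailers.
// [[Rcpp::export]]
RawVector crc32_raw(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1u) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  crc ^= 0xFFFFFFFFu;
  RawVector out(4);
  out[0] = (crc >> 24) & 0xFF;
  out[1] = (crc >> 16) & 0xFF;
  out[2] = (crc >> 8) & 0xFF;
  out[3] = crc & 0xFF;
  return out;
}

// Rasterize polygons onto a pixel grid (even-odd rule; pixels whose centre
// lies on a polygon edge count as inside).  Vertices are 0-based image
// coordinates, columns of `v`: x = column, y = row.
// [[Rcpp::export]]
LogicalMatrix polygon_raster(int nrow, int ncol, List polygons) {
  LogicalMatrix out(nrow, ncol);
  for (int p = 0; p < polygons.size(); ++p) {
    NumericMatrix v = polygons[p];
    const int nv = v.nrow();
    if (nv < 3) stop("polygon must have at least 3 vertices");
    for (int r = 0; r < nrow; ++r) {
      for (int c = 0; c < ncol; ++c) {
        if (out(r, c)) continue;
        const double px = c, py = r;
        bool inside = false, onedge = false;
        for (int i = 0, j = nv - 1; i < nv; j = i++) {
          const double xi = v(i, 0), yi = v(i, 1);
          const double xj = v(j, 0), yj = v(j, 1);
          const double cross = (px - xi) * (yj - yi) - (py - yi) * (xj - xi);
          if (std::fabs(cross) < 1e-9) {
            const double dot = (px - xi) * (xj - xi) + (py - yi) * (yj - yi);
            const double len2 =
                (xj - xi) * (xj - xi) + (yj - yi) * (yj - yi);
            if (dot >= -1e-9 && dot <= len2 + 1e-9) {
              onedge = true;
              break;
            }
          }
          if (((yi > py) != (yj > py)) &&
              (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
            inside = !inside;
        }
        if (inside || onedge) out(r, c) = true;
      }
    }
  }
  return out;
}
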