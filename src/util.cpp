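#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// CRC-32 (IEEE 802.3, as used by ZIP). Table built once per session.
static uint32_t crc_table[256];
static bool crc_table_ready = false;

static void build_crc_table() {
  for (uint32_t n = 0; n < 256; ++n) {
    uint32_t c = n;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
    crc_table[n] = c;
  }
  crc_table_ready = true;
}

// [[Rcpp::export]]
double crc32_raw(RawVector data, double init = 0) {
  if (!crc_table_ready) build_crc_table();
  uint32_t c = static_cast<uint32_t>(init) ^ 0xFFFFFFFFu;
  const R_xlen_t n = data.size();
  for (R_xlen_t i = 0; i < n; ++i)
    c = crc_table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return static_cast<double>(c ^ 0xFFFFFFFFu);
}

// Label connected components of positive voxels with 26-connectivity.
// mask: logical vector in column-major 3D order; dims: the array extents.
// Returns integer labels (0 = background), components numbered from 1 in
// scan order of their first-encountered voxel.
// [[Rcpp::export]]
IntegerVector label_components26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = static_cast<int>(v % nx);
      int j = static_cast<int>((v / nx) % ny);
      int k = static_cast<int>(v / (static_cast<R_xlen_t>(nx) * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            R_xlen_t w = ii + static_cast<R_xlen_t>(nx) * (jj + static_cast<R_xlen_t>(ny) * kk);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return labels;
}
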