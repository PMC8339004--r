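#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Flood-fill labelling of a 3D logical mask stored in R's column-major
// order. Labels are assigned by first encounter in linear scan order, so
// label 1 always starts at the smallest linear index of any component --
// the deterministic tie-break used by the table-removal ranking.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  IntegerVector labels(n, 0);
  labels.attr("dim") = dim;

  // neighbour offsets in (i,j,k) steps
  std::vector<int> oi, oj, ok;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int nz = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        oi.push_back(di); oj.push_back(dj); ok.push_back(dk);
      }
  const int nn = (int)oi.size();

  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i = (int)(cur % d1);
      int j = (int)((cur / d1) % d2);
      int k = (int)(cur / ((R_xlen_t)d1 * d2));
      for (int m = 0; m < nn; ++m) {
        int ii = i + oi[m], jj = j + oj[m], kk = k + ok[m];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3)
          continue;
        R_xlen_t idx = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = next_label;
          stack.push_back(idx);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// Sliding-window box sums over a 3D array (column-major). For every
// window start s the sum of arr over [s, s + w - 1] is returned; output
// dimensions are dim - w + 1. Used to find all positions at which a
// nodule bounding box fits entirely inside the lung mask.
// [[Rcpp::export(name = ".box_sum3")]]
NumericVector box_sum3_cpp(NumericVector arr, IntegerVector dim,
                           IntegerVector w) {
  if (dim.size() != 3 || w.size() != 3) stop("dim and w must have length 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int w1 = w[0], w2 = w[1], w3 = w[2];
  const int n1 = d1 - w1 + 1, n2 = d2 - w2 + 1, n3 = d3 - w3 + 1;
  if (n1 < 1 || n2 < 1 || n3 < 1) {
    NumericVector empty(0);
    empty.attr("dim") = IntegerVector::create(std::max(n1, 0),
                                              std::max(n2, 0),
                                              std::max(n3, 0));
    return empty;
  }
  const R_xlen_t e1 = d1 + 1, e2 = d2 + 1, e3 = d3 + 1;
  std::vector<double> P((size_t)e1 * e2 * e3, 0.0);
  auto PI = [&](R_xlen_t i, R_xlen_t j, R_xlen_t k) -> double& {
    return P[i + e1 * (j + e2 * k)];
  };
  for (int k = 1; k < e3; ++k)
    for (int j = 1; j < e2; ++j)
      for (int i = 1; i < e1; ++i)
        PI(i, j, k) = arr[(i - 1) + (R_xlen_t)d1 * ((j - 1) + (R_xlen_t)d2 * (k - 1))]
                      + PI(i - 1, j, k) + PI(i, j - 1, k) + PI(i, j, k - 1)
                      - PI(i - 1, j - 1, k) - PI(i - 1, j, k - 1)
                      - PI(i, j - 1, k - 1) + PI(i - 1, j - 1, k - 1);
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  out.attr("dim") = IntegerVector::create(n1, n2, n3);
  R_xlen_t pos = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++pos)
        out[pos] = PI(i + w1, j + w2, k + w3) - PI(i, j + w2, k + w3)
                 - PI(i + w1, j, k + w3) - PI(i + w1, j + w2, k)
                 + PI(i, j, k + w3) + PI(i, j + w2, k) + PI(i + w1, j, k)
                 - PI(i, j, k);
  return out;
}

// CRC-32 (ISO 3309 / PNG chunk checksum) over a raw vector.
// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
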