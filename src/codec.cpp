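// Compiled kernels: CBF byte-offset codec, integer H-transform pyramid,
// zigzag-varint coefficient serialization, and gap-pixel median fill.
// All integer values travel as doubles on the R side; they are exact for
// |v| < 2^53, far beyond the 32-bit detector dynamic range handled here.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int64_t as_i64(double x) {
  return static_cast<int64_t>(std::llround(x));
}

// ---------------------------------------------------------------------------
// CBF byte-offset codec.
//
// Running delta from the previous value (initial previous = 0).
//   delta in [-127, 127]          -> 1 signed byte
//   else marker 0x80, then        -> signed 16-bit LE if in [-32767, 32767]
//   else marker 0x8000 (16b LE),  -> signed 32-bit LE if in int32 (excl. min)
//   else marker 0x80000000 (32b), -> signed 64-bit LE
// ---------------------------------------------------------------------------

static inline void push_le(std::vector<uint8_t> &out, uint64_t v, int nbytes) {
  for (int b = 0; b < nbytes; ++b) out.push_back((uint8_t)((v >> (8 * b)) & 0xFF));
}

// [[Rcpp::export(name = ".bo_encode")]]
RawVector bo_encode(NumericVector values) {
  const R_xlen_t n = values.size();
  std::vector<uint8_t> out;
  out.reserve((size_t)(n > 0 ? n + 16 : 16));
  int64_t prev = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (NumericVector::is_na(values[i]))
      stop("byte-offset encoder: NA at element %td", (ptrdiff_t)(i + 1));
    const int64_t v = as_i64(values[i]);
    const int64_t d = v - prev;
    prev = v;
    if (d >= -127 && d <= 127) {
      out.push_back((uint8_t)(int8_t)d);
    } else {
      out.push_back(0x80);
      if (d >= -32767 && d <= 32767) {
        push_le(out, (uint64_t)(uint16_t)(int16_t)d, 2);
      } else {
        push_le(out, 0x8000u, 2);
        if (d >= -2147483647LL && d <= 2147483647LL) {
          push_le(out, (uint64_t)(uint32_t)(int32_t)d, 4);
        } else {
          push_le(out, 0x80000000ULL, 4);
          push_le(out, (uint64_t)d, 8);
        }
      }
    }
  }
  RawVector res((R_xlen_t)out.size());
  if (!out.empty()) std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// [[Rcpp::export(name = ".bo_decode")]]
NumericVector bo_decode(RawVector payload, double n_values) {
  const R_xlen_t n = (R_xlen_t)n_values;
  const R_xlen_t len = payload.size();
  NumericVector out(n);
  R_xlen_t pos = 0;
  int64_t prev = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (pos >= len)
      stop("byte-offset decoder: payload truncated at byte %td (value %td of %td)",
           (ptrdiff_t)pos, (ptrdiff_t)(i + 1), (ptrdiff_t)n);
    int64_t d;
    uint8_t b = payload[pos++];
    if (b != 0x80) {
      d = (int64_t)(int8_t)b;
    } else {
      if (pos + 2 > len)
        stop("byte-offset decoder: payload truncated mid-escape at byte %td", (ptrdiff_t)pos);
      uint16_t u16 = (uint16_t)payload[pos] | ((uint16_t)payload[pos + 1] << 8);
      pos += 2;
      if (u16 != 0x8000u) {
        d = (int64_t)(int16_t)u16;
      } else {
        if (pos + 4 > len)
          stop("byte-offset decoder: payload truncated mid-escape at byte %td", (ptrdiff_t)pos);
        uint32_t u32 = 0;
        for (int k = 0; k < 4; ++k) u32 |= ((uint32_t)payload[pos + k]) << (8 * k);
        pos += 4;
        if (u32 != 0x80000000u) {
          d = (int64_t)(int32_t)u32;
        } else {
          if (pos + 8 > len)
            stop("byte-offset decoder: payload truncated mid-escape at byte %td", (ptrdiff_t)pos);
          uint64_t u64 = 0;
          for (int k = 0; k < 8; ++k) u64 |= ((uint64_t)payload[pos + k]) << (8 * k);
          pos += 8;
          d = (int64_t)u64;
        }
      }
    }
    prev += d;
    out[i] = (double)prev;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Integer H-transform (Haar pyramid) on a square power-of-two plane.
//
// Per 2x2 block [[a, b], [c, d]] (a = p00, b = p01, c = p10, d = p11):
//   h0 = a+b+c+d,  hx = (c+d)-(a+b),  hy = (b+d)-(a+c),  hc = d-c-b+a
// No division is performed at any level (divisions are deferred entirely),
// so the transform is exactly invertible in integer arithmetic: each pixel
// is (h0 +/- hx +/- hy +/- hc)/4, which is exact on unquantized input.
// Band layout after each level: h0 quadrant top-left, hy top-right,
// hx bottom-left, hc bottom-right.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".htrans_forward")]]
NumericMatrix htrans_forward(NumericMatrix x, int n_levels) {
  const int N = x.nrow();
  if (x.ncol() != N) stop("H-transform expects a square plane");
  NumericMatrix w = clone(x);
  std::vector<double> tmp((size_t)N * N);
  int m = N;
  for (int lev = 0; lev < n_levels; ++lev) {
    const int h = m / 2;
    for (int i = 0; i < h; ++i) {
      for (int j = 0; j < h; ++j) {
        const double a = w(2 * i, 2 * j);
        const double b = w(2 * i, 2 * j + 1);
        const double c = w(2 * i + 1, 2 * j);
        const double d = w(2 * i + 1, 2 * j + 1);
        tmp[(size_t)i + (size_t)j * m]             = a + b + c + d;
        tmp[(size_t)i + (size_t)(j + h) * m]       = (b + d) - (a + c);
        tmp[(size_t)(i + h) + (size_t)j * m]       = (c + d) - (a + b);
        tmp[(size_t)(i + h) + (size_t)(j + h) * m] = d - c - b + a;
      }
    }
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < m; ++i)
        w(i, j) = tmp[(size_t)i + (size_t)j * m];
    m = h;
  }
  return w;
}

// [[Rcpp::export(name = ".htrans_inverse")]]
NumericMatrix htrans_inverse(NumericMatrix coef, int n_levels) {
  const int N = coef.nrow();
  if (coef.ncol() != N) stop("H-transform expects a square plane");
  NumericMatrix w = clone(coef);
  std::vector<double> tmp((size_t)N * N);
  int m = N >> (n_levels - 1);
  if (n_levels <= 0) return w;
  for (int lev = n_levels - 1; lev >= 0; --lev) {
    const int h = m / 2;
    for (int i = 0; i < h; ++i) {
      for (int j = 0; j < h; ++j) {
        const double h0 = w(i, j);
        const double hy = w(i, j + h);
        const double hx = w(i + h, j);
        const double hc = w(i + h, j + h);
        tmp[(size_t)(2 * i) + (size_t)(2 * j) * m]         = (h0 - hx - hy + hc) / 4.0;
        tmp[(size_t)(2 * i) + (size_t)(2 * j + 1) * m]     = (h0 - hx + hy - hc) / 4.0;
        tmp[(size_t)(2 * i + 1) + (size_t)(2 * j) * m]     = (h0 + hx - hy - hc) / 4.0;
        tmp[(size_t)(2 * i + 1) + (size_t)(2 * j + 1) * m] = (h0 + hx + hy + hc) / 4.0;
      }
    }
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < m; ++i)
        w(i, j) = tmp[(size_t)i + (size_t)j * m];
    m *= 2;
  }
  return w;
}

// ---------------------------------------------------------------------------
// Zigzag varint serialization for signed integer coefficient streams.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".zz_encode")]]
RawVector zz_encode(NumericVector values) {
  std::vector<uint8_t> out;
  out.reserve((size_t)values.size() + 16);
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    int64_t v = as_i64(values[i]);
    uint64_t z = ((uint64_t)v << 1) ^ (uint64_t)(v >> 63);
    while (z >= 0x80) {
      out.push_back((uint8_t)(z | 0x80));
      z >>= 7;
    }
    out.push_back((uint8_t)z);
  }
  RawVector res((R_xlen_t)out.size());
  if (!out.empty()) std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// [[Rcpp::export(name = ".zz_decode")]]
NumericVector zz_decode(RawVector payload, double n_values) {
  const R_xlen_t n = (R_xlen_t)n_values;
  const R_xlen_t len = payload.size();
  NumericVector out(n);
  R_xlen_t pos = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t z = 0;
    int shift = 0;
    while (true) {
      if (pos >= len) stop("varint stream truncated at byte %td", (ptrdiff_t)pos);
      uint8_t b = payload[pos++];
      z |= ((uint64_t)(b & 0x7F)) << shift;
      if (!(b & 0x80)) break;
      shift += 7;
      if (shift > 63) stop("varint value overflows 64 bits");
    }
    int64_t v = (int64_t)(z >> 1) ^ -(int64_t)(z & 1);
    out[i] = (double)v;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Iterative median fill of invalid pixels from valid 5x5 neighbours, used to
// keep detector-gap sentinels out of the wavelet transform. Pixels filled in
// one sweep become donors for the next, so arbitrarily wide gaps close.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".fill_invalid_median")]]
NumericMatrix fill_invalid_median(NumericMatrix counts, LogicalMatrix valid) {
  const int nr = counts.nrow(), nc = counts.ncol();
  NumericMatrix out = clone(counts);
  std::vector<char> ok((size_t)nr * nc);
  std::vector<std::pair<int,int> > todo;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      ok[(size_t)i + (size_t)j * nr] = valid(i, j) ? 1 : 0;
      if (!valid(i, j)) todo.push_back(std::make_pair(i, j));
    }
  std::vector<double> nb;
  while (!todo.empty()) {
    std::vector<std::pair<int,int> > next;
    std::vector<std::pair<int,int> > filled;
    for (size_t k = 0; k < todo.size(); ++k) {
      const int i = todo[k].first, j = todo[k].second;
      nb.clear();
      for (int dj = -2; dj <= 2; ++dj)
        for (int di = -2; di <= 2; ++di) {
          const int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
          if (ok[(size_t)ii + (size_t)jj * nr]) nb.push_back(out(ii, jj));
        }
      if (nb.empty()) { next.push_back(todo[k]); continue; }
      std::sort(nb.begin(), nb.end());
      const size_t m = nb.size();
      // lower median keeps the fill integral
      out(i, j) = nb[(m - 1) / 2];
      filled.push_back(todo[k]);
    }
    if (filled.empty()) {
      // fully invalid plane: nothing to borrow from, fill zero
      for (size_t k = 0; k < next.size(); ++k) out(next[k].first, next[k].second) = 0;
      break;
    }
    for (size_t k = 0; k < filled.size(); ++k)
      ok[(size_t)filled[k].first + (size_t)filled[k].second * nr] = 1;
    todo.swap(next);
  }
  return out;
}
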