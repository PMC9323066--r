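// Bit-level canonical Huffman encode/decode and small raster helpers.
// Lengths are capped at 64 bits: exceeding that would require pathological
// (Fibonacci-growth) frequency tables far beyond any addressable image.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// canonical codes from canonical-order lengths (nondecreasing)
static std::vector<uint64_t> canon_codes(const IntegerVector& lengths) {
  int n = lengths.size();
  std::vector<uint64_t> codes(n);
  uint64_t code = 0;
  int prev = lengths[0];
  if (prev > 64) stop("code length exceeds 64 bits");
  for (int k = 0; k < n; ++k) {
    int len = lengths[k];
    if (len > 64) stop("code length exceeds 64 bits");
    if (len < prev) stop("lengths must be in canonical (nondecreasing) order");
    if (k > 0) code = (code + 1) << (len - prev);
    codes[k] = code;
    prev = len;
  }
  return codes;
}

// [[Rcpp::export(name = ".huff_pack")]]
List huff_pack(IntegerVector idx, IntegerVector lengths) {
  // idx: 0-based canonical codebook index per payload symbol
  std::vector<uint64_t> codes = canon_codes(lengths);
  R_xlen_t ns = idx.size();
  double total_bits = 0;
  for (R_xlen_t i = 0; i < ns; ++i) {
    int k = idx[i];
    if (k < 0 || k >= lengths.size()) stop("symbol index out of range");
    total_bits += lengths[k];
  }
  R_xlen_t nbytes = (R_xlen_t)((total_bits + 7) / 8);
  RawVector out(nbytes);
  std::fill(out.begin(), out.end(), 0);
  R_xlen_t bitpos = 0;  // MSB-first within each byte
  for (R_xlen_t i = 0; i < ns; ++i) {
    int k = idx[i];
    int len = lengths[k];
    uint64_t code = codes[k];
    for (int b = len - 1; b >= 0; --b) {
      if ((code >> b) & 1ULL)
        out[bitpos >> 3] |= (uint8_t)(0x80 >> (bitpos & 7));
      ++bitpos;
    }
  }
  return List::create(_["bytes"] = out, _["nbits"] = total_bits);
}

// [[Rcpp::export(name = ".huff_unpack")]]
IntegerVector huff_unpack(RawVector bytes, double nbits, IntegerVector lengths,
                          double count) {
  // canonical decode: per-length first-code/offset tables
  int n = lengths.size();
  std::vector<uint64_t> codes = canon_codes(lengths);
  int maxlen = lengths[n - 1];
  // first_code[len], first_index[len], count_at[len]
  std::vector<uint64_t> first_code(maxlen + 1, 0);
  std::vector<int> first_index(maxlen + 1, -1), count_at(maxlen + 1, 0);
  for (int k = 0; k < n; ++k) {
    int len = lengths[k];
    if (first_index[len] < 0) { first_index[len] = k; first_code[len] = codes[k]; }
    ++count_at[len];
  }
  R_xlen_t total = (R_xlen_t)count;
  IntegerVector out(total);
  uint64_t acc = 0;
  int acc_len = 0;
  R_xlen_t bitpos = 0, nb = (R_xlen_t)nbits;
  R_xlen_t produced = 0;
  while (produced < total) {
    if (bitpos >= nb)
      stop("corrupt payload: bit stream exhausted at bit %g of %g after %g of %g symbols",
           (double)bitpos, (double)nb, (double)produced, (double)total);
    int bit = (bytes[bitpos >> 3] >> (7 - (bitpos & 7))) & 1;
    ++bitpos;
    acc = (acc << 1) | (uint64_t)bit;
    ++acc_len;
    if (acc_len <= maxlen && count_at[acc_len] > 0) {
      uint64_t fc = first_code[acc_len];
      if (acc >= fc && acc < fc + (uint64_t)count_at[acc_len]) {
        out[produced++] = first_index[acc_len] + (int)(acc - fc);
        acc = 0; acc_len = 0;
        continue;
      }
    }
    if (acc_len >= maxlen && !(acc_len <= maxlen && count_at[acc_len] > 0))
      ; // keep accumulating only while a longer code could still match
    if (acc_len > maxlen)
      stop("corrupt payload: no code matches at bit %g (byte offset %g)",
           (double)bitpos, (double)(bitpos >> 3));
  }
  if (bitpos != nb)
    stop("corrupt payload: %g unread bits after final symbol", (double)(nb - bitpos));
  return out;
}

// ---- CRC-32 (PNG chunk checksums) ------------------------------------------

static uint32_t crc_table[256];
static bool crc_ready = false;
static void crc_init() {
  for (uint32_t i = 0; i < 256; ++i) {
    uint32_t c = i;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
    crc_table[i] = c;
  }
  crc_ready = true;
}

// [[Rcpp::export(name = ".crc32")]]
double crc32_raw(RawVector data) {
  if (!crc_ready) crc_init();
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = crc_table[(c ^ data[i]) & 0xFF] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}

// ---- PNG scanline unfiltering ----------------------------------------------

static inline int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export(name = ".png_unfilter")]]
RawVector png_unfilter(RawVector data, int nrow, int rowbytes, int bpp) {
  // data: nrow * (1 + rowbytes), each row led by its filter-type byte
  if ((R_xlen_t)nrow * (rowbytes + 1) != data.size())
    stop("filtered data size mismatch");
  RawVector out((R_xlen_t)nrow * rowbytes);
  std::vector<uint8_t> prev(rowbytes, 0), cur(rowbytes, 0);
  R_xlen_t ip = 0;
  for (int r = 0; r < nrow; ++r) {
    int ft = data[ip++];
    for (int i = 0; i < rowbytes; ++i) cur[i] = data[ip + i];
    ip += rowbytes;
    switch (ft) {
    case 0: break;
    case 1:
      for (int i = bpp; i < rowbytes; ++i) cur[i] += cur[i - bpp];
      break;
    case 2:
      for (int i = 0; i < rowbytes; ++i) cur[i] += prev[i];
      break;
    case 3:
      for (int i = 0; i < rowbytes; ++i) {
        int a = i >= bpp ? cur[i - bpp] : 0;
        cur[i] += (uint8_t)((a + prev[i]) >> 1);
      }
      break;
    case 4:
      for (int i = 0; i < rowbytes; ++i) {
        int a = i >= bpp ? cur[i - bpp] : 0;
        int c = i >= bpp ? prev[i - bpp] : 0;
        cur[i] += (uint8_t)paeth(a, prev[i], c);
      }
      break;
    default: stop("unsupported PNG filter type %d on row %d", ft, r);
    }
    std::copy(cur.begin(), cur.end(), out.begin() + (R_xlen_t)r * rowbytes);
    std::swap(prev, cur);
  }
  return out;
}
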